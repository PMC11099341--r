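#!/usr/bin/env Rscript
# Stage 6: train the five DNAm predictors of CRP on the training cohort and
# serialize their weights: elastic net (alpha 0.5, 20-fold CV), Bayesian
# posterior-mean weights, PCA + elastic net on pre-filtered probes, and two
# EWAS-weight scores (own EWAS and an independent reference EWAS).

suppressPackageStartupMessages(library(methylcrp))

seed <- 2024L
dir.create("results", showWarnings = FALSE)
train <- generate_cohort(sim_config(n_samples = 1000, n_probes = 2000,
                                    n_snps = 300, seed = seed))
ph <- prepare_phenotype(train$pheno)
y <- ph$log_crp

basic <- run_ewas(train$meth, ph, ewas_covariates(ph, "basic"), "basic")
mcmc <- desk_mixture_config(seeds = c(seed + 11L, seed + 23L))

w <- list()
w$elnet <- train_elastic_net(train$meth, y, seed = seed)

Bs <- methylcrp:::scale_cols(train$meth$beta)
colnames(Bs) <- train$meth$probe_ids
post <- gibbs_fit(list(methylation = Bs), methylcrp:::std_vec(y), mcmc)
w$bayes <- bayes_weights(
  post,
  setNames(colMeans(train$meth$beta), train$meth$probe_ids),
  setNames(apply(train$meth$beta, 2, sd), train$meth$probe_ids),
  y_center = mean(y), y_scale = sd(y))

w$pca_elnet <- train_pca_elnet(train$meth, y, prefilter = basic,
                               p_threshold = 1e-3, seed = seed)
w$ewas_own <- ewas_weight_score(basic, p_threshold = 1e-5)

ref <- derive_test_cohort(train, probes_missing = 0, seed = seed + 707L)
ref_ph <- prepare_phenotype(ref$pheno)
ref_ewas <- run_ewas(ref$meth, ref_ph, ewas_covariates(ref_ph, "basic"),
                     "reference")
w$ewas_ref <- ewas_weight_score(ref_ewas, p_threshold = 1e-5)

for (nm in names(w))
  write_weights(w[[nm]], sprintf("results/06_weights_%s.tsv", nm))

cat("probes selected per predictor:\n")
for (nm in names(w))
  cat(sprintf("  %-10s %5d probes\n", nm, w[[nm]]$n_probes))
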