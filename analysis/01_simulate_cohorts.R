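#!/usr/bin/env Rscript
# Stage 1: generate the synthetic training cohort and a derived external
# test cohort, and record their demographics and the generative truth.
#
# The training cohort emulates a population study with high-sensitivity CRP
# and EPIC-style methylation; the test cohort is drawn from the same law on
# a 450K-style array with a configurable number of missing probes.

suppressPackageStartupMessages(library(methylcrp))

seed <- 2024L
dir.create("results", showWarnings = FALSE)

cfg <- sim_config(n_samples = 1000, n_probes = 2000, n_snps = 300,
                  probes_missing_in_test = 50, seed = seed)
train <- generate_cohort(cfg)
test <- derive_test_cohort(train, seed = seed + 101L)

demog <- function(co, label) {
  p <- co$pheno
  data.frame(cohort = label, n = nrow(p),
             age_mean = mean(p$age), age_sd = sd(p$age),
             pct_female = 100 * mean(p$sex == 1),
             crp_mean = mean(p$crp_mg_per_l), crp_sd = sd(p$crp_mg_per_l),
             assay = p$assay[1], array = co$meth$array_tag,
             n_probes = length(co$meth$probe_ids))
}
tab <- rbind(demog(train, "train"), demog(test, "test"))
write.table(format(tab, digits = 3), "results/01_demographics.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)

tr <- train$truth
jsonlite::write_json(list(
  seed = seed,
  n_causal_probes = length(tr$causal_probe_ids),
  n_causal_snps = length(tr$causal_snp_ids),
  realized_variance = as.list(round(tr$realized_var, 4)),
  configured = list(var_dnam = cfg$var_dnam, var_snp = cfg$var_snp)),
  "results/01_truth.json", auto_unbox = TRUE, pretty = TRUE)

cat(sprintf("training cohort: n=%d, CRP mean %.1f mg/L (target ~3.3)\n",
            nrow(train$pheno), mean(train$pheno$crp_mg_per_l)))
cat(sprintf("realized variance shares: dnam %.3f, snp %.3f, conf %.3f\n",
            tr$realized_var[["dnam"]], tr$realized_var[["snp"]],
            tr$realized_var[["conf"]]))
cat(sprintf("test cohort lacks %d of %d probes\n",
            length(train$meth$probe_ids) - length(test$meth$probe_ids),
            length(train$meth$probe_ids)))
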