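# methylcrp

Blood DNA-methylation analysis and prediction of chronic low-grade
inflammation, indexed by C-reactive protein (CRP).

CRP is the standard blood marker of systemic inflammation, but it is
phasic: a single measurement reflects recent infection or injury as much
as a person's long-term inflammatory state. Blood DNA methylation (DNAm)
changes slowly, and weighted combinations of CpG beta-values can act as
temporally stable surrogates of CRP. This package implements the full
analysis sequence of such a study — from epigenome-wide association through
Bayesian variance partitioning to predictor training and health-outcome
testing — as tested, reusable functions, driven by a synthetic-cohort
generator with known architecture so that every claim is checkable against
ground truth.

It is aimed at statistical geneticists and epigenetics researchers who
want a transparent, desk-scale re-implementation of this analysis style:
the Gibbs sampler, the relationship-matrix REML, the weight composition
and the evaluation battery are all open code with oracle-backed tests.

## What is implemented

* **Synthetic cohorts** (`sim_config()`, `generate_cohort()`,
  `derive_test_cohort()`, `generate_longitudinal()`): correlated CpG
  blocks within 2.5 kb windows on a logistic latent scale, a methylation
  and a genetic variance component of log CRP (defaults 50% and 13%),
  confounding through BMI/smoking/cells/batch, low-/high-sensitivity
  assay behaviour, multi-wave phasic CRP over stable methylation, 26
  health outcomes, and a ground-truth record enabling parameter-recovery
  tests.
* **Preprocessing** (`transform_crp()`, `filter_outliers()`,
  `residualize()`, `qc_genotypes()`): below-detection low-sensitivity
  readings assigned 1.5 mg/L, `log(CRP + 0.01)`, median ± 4 SD exclusion,
  SNP filters (call rate > 98%, HWE p ≥ 1e-6, MAF ≥ 1%) with mean
  imputation.
* **EWAS** (`run_ewas()`, `genomic_inflation()`, `attenuation_stats()`,
  `compare_ewas()`): per-probe OLS of `log(CRP + 0.01) ~ probe + age +
  sex + cells (granulocytes dropped) + batch`, the fully adjusted variant
  adding lifestyle covariates and 20 ancestry components, lambda,
  attenuation and cross-study effect-size comparison. Significance
  defaults to p < 3.6e-8.
* **Bayesian mixture regression** (`gibbs_fit()`, `compute_pip()`,
  `group_probes()`, `variance_partition()`): spike plus N(0, 0.001),
  N(0, 0.01), N(0, 0.1) mixture over one or two standardised feature
  classes; 10,000-iteration/4-chain published schedule with pooled final
  draws (1,000), PIPs, 2.5 kb/|r|>0.5 probe grouping at group PIP > 80%,
  and rank-based 95% credible intervals (ranks 25/975 of 1,000). The
  sweep kernel is compiled (RcppArmadillo).
* **REML cross-check** (`build_relationship_matrix()`, `prune_related()`,
  `reml_fit()`): ORM/GRM construction, greedy relatedness pruning,
  AI-REML with EM fallback and monitored likelihood.
* **Predictors** (`train_elastic_net()`, `train_pca_elnet()`,
  `ewas_weight_score()`, `bayes_weights()`, `project_score()`,
  `write_weights()`/`read_weights()`): five predictor styles with
  raw-beta-scale portable weights and missing-probe-tolerant projection.
* **Evaluation** (`correlation_eval()`, `incremental_r2()`, `icc2k()`,
  `longitudinal_lmm()`, `outcome_battery()`, `bh_fdr()`,
  `polygenic_score()`) and the orchestrated study replica
  (`run_pipeline()`, `compare_predictors()`).

## Worked example

The numbered scripts under `analysis/` run the study replica stage by
stage at n = 1,000 samples × 2,000 probes (seed 2024) and write their
tables under `results/`. A condensed session:

```r
library(methylcrp)

cfg   <- sim_config(n_samples = 1000, n_probes = 2000, n_snps = 300,
                    seed = 2024)
train <- generate_cohort(cfg)
ph    <- prepare_phenotype(train$pheno)

basic <- run_ewas(train$meth, ph, ewas_covariates(ph, "basic"), "basic")
full  <- run_ewas(train$meth, ph, ewas_covariates(ph, "full"), "full")
ewas_summary(basic)$n_signif
attenuation_stats(basic, full)$pct_lost
```

On this cohort the basic model finds 91 probes at p < 3.6e-8 (lambda
1.84, inflated by the built-in confounding); full adjustment keeps only 5
and attenuates 94.5% of the basic hits to non-significance — the
qualitative signature of lifestyle confounding of blood methylation.

```r
adj  <- methylcrp:::adjust_for_variance_partition(train)
post <- gibbs_fit(list(methylation = adj$B), adj$y,
                  desk_mixture_config(seeds = c(2035L, 2047L)))
variance_partition(post)
```

The mixture model attributes 57.2% of CRP variance to genome-wide DNAm
(95% CrI 49.8–64.9); the ORM-REML route gives 55.0% (95% CI 47.2–62.8) on
the same data, and the joint genetic + methylation model gives 56.6% and
13.6%. The recovered genome-wide estimate sits above the causal
methylation share (50.3% realized in this draw) because it also absorbs
confounder-shared probe–CRP covariance — as genome-wide estimates on real
data do.

```r
res <- run_pipeline(sim = cfg,
                    mcmc = desk_mixture_config(seeds = c(2035L, 2047L)))
compare_predictors(res)
```

On the held-out test cohort the feature-selection predictors (elastic
net, Bayesian, PCA+elnet) reach r ≈ 0.54–0.71 with measured log CRP and
clearly out-perform the EWAS-weight scores (r ≈ 0.37–0.39); the DNAm
score is temporally more stable than phasic assay CRP (ICC2k 0.98 vs
0.94); and the genetic score's incremental R² (11.2%) tracks its
generative share (13.1%).

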