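#' Synthetic GWAS summary table for a cohort's genetic architecture
#'
#' Emulates external GWAS summary statistics: causal SNPs receive their
#' generative per-allele effects (standardised weight over the population
#' dosage SD) with genome-wide-significant p-values; null SNPs get null
#' effects. Used to drive polygenic scoring without a deposited reference.
#'
#' @param cohort A \code{crp_cohort}.
#' @param p_causal,p_null P-values assigned to causal and null SNPs.
#' @return Data frame: snp_id, effect_allele, other_allele, effect, p.
#' @export
synthetic_gwas_table <- function(cohort, p_causal = 1e-10, p_null = 0.5) {
  g <- cohort$geno
  tr <- cohort$truth
  sd_pop <- sqrt(2 * g$maf * (1 - g$maf))
  eff <- rep(0, length(g$snp_ids))
  ci <- match(tr$causal_snp_ids, g$snp_ids)
  eff[ci] <- tr$causal_snp_effects / sd_pop[ci]
  data.frame(snp_id = g$snp_ids, effect_allele = g$effect_allele,
             other_allele = g$other_allele, effect = eff,
             p = ifelse(seq_along(eff) %in% ci, p_causal, p_null),
             stringsAsFactors = FALSE)
}

# Standardised probe matrix and phenotype residuals for the variance
# partitioning pipeline: phenotype adjusted for age + sex; probes adjusted
# for age, sex, cell proportions and batch. Residuals scaled to unit
# variance.
adjust_for_variance_partition <- function(cohort) {
  ph <- cohort$pheno
  if (is.null(ph$log_crp)) ph <- prepare_phenotype(ph)
  y_cov <- ph[, c("age", "sex")]
  meth_cov <- ph[, c("age", "sex", "bcell", "cd4t", "cd8t", "gran",
                     "mono", "nk", "batch")]
  y_adj <- std_vec(residualize(ph$log_crp, y_cov))
  B_adj <- residualize(cohort$meth$beta, meth_cov, scale = TRUE)
  colnames(B_adj) <- cohort$meth$probe_ids
  list(y = y_adj, B = B_adj)
}

#' Run the full study replica on synthetic data
#'
#' Executes the whole analysis sequence on one generated training cohort
#' and one derived test cohort: phenotype preparation, basic and fully
#' adjusted EWAS with inflation and attenuation summaries, the Bayesian
#' mixture fit with probe grouping and variance partitioning (methylation
#' alone and jointly with genotypes), the ORM-REML cross-check, training of
#' the five DNAm predictors, projection onto the test cohort, and the
#' evaluation battery (correlations, incremental R-squared with a polygenic
#' score, temporal stability, longitudinal mixed model, health-outcome
#' associations).
#'
#' @param sim A [sim_config()] (defines both cohorts via its seed).
#' @param mcmc A [mixture_config()]; defaults to the reduced desk scale.
#' @param ewas_score_threshold P-value threshold for the own-EWAS weighted
#'   score.
#' @param prefilter_threshold Pre-filter threshold for the PCA+elnet
#'   predictor (applied to the basic-model EWAS as reference table).
#' @param n_waves,tracking_corr,assay_per_wave Longitudinal design for the
#'   stability analyses on the test cohort.
#' @param reml If \code{FALSE}, skip the REML cross-check.
#' @param joint If \code{FALSE}, skip the joint methylation + genetic fit.
#' @param grm_cutoff Relatedness cutoff for pruning before genetic REML.
#'   \code{NULL} (default) uses \code{max(0.05, 4 / sqrt(n_snps))}: with few
#'   markers the sampling noise of estimated relatedness (~1/sqrt(m))
#'   exceeds the production cutoff of 0.05, which would spuriously prune
#'   unrelated samples.
#' @param out_dir Optional directory for per-stage TSV outputs and the JSON
#'   summary.
#' @return List with all stage outputs and a machine-readable
#'   \code{summary}.
#' @export
run_pipeline <- function(sim = sim_config(), mcmc = desk_mixture_config(),
                         ewas_score_threshold = 1e-5,
                         prefilter_threshold = 1e-3,
                         n_waves = 4, tracking_corr = 0.3,
                         assay_per_wave = c("low", "high", "high", "high"),
                         reml = TRUE, joint = TRUE, grm_cutoff = NULL,
                         out_dir = NULL) {
  t0 <- Sys.time()
  train <- generate_cohort(sim)
  test <- derive_test_cohort(train, seed = sim$seed + 101L)
  train$pheno <- prepare_phenotype(train$pheno)
  test$pheno <- prepare_phenotype(test$pheno)

  # --- EWAS ---------------------------------------------------------------
  basic <- run_ewas(train$meth, train$pheno,
                    ewas_covariates(train$pheno, "basic"), "basic")
  full <- run_ewas(train$meth, train$pheno,
                   ewas_covariates(train$pheno, "full"), "full")
  ewas_sum <- list(basic = ewas_summary(basic), full = ewas_summary(full),
                   attenuation = attenuation_stats(basic, full))

  # --- Bayesian mixture: variance partition + grouping --------------------
  adj <- adjust_for_variance_partition(train)
  post_meth <- gibbs_fit(list(methylation = adj$B), adj$y, mcmc)
  vp_meth <- variance_partition(post_meth)
  pips <- compute_pip(post_meth)
  groups <- group_probes(post_meth, train$meth)

  post_joint <- vp_joint <- NULL
  geno_qc <- qc_genotypes(train$geno)
  if (joint) {
    G_std <- scale_cols(geno_qc$dosage)
    colnames(G_std) <- geno_qc$snp_ids
    post_joint <- gibbs_fit(list(methylation = adj$B, genetic = G_std),
                            adj$y, mcmc)
    vp_joint <- variance_partition(post_joint)
  }

  # --- REML cross-check ---------------------------------------------------
  reml_meth <- reml_joint <- NULL
  if (reml) {
    orm <- build_relationship_matrix(adj$B, "ORM")
    reml_meth <- reml_fit(adj$y, matrices = orm)
    if (joint) {
      grm <- build_relationship_matrix(geno_qc$dosage, "GRM",
                                       maf = geno_qc$maf)
      if (is.null(grm_cutoff))
        grm_cutoff <- max(0.05, 4 / sqrt(grm$n_features))
      keep <- prune_related(grm, grm_cutoff)
      if (length(keep) == length(adj$y)) {
        reml_joint <- reml_fit(adj$y, matrices = list(orm, grm))
      } else {
        orm_k <- orm; orm_k$values <- orm$values[keep, keep]
        grm_k <- grm; grm_k$values <- grm$values[keep, keep]
        reml_joint <- reml_fit(adj$y[keep],
                               matrices = list(orm_k, grm_k))
      }
    }
  }

  # --- Predictor training (unadjusted, scaled pipeline) -------------------
  y_train <- train$pheno$log_crp
  w_elnet <- train_elastic_net(train$meth, y_train, seed = sim$seed)
  Bs <- scale_cols(train$meth$beta)
  colnames(Bs) <- train$meth$probe_ids
  post_pred <- gibbs_fit(list(methylation = Bs), std_vec(y_train), mcmc)
  w_bayes <- bayes_weights(post_pred,
                           stats::setNames(colMeans(train$meth$beta),
                                           train$meth$probe_ids),
                           stats::setNames(apply(train$meth$beta, 2,
                                                 stats::sd),
                                           train$meth$probe_ids),
                           y_center = mean(y_train),
                           y_scale = stats::sd(y_train))
  w_pca <- train_pca_elnet(train$meth, y_train, prefilter = basic,
                           p_threshold = prefilter_threshold,
                           seed = sim$seed)
  w_ewas_own <- ewas_weight_score(basic, ewas_score_threshold,
                                  training_means =
                                    stats::setNames(colMeans(train$meth$beta),
                                                    train$meth$probe_ids))
  # "reference-EWAS" score: weights from an EWAS in an independent cohort
  ref_cohort <- derive_test_cohort(train, probes_missing = 0,
                                   seed = sim$seed + 707L)
  ref_cohort$pheno <- prepare_phenotype(ref_cohort$pheno)
  ref_ewas <- run_ewas(ref_cohort$meth, ref_cohort$pheno,
                       ewas_covariates(ref_cohort$pheno, "basic"),
                       "reference")
  w_ewas_ref <- ewas_weight_score(ref_ewas, ewas_score_threshold)
  predictors <- list(elnet = w_elnet, bayes = w_bayes, pca_elnet = w_pca,
                     ewas_own = w_ewas_own, ewas_ref = w_ewas_ref)

  # --- Evaluation on the test cohort --------------------------------------
  scores <- lapply(predictors, project_score, meth = test$meth)
  correlations <- lapply(scores, correlation_eval, pheno = test$pheno)
  gwas <- synthetic_gwas_table(test)
  pgs <- polygenic_score(test$geno, gwas)
  base_cov <- test$pheno[, c("age", "sex")]
  incr <- lapply(scores, function(s)
    incremental_r2(test$pheno$log_crp, base_cov,
                   s$score[match(test$pheno$sample_id, s$sample_id)]))
  incr_pgs <- incremental_r2(test$pheno$log_crp, base_cov,
                             pgs$score[match(test$pheno$sample_id,
                                             pgs$sample_id)])
  incr_stacked <- lapply(scores, function(s)
    incremental_r2(test$pheno$log_crp, base_cov,
                   s$score[match(test$pheno$sample_id, s$sample_id)],
                   prior_additions = pgs$score[match(test$pheno$sample_id,
                                                     pgs$sample_id)]))

  # temporal stability: repeated measures on the test cohort; ICCs use the
  # high-sensitivity waves only, matching the headline comparison
  lng <- generate_longitudinal(test, n_waves = n_waves,
                               tracking_corr = tracking_corr,
                               assay_per_wave = assay_per_wave,
                               seed = sim$seed + 31L)
  hs_waves <- which(rep_len(assay_per_wave, n_waves) == "high")
  crp_wide <- sapply(hs_waves, function(w) {
    ph <- lng$pheno[lng$pheno$wave == w, ]
    transform_crp(ph$crp_mg_per_l, ph$assay, ph$below_detection)$log_crp
  })
  icc_assay <- icc2k(crp_wide, "assay_crp")
  score_wide <- sapply(hs_waves, function(w)
    project_score(w_elnet, lng$meth[[w]])$score)
  icc_dnam <- icc2k(score_wide, "dnam_crp_elnet")

  # longitudinal association of the wave-2 baseline with later CRP
  long_hs <- lng$pheno[lng$pheno$wave %in% hs_waves, ]
  long_hs$log_crp <- transform_crp(long_hs$crp_mg_per_l, long_hs$assay,
                                   long_hs$below_detection)$log_crp
  w2 <- lng$pheno[lng$pheno$wave == hs_waves[1], ]
  base_assay <- stats::setNames(transform_crp(w2$crp_mg_per_l, w2$assay,
                                              w2$below_detection)$log_crp,
                                w2$sample_id)
  lmm_assay <- longitudinal_lmm(long_hs, base_assay)
  base_dnam <- stats::setNames(project_score(w_elnet,
                                             lng$meth[[hs_waves[1]]])$score,
                               w2$sample_id)
  lmm_dnam <- longitudinal_lmm(long_hs, base_dnam)

  # health-outcome battery on the test cohort
  elnet_scores <- scores$elnet$score[match(test$pheno$sample_id,
                                           scores$elnet$sample_id)]
  battery <- outcome_battery(
    list(dnam_crp = elnet_scores, assay_crp = test$pheno$log_crp,
         genetic_score = pgs$score[match(test$pheno$sample_id,
                                         pgs$sample_id)]),
    test$pheno)

  summary <- list(
    schema_version = "1.0",
    seed = sim$seed,
    n_train = sim$n_samples, n_probes = sim$n_probes,
    ewas = list(lambda_basic = ewas_sum$basic$lambda_gc,
                lambda_full = ewas_sum$full$lambda_gc,
                n_hits_basic = ewas_sum$basic$n_signif,
                n_hits_full = ewas_sum$full$n_signif,
                pct_lost_full = ewas_sum$attenuation$pct_lost,
                mean_attenuation_pct =
                  ewas_sum$attenuation$mean_effect_attenuation_pct),
    variance = list(
      bayes_dnam = vp_meth$estimate[vp_meth$component == "methylation"],
      bayes_dnam_ci = c(vp_meth$lower[1], vp_meth$upper[1]),
      reml_dnam = if (!is.null(reml_meth))
        reml_meth$estimate[reml_meth$component == "methylation"] else NA,
      bayes_joint = if (!is.null(vp_joint))
        stats::setNames(vp_joint$estimate, vp_joint$component) else NULL,
      true_dnam = train$truth$realized_var[["dnam"]],
      true_snp = train$truth$realized_var[["snp"]]),
    n_significant_groups = sum(groups$significant),
    predictors = list(
      n_probes = vapply(predictors, `[[`, 0L, "n_probes"),
      test_r = vapply(correlations, `[[`, 0, "r"),
      incremental_r2 = vapply(incr, `[[`, 0, "delta_r2"),
      incremental_r2_pgs = incr_pgs$delta_r2,
      incremental_r2_stacked = vapply(incr_stacked, `[[`, 0, "delta_r2")),
    stability = list(icc_assay = icc_assay$icc2k,
                     icc_dnam = icc_dnam$icc2k,
                     lmm_interaction_assay = lmm_assay$effect,
                     lmm_interaction_dnam = lmm_dnam$effect),
    battery = list(
      n_fdr_hits = vapply(split(battery, battery$exposure), function(d)
        sum(d$q < 0.05, na.rm = TRUE), 0L)),
    runtime_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  result <- list(train = train, test = test, ewas_basic = basic,
                 ewas_full = full, ewas_summary = ewas_sum,
                 posterior = post_meth, posterior_joint = post_joint,
                 variance_bayes = vp_meth, variance_joint = vp_joint,
                 variance_reml = reml_meth, variance_reml_joint = reml_joint,
                 pips = pips, groups = groups, predictors = predictors,
                 scores = scores, correlations = correlations,
                 incremental = incr, incremental_pgs = incr_pgs,
                 icc = list(assay = icc_assay, dnam = icc_dnam),
                 lmm = list(assay = lmm_assay, dnam = lmm_dnam),
                 battery = battery, summary = summary)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

# Per-stage TSVs plus the JSON summary; every file carries the config hash.
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_file <- tempfile()
  writeLines(deparse(result$summary$seed), cfg_file)
  hash <- unname(tools::md5sum(cfg_file))
  unlink(cfg_file)
  stamp <- function(path) {
    cat(sprintf("# config_hash: %s\n", hash), file = path)
    path
  }
  wt <- function(d, name) {
    p <- stamp(file.path(out_dir, name))
    suppressWarnings(utils::write.table(d, p, sep = "\t", row.names = FALSE,
                                        quote = FALSE, append = TRUE))
  }
  wt(result$ewas_basic, "ewas_basic.tsv")
  wt(result$ewas_full, "ewas_full.tsv")
  wt(result$variance_bayes, "variance_bayes.tsv")
  if (!is.null(result$variance_reml))
    wt(result$variance_reml, "variance_reml.tsv")
  wt(result$groups, "probe_groups.tsv")
  wt(result$battery, "outcome_battery.tsv")
  s <- result$summary
  s$config_hash <- hash
  jsonlite::write_json(s, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Rank the trained predictors on a common test cohort
#'
#' @param result A [run_pipeline()] result.
#' @return Data frame of r, incremental R-squared (and ICC where computed)
#'   per predictor, ranked by incremental R-squared with the winner
#'   flagged.
#' @export
compare_predictors <- function(result) {
  nm <- names(result$predictors)
  tab <- data.frame(
    predictor = nm,
    r = vapply(result$correlations[nm], `[[`, 0, "r"),
    incremental_r2 = vapply(result$incremental[nm], `[[`, 0, "delta_r2"),
    icc = ifelse(nm == "elnet", result$icc$dnam$icc2k, NA_real_),
    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$incremental_r2), ]
  tab$rank <- rank(-tab$incremental_r2, ties.method = "min")
  tab$winner <- tab$rank == 1L
  rownames(tab) <- NULL
  tab
}
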