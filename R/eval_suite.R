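#' Pearson correlation between a DNAm score and log CRP
#'
#' @param scores Score data frame from [project_score()] (or any table with
#'   \code{sample_id} and \code{score}).
#' @param pheno Prepared phenotype table with \code{sample_id} and
#'   \code{log_crp} (rows with \code{included == FALSE} are dropped).
#' @return List with \code{r}, Fisher-z 95\% confidence bounds and \code{n}.
#' @export
correlation_eval <- function(scores, pheno) {
  if (!is.null(pheno$included)) pheno <- pheno[pheno$included, ]
  idx <- match(pheno$sample_id, scores$sample_id)
  ok <- !is.na(idx) & is.finite(pheno$log_crp)
  if (sum(ok) < 10) stop("fewer than 10 paired values")
  x <- scores$score[idx[ok]]
  y <- pheno$log_crp[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in scores or phenotype")
  r <- stats::cor(x, y)
  n <- sum(ok)
  z <- atanh(r)
  hw <- 1.96 / sqrt(n - 3)
  list(r = r, ci_low = tanh(z - hw), ci_high = tanh(z + hw), n = n)
}

#' Incremental R-squared of an added predictor
#'
#' Delta R2 = R2(full) - R2(null), where the null model regresses the
#' outcome on the base covariates (age and sex in the headline analyses)
#' and the full model adds the predictor(s). Prior additions support
#' stacked models (e.g. genetic score first, then the DNAm score).
#'
#' @param y Outcome vector (log CRP).
#' @param base_covariates Data frame of null-model covariates.
#' @param addition Vector or matrix added in the full model.
#' @param prior_additions Optional vector/matrix present in both models.
#' @return List with \code{delta_r2}, \code{r2_null}, \code{r2_full}.
#' @export
incremental_r2 <- function(y, base_covariates, addition,
                           prior_additions = NULL) {
  X0 <- build_design(base_covariates)
  if (!is.null(prior_additions)) X0 <- cbind(X0, as.matrix(prior_additions))
  X1 <- cbind(X0, as.matrix(addition))
  if (qr(X1)$rank < ncol(X1)) stop("full model design is rank deficient")
  r2 <- function(X) {
    res <- qr.resid(qr(X), y)
    1 - sum(res^2) / sum((y - mean(y))^2)
  }
  r2n <- r2(X0); r2f <- r2(X1)
  list(delta_r2 = r2f - r2n, r2_null = r2n, r2_full = r2f)
}

#' Temporal stability: ICC(2,k) from a subjects-by-waves matrix
#'
#' Two-way random-effects, absolute-agreement, average-measures intraclass
#' correlation (the Shrout-Fleiss "average random raters" form), computed
#' from the two-way ANOVA mean squares on complete cases:
#' ICC(2,k) = (MS_R - MS_E) / (MS_R + (MS_C - MS_E) / n).
#'
#' @param wide Numeric matrix, subjects in rows, waves in columns.
#' @param measure Label stored in the report.
#' @return List with \code{icc2k}, \code{n_subjects}, \code{n_waves},
#'   \code{measure}.
#' @export
icc2k <- function(wide, measure = "measure") {
  wide <- as.matrix(wide)
  cc <- stats::complete.cases(wide)
  M <- wide[cc, , drop = FALSE]
  n <- nrow(M); k <- ncol(M)
  if (k < 2) stop("need at least 2 waves")
  if (n < 5) stop("need at least 5 complete subjects")
  grand <- mean(M)
  row_m <- rowMeans(M); col_m <- colMeans(M)
  ss_r <- k * sum((row_m - grand)^2)
  ss_c <- n * sum((col_m - grand)^2)
  ss_tot <- sum((M - grand)^2)
  ss_e <- ss_tot - ss_r - ss_c
  ms_r <- ss_r / (n - 1)
  ms_c <- ss_c / (k - 1)
  ms_e <- ss_e / ((n - 1) * (k - 1))
  icc <- (ms_r - ms_e) / (ms_r + (ms_c - ms_e) / n)
  list(icc2k = icc, n_subjects = n, n_waves = k, measure = measure)
}

#' Longitudinal mixed model: baseline CRP measure vs future CRP
#'
#' Regresses repeated high-sensitivity log CRP on the baseline exposure
#' (assay CRP or a DNAm score at the first high-sensitivity wave), age, sex
#' and the baseline-by-age interaction, with a per-subject random intercept;
#' reports the Wald test on the interaction. Falls back to a fixed-effects
#' fit (flagged) if the random-intercept fit is singular.
#'
#' @param long Long-format data frame with columns \code{sample_id},
#'   \code{log_crp}, \code{age}, \code{sex}.
#' @param baseline Named or aligned vector: one baseline exposure value per
#'   subject (matched to \code{long$sample_id}).
#' @return List with interaction \code{effect}, \code{se}, \code{p},
#'   \code{singular} flag and the fitted model.
#' @export
longitudinal_lmm <- function(long, baseline) {
  if (!is.null(names(baseline)))
    long$base <- baseline[long$sample_id]
  else
    long$base <- baseline[match(long$sample_id, unique(long$sample_id))]
  n_subj <- length(unique(long$sample_id))
  if (n_subj < 20) stop("need at least 20 subjects")
  fit <- lmerTest::lmer(log_crp ~ base * age + sex + (1 | sample_id),
                        data = long)
  singular <- lme4::isSingular(fit)
  if (singular) {
    lmfit <- stats::lm(log_crp ~ base * age + sex, data = long)
    co <- summary(lmfit)$coefficients["base:age", ]
    return(list(effect = co[1], se = co[2], p = co[4], singular = TRUE,
                model = lmfit))
  }
  co <- summary(fit)$coefficients["base:age", ]
  list(effect = unname(co["Estimate"]), se = unname(co["Std. Error"]),
       p = unname(co["Pr(>|t|)"]), singular = FALSE, model = fit)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' @param p P-values in (0, 1].
#' @return Step-up adjusted q-values (monotone in p).
#' @export
bh_fdr <- function(p) {
  if (!length(p)) return(numeric(0))
  stats::p.adjust(p, method = "BH")
}

#' Health-outcome association battery
#'
#' For each exposure (DNAm score or assay CRP, standardised) and each
#' outcome: linear regression for continuous outcomes (standardised),
#' logistic regression for binary outcomes, Cox proportional hazards (Efron
#' ties) for survival. All models adjust for age and sex; outcomes listed in
#' \code{height_outcomes} additionally adjust for height when a
#' \code{height} column exists. BH-FDR is applied within each exposure's
#' family of outcomes. Binary outcomes with fewer than 10 events are
#' flagged and not fitted.
#'
#' @param exposures Named list of numeric vectors aligned to \code{pheno}
#'   rows.
#' @param pheno Phenotype table with outcome columns, \code{age},
#'   \code{sex}, and \code{survival_time}/\code{death_event} if survival is
#'   tested.
#' @param continuous,binary Character vectors of outcome column names.
#' @param survival If \code{TRUE}, include the all-cause mortality Cox
#'   model.
#' @param height_outcomes Continuous outcomes that get the extra height
#'   covariate.
#' @return Data frame of association records (outcome, model, exposure,
#'   effect with CI on the log scale for OR/HR, se, p, q, flag).
#' @export
outcome_battery <- function(exposures, pheno,
                            continuous = grep("^outcome_c",
                                              names(pheno), value = TRUE),
                            binary = grep("^outcome_b", names(pheno),
                                          value = TRUE),
                            survival = TRUE,
                            height_outcomes = character(0)) {
  stopifnot(is.list(exposures), !is.null(names(exposures)))
  rows <- list()
  for (ex_name in names(exposures)) {
    x <- std_vec(exposures[[ex_name]])
    fam <- list()
    for (oc in continuous) {
      yv <- std_vec(pheno[[oc]])
      dat <- data.frame(y = yv, x = x, age = pheno$age, sex = pheno$sex)
      if (oc %in% height_outcomes && !is.null(pheno$height))
        dat$height <- pheno$height
      fit <- stats::lm(y ~ ., data = dat)
      co <- summary(fit)$coefficients["x", ]
      fam[[length(fam) + 1L]] <- data.frame(
        outcome = oc, model = "linear", exposure = ex_name,
        effect = co[1], se = co[2], p = co[4], flagged = FALSE)
    }
    for (oc in binary) {
      yv <- pheno[[oc]]
      if (min(sum(yv == 1), sum(yv == 0)) < 10) {
        fam[[length(fam) + 1L]] <- data.frame(
          outcome = oc, model = "logistic", exposure = ex_name,
          effect = NA_real_, se = NA_real_, p = NA_real_, flagged = TRUE)
        next
      }
      fit <- stats::glm(yv ~ x + age + sex, data = pheno,
                        family = stats::binomial())
      co <- summary(fit)$coefficients["x", ]
      fam[[length(fam) + 1L]] <- data.frame(
        outcome = oc, model = "logistic", exposure = ex_name,
        effect = co[1], se = co[2], p = co[4], flagged = FALSE)
    }
    if (survival) {
      fit <- survival::coxph(
        survival::Surv(pheno$survival_time, pheno$death_event) ~ x +
          age + sex, data = pheno, ties = "efron")
      co <- summary(fit)$coefficients["x", ]
      fam[[length(fam) + 1L]] <- data.frame(
        outcome = "all_cause_mortality", model = "cox", exposure = ex_name,
        effect = co["coef"], se = co["se(coef)"],
        p = co["Pr(>|z|)"], flagged = FALSE)
    }
    fam <- do.call(rbind, fam)
    fam$q <- NA_real_
    fam$q[!fam$flagged] <- bh_fdr(fam$p[!fam$flagged])
    fam$ci_low <- fam$effect - 1.96 * fam$se
    fam$ci_high <- fam$effect + 1.96 * fam$se
    rows[[ex_name]] <- fam
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Additive weighted polygenic score
#'
#' Sums dosage times effect over SNPs passing the GWAS significance
#' threshold, aligning alleles first: when the GWAS effect allele matches
#' the cohort's other allele (swapped coding) the effect sign is flipped;
#' SNPs whose alleles cannot be reconciled are dropped with a warning.
#'
#' @param geno A \code{geno_set} (dosages count the \code{effect_allele}).
#' @param gwas Data frame with \code{snp_id}, \code{effect_allele},
#'   \code{other_allele}, \code{effect}, \code{p}.
#' @param p_threshold Genome-wide threshold (default 5e-8).
#' @return Data frame: sample_id, score, n_snps_used.
#' @export
polygenic_score <- function(geno, gwas, p_threshold = 5e-8) {
  g <- gwas[gwas$p < p_threshold, ]
  idx <- match(g$snp_id, geno$snp_ids)
  ok <- !is.na(idx)
  g <- g[ok, ]; idx <- idx[ok]
  same <- g$effect_allele == geno$effect_allele[idx] &
    g$other_allele == geno$other_allele[idx]
  swap <- g$effect_allele == geno$other_allele[idx] &
    g$other_allele == geno$effect_allele[idx]
  bad <- !(same | swap)
  if (any(bad)) {
    warning(sum(bad), " SNP(s) dropped for unresolvable allele mismatch")
    keep <- !bad
    g <- g[keep, ]; idx <- idx[keep]
    same <- same[keep]
  }
  w <- ifelse(same, g$effect, -g$effect)
  score <- if (length(idx))
    drop(geno$dosage[, idx, drop = FALSE] %*% w) else
      rep(0, length(geno$sample_ids))
  data.frame(sample_id = geno$sample_ids, score = score,
             n_snps_used = length(idx), stringsAsFactors = FALSE)
}
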