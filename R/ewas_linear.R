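#' Covariate sets for the EWAS models
#'
#' The basic model adjusts for chronological age, sex, estimated white blood
#' cell proportions (granulocytes dropped; the six proportions sum to one)
#' and experimental batch. The fully adjusted model further includes alcohol
#' consumption, BMI, deprivation, education, a smoking score and 20 genetic
#' ancestry components.
#'
#' @param pheno Phenotype table from the generator / [prepare_phenotype()].
#' @param model \code{"basic"} or \code{"full"}.
#' @return Data frame of covariates aligned to the phenotype rows.
#' @export
ewas_covariates <- function(pheno, model = c("basic", "full")) {
  model <- match.arg(model)
  cols <- c("age", "sex", "bcell", "cd4t", "cd8t", "gran", "mono", "nk",
            "batch")
  if (model == "full")
    cols <- c(cols, "alcohol", "bmi", "deprivation", "education",
              "smoking_score", paste0("anc", 1:20))
  pheno[, intersect(cols, names(pheno)), drop = FALSE]
}

#' Mass-univariate EWAS of log CRP
#'
#' Fits, for every probe, the OLS model
#' \code{log_crp ~ probe + covariates} and reports the probe coefficient
#' (change in log CRP per unit beta-value), its standard error and two-sided
#' p-value from the t statistic. Computation uses the Frisch-Waugh
#' decomposition: phenotype and probes are residualized on the covariates
#' once, then each probe enters a simple regression with the covariate
#' degrees of freedom accounted for.
#'
#' @param meth A \code{meth_set}.
#' @param pheno Prepared phenotype table (needs \code{log_crp}; rows with
#'   \code{included == FALSE} are dropped).
#' @param covariates Data frame of covariates aligned to \code{pheno} rows,
#'   e.g. from [ewas_covariates()].
#' @param model_tag Label stored with the results.
#' @return Data frame of class \code{ewas_result}: probe_id, chr, pos,
#'   effect, se, p, n, model_tag; constant probes get effect 0, p 1 and a
#'   \code{constant} flag.
#' @export
run_ewas <- function(meth, pheno, covariates, model_tag = "custom") {
  keep <- rep(TRUE, nrow(pheno))
  if (!is.null(pheno$included)) keep <- keep & pheno$included
  cc <- stats::complete.cases(pheno$log_crp, covariates)
  keep <- keep & cc
  if (sum(keep) < 10) stop("fewer than 10 complete cases")
  idx <- match(pheno$sample_id[keep], meth$sample_ids)
  if (anyNA(idx)) stop("phenotype samples missing from methylation data")
  B <- meth$beta[idx, , drop = FALSE]
  y <- pheno$log_crp[keep]
  X <- build_design(covariates[keep, , drop = FALSE])
  qrX <- qr(X)
  n <- length(y)
  df <- n - qrX$rank - 1L
  y_r <- qr.resid(qrX, y)
  B_r <- qr.resid(qrX, B)
  ss_b <- colSums(B_r^2)
  const <- ss_b < 1e-12
  ss_b[const] <- 1
  xy <- drop(crossprod(B_r, y_r))
  eff <- xy / ss_b
  rss <- sum(y_r^2) - eff * xy
  sigma2 <- pmax(rss, 0) / df
  se <- sqrt(sigma2 / ss_b)
  tval <- eff / se
  p <- 2 * stats::pt(-abs(tval), df = df)
  eff[const] <- 0; se[const] <- NA_real_; p[const] <- 1
  res <- data.frame(probe_id = meth$probe_ids, chr = meth$probe_chr,
                    pos = meth$probe_pos, effect = eff, se = se,
                    p = pmax(p, .Machine$double.xmin), n = n,
                    model_tag = model_tag, constant = const,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(res) <- c("ewas_result", "data.frame")
  res
}

#' Genomic inflation factor from p-values
#'
#' Lambda is the median of the 1-df chi-square statistics implied by the
#' p-values divided by the null 1-df chi-square median (about 0.45494).
#'
#' @param p_values P-values in (0, 1].
#' @return The inflation factor lambda.
#' @export
genomic_inflation <- function(p_values) {
  p_values <- p_values[!is.na(p_values)]
  if (any(p_values <= 0)) stop("p-values must be strictly positive")
  if (length(p_values) < 100)
    warning("fewer than 100 p-values; lambda is unstable")
  chisq <- stats::qchisq(p_values, df = 1, lower.tail = FALSE)
  stats::median(chisq) / stats::qchisq(0.5, df = 1)
}

#' Summarise an EWAS at a significance threshold
#'
#' @param ewas An \code{ewas_result}.
#' @param threshold Epigenome-wide significance threshold (default 3.6e-8).
#' @return List with \code{lambda_gc}, \code{n_signif} and the threshold.
#' @export
ewas_summary <- function(ewas, threshold = 3.6e-8) {
  list(lambda_gc = genomic_inflation(ewas$p),
       n_signif = sum(ewas$p < threshold),
       threshold = threshold)
}

#' Attenuation of basic-model associations after further adjustment
#'
#' Over the probes significant in the basic model at the threshold, reports
#' (a) the percentage whose adjusted-model p-value no longer reaches the
#' threshold and (b) the mean per-probe effect-size attenuation,
#' \code{100 * (|b_basic| - |b_adj|) / |b_basic|} (absolute effects).
#'
#' @param basic,adjusted \code{ewas_result}s over the same probe universe.
#' @param threshold Significance threshold.
#' @return List with \code{n_basic_hits}, \code{pct_lost},
#'   \code{mean_effect_attenuation_pct} and an \code{empty} flag.
#' @export
attenuation_stats <- function(basic, adjusted, threshold = 3.6e-8) {
  if (!identical(basic$probe_id, adjusted$probe_id))
    adjusted <- adjusted[match(basic$probe_id, adjusted$probe_id), ]
  hits <- which(basic$p < threshold)
  if (!length(hits))
    return(list(n_basic_hits = 0L, pct_lost = NA_real_,
                mean_effect_attenuation_pct = NA_real_, empty = TRUE))
  lost <- adjusted$p[hits] >= threshold
  att <- 100 * (abs(basic$effect[hits]) - abs(adjusted$effect[hits])) /
    abs(basic$effect[hits])
  list(n_basic_hits = length(hits), pct_lost = 100 * mean(lost),
       mean_effect_attenuation_pct = mean(att), empty = FALSE)
}

#' Correlate effect sizes with an external EWAS summary table
#'
#' Restricts to probes passing the threshold in the reference table and
#' present in \code{mine}, then reports the Pearson correlation of effect
#' sizes.
#'
#' @param mine An \code{ewas_result}.
#' @param reference Data frame with \code{probe_id}, \code{effect}, \code{p}.
#' @param threshold Reference significance threshold.
#' @return List with \code{r} and \code{n_shared}.
#' @export
compare_ewas <- function(mine, reference, threshold = 3.6e-8) {
  ref <- reference[reference$p < threshold, ]
  idx <- match(ref$probe_id, mine$probe_id)
  ok <- !is.na(idx)
  if (sum(ok) < 3) stop("fewer than 3 shared significant probes")
  list(r = stats::cor(ref$effect[ok], mine$effect[idx[ok]]),
       n_shared = sum(ok))
}
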