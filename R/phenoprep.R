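#' Transform CRP concentrations to the analysis scale
#'
#' Applies the two preprocessing rules used throughout the analyses:
#' low-sensitivity assays cannot resolve values below 3 mg/L, so
#' below-detection readings are assigned 1.5 mg/L; all values are then
#' log-transformed after adding a constant of 0.01 to prevent undefined
#' values at zero. Wide-range assays are treated like high-sensitivity ones
#' (no imputation).
#'
#' @param crp_mg_per_l Non-negative CRP concentrations (mg/L).
#' @param assay Assay type per value: \code{"high"}, \code{"low"} or
#'   \code{"wide"} (recycled).
#' @param below_detection Optional logical flag per value; when absent,
#'   low-sensitivity readings < 3 mg/L are treated as below detection.
#' @return A data frame with \code{log_crp}, \code{imputed_low_sens} and the
#'   working concentration \code{crp_used}.
#' @export
transform_crp <- function(crp_mg_per_l, assay = "high",
                          below_detection = NULL) {
  if (any(crp_mg_per_l < 0, na.rm = TRUE))
    stop("CRP concentrations must be non-negative")
  assay <- rep_len(assay, length(crp_mg_per_l))
  if (is.null(below_detection))
    below_detection <- assay == "low" & crp_mg_per_l < 3
  imput <- assay == "low" & below_detection
  crp_used <- ifelse(imput, 1.5, crp_mg_per_l)
  data.frame(log_crp = log(crp_used + 0.01),
             imputed_low_sens = imput,
             crp_used = crp_used)
}

#' Flag values within median +/- 4 SD
#'
#' Returns a logical mask that is \code{TRUE} for values retained by the
#' outlier rule: within four sample standard deviations of the median. The
#' SD is the plain sample SD of the full vector. For a constant vector the
#' SD is zero and only values equal to the median are retained (which is all
#' of them).
#'
#' @param values Numeric vector with at least 2 finite values.
#' @return Logical mask, \code{TRUE} = retained; the number of exclusions is
#'   attached as attribute \code{n_excluded}.
#' @export
filter_outliers <- function(values) {
  ok <- is.finite(values)
  if (sum(ok) < 2) stop("need at least 2 finite values")
  med <- stats::median(values[ok])
  s <- stats::sd(values[ok])
  mask <- ok & abs(values - med) <= 4 * s
  attr(mask, "n_excluded") <- sum(ok) - sum(mask)
  mask
}

#' Residualize a target on a covariate design
#'
#' Returns OLS residuals of each column of \code{target} on the covariates;
#' optionally scales each residual column to mean zero and unit variance
#' (the adjustment used before variance partitioning). If the design
#' contains all six cell-proportion columns (\code{bcell}, \code{cd4t},
#' \code{cd8t}, \code{gran}, \code{mono}, \code{nk}), the granulocyte column
#' is dropped to avoid collinearity, since the proportions sum to one.
#'
#' @param target Numeric vector or matrix (samples in rows).
#' @param covariates Data frame or matrix of covariates; factors are
#'   expanded to dummies.
#' @param scale If \code{TRUE}, scale residual columns to mean 0, variance 1.
#' @return Residuals with the same shape as \code{target}.
#' @export
residualize <- function(target, covariates, scale = FALSE) {
  X <- build_design(covariates)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient covariate design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  vec <- is.null(dim(target))
  Y <- as.matrix(target)
  if (nrow(Y) != nrow(X)) stop("target and covariates disagree on n")
  R <- qr.resid(qrX, Y)
  if (scale) R <- scale_cols(R)
  if (vec) drop(R) else R
}

# Expand a covariate spec into a full-rank-candidate design matrix with an
# intercept; drops the granulocyte column from a complete 6-cell design.
build_design <- function(covariates) {
  cv <- as.data.frame(covariates)
  cell_names <- c("bcell", "cd4t", "cd8t", "gran", "mono", "nk")
  if (all(cell_names %in% names(cv))) cv$gran <- NULL
  X <- stats::model.matrix(~ ., data = cv)
  X
}

#' Quality control for genotype data
#'
#' Removes SNPs with missing call rate above 2\%, Hardy-Weinberg equilibrium
#' exact-fit chi-square p below 1e-6, or minor allele frequency below 1\%;
#' remaining missing dosages are mean-imputed. Thresholds are configurable.
#'
#' @param geno A \code{geno_set} (dosage matrix with per-SNP metadata).
#' @param max_missing Maximum missing call rate.
#' @param hwe_p_min Minimum HWE p-value.
#' @param maf_min Minimum minor allele frequency.
#' @return The filtered \code{geno_set}; a removal report per criterion is
#'   attached as attribute \code{qc_report}.
#' @export
qc_genotypes <- function(geno, max_missing = 0.02, hwe_p_min = 1e-6,
                         maf_min = 0.01) {
  d <- geno$dosage
  miss <- colMeans(is.na(d))
  p_alt <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(p_alt, 1 - p_alt)
  hwe <- hwe_test(d)
  fail_miss <- miss > max_missing
  fail_hwe <- hwe < hwe_p_min
  fail_maf <- maf < maf_min
  keep <- !(fail_miss | fail_hwe | fail_maf)
  if (!any(keep)) stop("no SNPs survive quality control")
  d <- d[, keep, drop = FALSE]
  # mean imputation of remaining missing dosages
  if (anyNA(d)) {
    mu <- colMeans(d, na.rm = TRUE)
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- mu[idx[, 2]]
  }
  out <- list(sample_ids = geno$sample_ids, snp_ids = geno$snp_ids[keep],
              dosage = d, maf = maf[keep],
              effect_allele = geno$effect_allele[keep],
              other_allele = geno$other_allele[keep],
              missing_rate = miss[keep], hwe_p = hwe[keep])
  class(out) <- "geno_set"
  attr(out, "qc_report") <- list(n_input = length(keep),
                                 n_removed_missing = sum(fail_miss),
                                 n_removed_hwe = sum(fail_hwe),
                                 n_removed_maf = sum(fail_maf),
                                 n_kept = sum(keep))
  out
}

#' Prepare the CRP phenotype for analysis
#'
#' Convenience wrapper chaining [transform_crp()] and [filter_outliers()]:
#' low-sensitivity imputation, log(x + 0.01) transform, then the
#' median +/- 4 SD exclusion on the log scale (applied after imputation).
#'
#' @param pheno Phenotype table with \code{crp_mg_per_l}, \code{assay} and
#'   optionally \code{below_detection} columns.
#' @return The table with \code{log_crp}, \code{imputed_low_sens} and
#'   \code{included} columns appended.
#' @export
prepare_phenotype <- function(pheno) {
  tc <- transform_crp(pheno$crp_mg_per_l, pheno$assay,
                      pheno$below_detection)
  pheno$log_crp <- tc$log_crp
  pheno$imputed_low_sens <- tc$imputed_low_sens
  pheno$included <- as.logical(filter_outliers(pheno$log_crp))
  pheno
}
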