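#' @importFrom glmnet cv.glmnet
NULL

new_weights <- function(method, intercept, probe_ids, weights, means, sds,
                        provenance = list()) {
  keep <- weights != 0
  obj <- list(method = method, intercept = intercept,
              probe_ids = probe_ids[keep], weights = weights[keep],
              training_means = means[keep], training_sds = sds[keep],
              n_probes = sum(keep), provenance = provenance)
  class(obj) <- "predictor_weights"
  obj
}

#' Train an elastic-net DNAm predictor of log CRP
#'
#' Fits a penalized linear model over standardised probe beta-values with
#' mixing parameter \code{alpha} (default 0.5) and k-fold cross-validation
#' (default 20 folds, seeded fold assignment); the lambda minimising the
#' mean cross-validated error is selected. Nonzero standardised
#' coefficients are back-transformed to the raw beta scale
#' (w_raw = w_std / sd_train) with the intercept adjusted, so projection is
#' a plain weighted sum of betas.
#'
#' @param meth A \code{meth_set} (training cohort).
#' @param y log CRP values aligned to the methylation rows.
#' @param alpha Elastic-net mixing parameter.
#' @param n_folds Number of CV folds.
#' @param seed Seed for fold assignment.
#' @param probe_subset Optional probe ids restricting the training universe
#'   (e.g. the sites common to all arrays in a multi-cohort design).
#' @param extra_features Optional samples x k matrix of non-CpG candidate
#'   features (e.g. lifestyle covariates); selected ones are reported in the
#'   provenance, not in the probe weight map.
#' @return A \code{predictor_weights} object.
#' @export
train_elastic_net <- function(meth, y, alpha = 0.5, n_folds = 20, seed = 1,
                              probe_subset = NULL, extra_features = NULL) {
  B <- meth$beta
  if (!is.null(probe_subset)) {
    keep <- meth$probe_ids %in% probe_subset
    B <- B[, keep, drop = FALSE]
  }
  n <- nrow(B)
  if (n < n_folds) stop("fewer samples than CV folds")
  mu <- colMeans(B)
  sds <- apply(B, 2, stats::sd)
  ok <- sds > 0
  Z <- scale_cols(B[, ok, drop = FALSE])
  n_extra <- 0L
  if (!is.null(extra_features)) {
    Xe <- scale_cols(as.matrix(extra_features))
    n_extra <- ncol(Xe)
    Z <- cbind(Z, Xe)
  }
  set.seed(seed)
  foldid <- sample(rep_len(seq_len(n_folds), n))
  cv <- glmnet::cv.glmnet(Z, y, alpha = alpha, foldid = foldid,
                          standardize = FALSE)
  cf <- as.numeric(stats::coef(cv, s = "lambda.min"))
  a0 <- cf[1]
  w_std <- cf[-1]
  probe_w_std <- if (n_extra) utils::head(w_std, -n_extra) else w_std
  extra_w <- if (n_extra) utils::tail(w_std, n_extra) else numeric(0)
  w_raw <- probe_w_std / sds[ok]
  intercept <- a0 - sum(w_raw * mu[ok])
  new_weights("elnet", intercept, colnames(B)[ok], w_raw, mu[ok], sds[ok],
              provenance = list(alpha = alpha, n_folds = n_folds,
                                seed = seed, lambda = cv$lambda.min,
                                extra_feature_weights = extra_w,
                                n_candidate_probes = sum(ok)))
}

#' Train a PCA + elastic-net DNAm predictor
#'
#' Truncates the training probes to those significant in an external EWAS
#' reference at \code{p_threshold}, mean-centres (but does not scale) them,
#' applies PCA retaining all components of nonzero variance, fits an
#' elastic net on the component scores with the same CV protocol as
#' [train_elastic_net()], and composes the final weights back to CpG space
#' (w = L c, intercept = a - mu' w) so projection needs only raw betas.
#'
#' @param meth Training \code{meth_set}.
#' @param y log CRP values.
#' @param prefilter Data frame with \code{probe_id} and \code{p} columns
#'   (external EWAS summary table).
#' @param p_threshold Pre-filter significance threshold (default 1e-7).
#' @param alpha,n_folds,seed As in [train_elastic_net()].
#' @return A \code{predictor_weights} object.
#' @export
train_pca_elnet <- function(meth, y, prefilter, p_threshold = 1e-7,
                            alpha = 0.5, n_folds = 20, seed = 1) {
  sel <- prefilter$probe_id[prefilter$p < p_threshold]
  keep <- meth$probe_ids %in% sel
  if (sum(keep) < 2) stop("fewer than 2 pre-filtered probes in training data")
  B <- meth$beta[, keep, drop = FALSE]
  mu <- colMeans(B)
  pc <- stats::prcomp(B, center = TRUE, scale. = FALSE)
  nz <- pc$sdev > 1e-10
  L <- pc$rotation[, nz, drop = FALSE]
  S <- pc$x[, nz, drop = FALSE]
  set.seed(seed)
  foldid <- sample(rep_len(seq_len(n_folds), nrow(B)))
  cv <- glmnet::cv.glmnet(S, y, alpha = alpha, foldid = foldid)
  cf <- as.numeric(stats::coef(cv, s = "lambda.min"))
  a0 <- cf[1]
  comp_w <- cf[-1]
  w <- drop(L %*% comp_w)
  intercept <- a0 - sum(mu * w)
  new_weights("pca_elnet", intercept, colnames(B), w, mu,
              apply(B, 2, stats::sd),
              provenance = list(p_threshold = p_threshold, alpha = alpha,
                                n_folds = n_folds, seed = seed,
                                lambda = cv$lambda.min,
                                n_prefiltered = sum(keep),
                                n_components = sum(nz)))
}

#' EWAS-weight score (methylation risk score)
#'
#' Builds the classical additive score: the weights are the per-probe EWAS
#' effect sizes of probes passing the p-value threshold, with intercept 0.
#' Analogous to a polygenic score on CpG sites.
#'
#' @param ewas An \code{ewas_result} or external summary table with
#'   \code{probe_id}, \code{effect} and \code{p} columns.
#' @param p_threshold Inclusion threshold.
#' @param training_means Optional named vector of training probe means
#'   (enables the mean-imputation projection policy).
#' @return A \code{predictor_weights} object.
#' @export
ewas_weight_score <- function(ewas, p_threshold = 3.6e-8,
                              training_means = NULL) {
  pass <- ewas$p < p_threshold & ewas$effect != 0
  if (!any(pass)) stop("no probes pass the threshold")
  ids <- ewas$probe_id[pass]
  mns <- if (is.null(training_means)) rep(NA_real_, length(ids))
         else unname(training_means[ids])
  new_weights("ewas_ref", 0, ids, ewas$effect[pass], mns,
              rep(NA_real_, length(ids)),
              provenance = list(p_threshold = p_threshold,
                                n_passing = sum(pass)))
}

#' DNAm predictor from posterior-mean mixture effects
#'
#' Takes the posterior mean effect of every methylation feature over the
#' pooled draws of a mixture fit run on scaled-but-unadjusted data, and
#' back-transforms to the raw beta scale using the training means/SDs (and
#' the phenotype's training centre/scale).
#'
#' @param post A \code{mixture_posterior} fitted to standardised betas.
#' @param training_means,training_sds Named per-probe training statistics.
#' @param y_center,y_scale Centre and scale applied to the phenotype before
#'   the fit.
#' @return A \code{predictor_weights} object.
#' @export
bayes_weights <- function(post, training_means, training_sds,
                          y_center = 0, y_scale = 1) {
  idx <- post$class_id == 0L
  feats <- post$feature_names[idx]
  if (!all(feats %in% names(training_sds)))
    stop("posterior features missing from the training sd table")
  b_std <- rowMeans(post$beta[idx, , drop = FALSE])
  sds <- unname(training_sds[feats])
  mns <- unname(training_means[feats])
  w_raw <- b_std * y_scale / sds
  intercept <- y_center - sum(w_raw * mns)
  new_weights("bayes", intercept, feats, w_raw, mns, sds,
              provenance = list(n_draws = ncol(post$beta),
                                y_center = y_center, y_scale = y_scale))
}

#' Project predictor weights onto a cohort's methylation data
#'
#' Computes score_i = intercept + sum over present probes of
#' w_j * beta_ij. Probes absent from the cohort are omitted from the sum
#' (default) or replaced by their training means (\code{mean_impute}). An
#' error is raised when fewer than \code{min_present} of the weight probes
#' are available.
#'
#' @param weights A \code{predictor_weights}.
#' @param meth A \code{meth_set}.
#' @param missing_policy \code{"omit"} or \code{"mean_impute"}.
#' @param min_present Minimum fraction of weight probes that must be
#'   present.
#' @return Data frame: sample_id, score, n_probes_used, frac_missing.
#' @export
project_score <- function(weights, meth,
                          missing_policy = c("omit", "mean_impute"),
                          min_present = 0.5) {
  missing_policy <- match.arg(missing_policy)
  idx <- match(weights$probe_ids, meth$probe_ids)
  present <- !is.na(idx)
  frac_missing <- mean(!present)
  if (weights$n_probes > 0 && mean(present) < min_present)
    stop(sprintf("only %.1f%% of weight probes present (floor %.0f%%)",
                 100 * mean(present), 100 * min_present))
  n <- length(meth$sample_ids)
  score <- rep(weights$intercept, n)
  if (any(present))
    score <- score + drop(meth$beta[, idx[present], drop = FALSE] %*%
                            weights$weights[present])
  if (missing_policy == "mean_impute" && any(!present)) {
    mns <- weights$training_means[!present]
    if (anyNA(mns)) stop("mean_impute requires training means")
    score <- score + sum(weights$weights[!present] * mns)
  }
  data.frame(sample_id = meth$sample_ids, score = score,
             n_probes_used = sum(present), frac_missing = frac_missing,
             stringsAsFactors = FALSE)
}

#' Write predictor weights as a portable TSV
#'
#' Header block (\code{#key\tvalue} lines: method, intercept, n_probes)
#' followed by probe_id / weight / mean / sd rows at full double precision,
#' so a round-trip through [read_weights()] is bit-exact.
#'
#' @param weights A \code{predictor_weights}.
#' @param path Output file.
#' @export
write_weights <- function(weights, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#method\t%s", weights$method),
               sprintf("#intercept\t%s",
                       formatC(weights$intercept, digits = 17,
                               format = "g")),
               sprintf("#n_probes\t%d", weights$n_probes),
               "probe_id\tweight\tmean\tsd"), con)
  if (weights$n_probes > 0) {
    fmt <- function(x) formatC(x, digits = 17, format = "g")
    writeLines(paste(weights$probe_ids, fmt(weights$weights),
                     fmt(weights$training_means),
                     fmt(weights$training_sds), sep = "\t"), con)
  }
  invisible(path)
}

#' Read predictor weights written by [write_weights()]
#'
#' @param path Weight TSV file.
#' @return A \code{predictor_weights}.
#' @export
read_weights <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  kv <- do.call(rbind, strsplit(sub("^#", "", hdr), "\t"))
  meta <- stats::setNames(kv[, 2], kv[, 1])
  body <- utils::read.table(path, header = TRUE, sep = "\t",
                            comment.char = "#",
                            colClasses = c("character", "numeric",
                                           "numeric", "numeric"))
  new_weights(meta[["method"]], as.numeric(meta[["intercept"]]),
              body$probe_id, body$weight, body$mean, body$sd)
}
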