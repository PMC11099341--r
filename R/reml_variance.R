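#' Build an omics or genomic relationship matrix
#'
#' Computes A = Z Z' / m from column-standardised features. For an ORM
#' (methylation or other omics), columns are standardised to mean zero and
#' unit variance. For a GRM, dosages are centred at twice the allele
#' frequency and scaled by sqrt(2 p (1 - p)) when \code{maf} is supplied;
#' otherwise plain column standardisation is used. Zero-variance features
#' are dropped with a warning.
#'
#' @param features Samples x features matrix (betas, residuals or dosages).
#' @param kind \code{"ORM"} or \code{"GRM"}.
#' @param maf Optional per-feature allele frequencies for GRM scaling.
#' @return A list of class \code{rel_matrix}: \code{values} (n x n),
#'   \code{kind}, \code{n_features}, \code{sample_ids}.
#' @export
build_relationship_matrix <- function(features, kind = c("ORM", "GRM"),
                                      maf = NULL) {
  kind <- match.arg(kind)
  M <- as.matrix(features)
  if (ncol(M) < 1) stop("need at least one feature")
  if (kind == "GRM" && !is.null(maf)) {
    keep <- maf > 0 & maf < 1
    if (!all(keep)) {
      warning(sum(!keep), " zero-variance feature(s) dropped")
      M <- M[, keep, drop = FALSE]; maf <- maf[keep]
    }
    Z <- sweep(sweep(M, 2, 2 * maf), 2, sqrt(2 * maf * (1 - maf)), "/")
  } else {
    sds <- apply(M, 2, stats::sd)
    keep <- sds > 0
    if (!all(keep)) {
      warning(sum(!keep), " zero-variance feature(s) dropped")
      M <- M[, keep, drop = FALSE]
    }
    Z <- scale_cols(M)
  }
  A <- tcrossprod(Z) / ncol(Z)
  structure(list(kind = kind, values = A, n_features = ncol(Z),
                 sample_ids = rownames(M)), class = "rel_matrix")
}

#' Prune related samples from a GRM
#'
#' Greedy removal: while any off-diagonal relatedness exceeds the cutoff,
#' the sample involved in the most such pairs is removed (ties broken by
#' index). Mirrors the usual relatedness-cutoff semantics of genetic
#' relationship matrices (individual pruning, not matrix sparsification).
#'
#' @param grm A \code{rel_matrix}.
#' @param cutoff Relatedness threshold (> 0).
#' @return Integer vector of retained sample indices; removed indices are
#'   attached as attribute \code{removed}.
#' @export
prune_related <- function(grm, cutoff = 0.05) {
  if (cutoff <= 0) stop("cutoff must be positive")
  A <- grm$values
  n <- nrow(A)
  active <- rep(TRUE, n)
  rel <- abs(A) > cutoff
  diag(rel) <- FALSE
  removed <- integer(0)
  repeat {
    deg <- rowSums(rel[active, active, drop = FALSE])
    if (!length(deg) || max(deg) == 0) break
    victim <- which(active)[which.max(deg)]
    active[victim] <- FALSE
    removed <- c(removed, victim)
  }
  keep <- which(active)
  attr(keep, "removed") <- removed
  keep
}

#' REML variance components with relationship-matrix random effects
#'
#' Fits y = Xb + g_1 (+ g_2) + e with Var(g_c) = theta_c A_c and
#' Var(e) = theta_e I by average-information REML with EM fallback steps and
#' variance floors at 1e-6. Reports each component's fraction of the total
#' variance with a standard-error-based 95\% confidence interval (delta
#' method, truncated to \[0, 1\]). The restricted likelihood is monitored
#' and returned; steps that would decrease it fall back to EM.
#'
#' @param y Phenotype vector (typically residualized and standardised
#'   upstream, matching the Bayesian pipeline).
#' @param covariates Optional covariate data frame/matrix (an intercept is
#'   always included).
#' @param matrices A \code{rel_matrix} or list of one or two of them.
#' @param max_iter,tol Convergence controls on the likelihood change.
#' @return Data frame with one row per component (plus residual): estimate
#'   (fraction), interval bounds, SE, method tag, conditioning set;
#'   attributes \code{converged}, \code{loglik_trace}, \code{theta}.
#' @export
reml_fit <- function(y, covariates = NULL, matrices, max_iter = 50,
                     tol = 1e-6) {
  if (inherits(matrices, "rel_matrix")) matrices <- list(matrices)
  A_list <- lapply(matrices, function(mm) {
    if (!inherits(mm, "rel_matrix")) stop("matrices must be rel_matrix")
    if (max(abs(mm$values - t(mm$values))) > 1e-10)
      stop("relationship matrix is not symmetric")
    mm$values
  })
  kinds <- vapply(matrices, `[[`, "", "kind")
  n <- length(y)
  X <- if (is.null(covariates)) matrix(1, n, 1)
       else build_design(covariates)
  nA <- length(A_list)
  vy <- stats::var(y)
  theta <- rep(vy / (nA + 1), nA + 1)  # components then residual

  make_V <- function(theta) {
    V <- diag(theta[nA + 1], n)
    for (i in seq_len(nA)) V <- V + theta[i] * A_list[[i]]
    V
  }
  loglik_P <- function(theta) {
    V <- make_V(theta)
    cv <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(cv)) return(list(ll = -Inf))
    Vi <- chol2inv(cv)
    XtViX <- crossprod(X, Vi %*% X)
    cx <- chol(XtViX)
    B <- Vi %*% X
    P <- Vi - B %*% chol2inv(cx) %*% t(B)
    Py <- P %*% y
    ll <- -0.5 * (2 * sum(log(diag(cv))) + 2 * sum(log(diag(cx))) +
                    drop(crossprod(y, Py)))
    list(ll = ll, P = P, Py = Py)
  }

  st <- loglik_P(theta)
  ll_trace <- st$ll
  converged <- FALSE
  AI <- NULL
  for (it in seq_len(max_iter)) {
    P <- st$P; Py <- st$Py
    APy <- vector("list", nA + 1)
    for (i in seq_len(nA)) APy[[i]] <- A_list[[i]] %*% Py
    APy[[nA + 1]] <- Py
    score <- numeric(nA + 1)
    for (i in seq_len(nA))
      score[i] <- -0.5 * (sum(P * A_list[[i]]) -
                            drop(crossprod(Py, APy[[i]])))
    score[nA + 1] <- -0.5 * (sum(diag(P)) - drop(crossprod(Py, Py)))
    AI <- matrix(0, nA + 1, nA + 1)
    PAPy <- lapply(APy, function(v) P %*% v)
    for (i in seq_len(nA + 1))
      for (j in i:(nA + 1))
        AI[i, j] <- AI[j, i] <- 0.5 * drop(crossprod(APy[[i]], PAPy[[j]]))
    step <- tryCatch(solve(AI, score), error = function(e) NULL)
    new_theta <- if (is.null(step)) NULL else pmax(theta + step, 1e-6)
    new_st <- if (is.null(new_theta)) list(ll = -Inf)
              else loglik_P(new_theta)
    if (new_st$ll < st$ll - 1e-8 || !is.finite(new_st$ll)) {
      # EM fallback keeps the likelihood non-decreasing
      em <- theta
      for (i in seq_len(nA))
        em[i] <- pmax(theta[i] + theta[i]^2 *
                        (drop(crossprod(Py, APy[[i]])) -
                           sum(P * A_list[[i]])) / n, 1e-6)
      em[nA + 1] <- pmax(theta[nA + 1] + theta[nA + 1]^2 *
                           (drop(crossprod(Py, Py)) - sum(diag(P))) / n,
                         1e-6)
      new_theta <- em
      new_st <- loglik_P(new_theta)
      if (new_st$ll < st$ll - 1e-8) break
    }
    delta <- abs(new_st$ll - st$ll)
    theta <- new_theta; st <- new_st
    ll_trace <- c(ll_trace, st$ll)
    if (delta < tol) { converged <- TRUE; break }
  }

  tot <- sum(theta)
  frac <- theta / tot
  # delta-method SEs of fractions from the inverse AI matrix
  covth <- tryCatch(solve(AI), error = function(e)
    matrix(NA_real_, nA + 1, nA + 1))
  se_frac <- vapply(seq_len(nA + 1), function(i) {
    g <- -theta / tot^2
    g[i] <- g[i] + 1 / tot
    sqrt(max(0, drop(t(g) %*% covth %*% g)))
  }, 0)
  comp_names <- c(ifelse(kinds == "ORM", "methylation", "genetic"),
                  "residual")
  out <- data.frame(component = comp_names, estimate = frac,
                    lower = pmax(0, frac - 1.96 * se_frac),
                    upper = pmin(1, frac + 1.96 * se_frac),
                    se = se_frac, method = "reml",
                    conditioning = vapply(seq_len(nA + 1), function(i)
                      paste(comp_names[setdiff(seq_len(nA), i)],
                            collapse = "+"), ""),
                    stringsAsFactors = FALSE)
  attr(out, "converged") <- converged
  attr(out, "loglik_trace") <- ll_trace
  attr(out, "theta") <- theta
  out
}
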