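#' Configuration for the Bayesian mixture regression
#'
#' Defaults follow the published analysis: prior mixture variances of 0.001,
#' 0.01 and 0.1 (features capturing 0.1\%, 1\% and 10\% of the variance of
#' the standardised phenotype), 10,000 Gibbs iterations with 5,000 burn-in,
#' thinning of 5 (leaving 1,000 retained draws per chain), four chains with
#' distinct seeds, and the final 250 retained draws of each chain pooled for
#' inference (1,000 pooled draws).
#'
#' @param mixture_variances Strictly increasing positive component variances
#'   as fractions of the phenotypic variance.
#' @param n_iter,burn_in,thinning Gibbs schedule.
#' @param n_chains Number of independent chains.
#' @param final_per_chain Retained draws per chain entering the pooled
#'   posterior (taken from the end of each chain's thinned stream).
#' @param seeds Optional integer vector of per-chain seeds.
#' @param fix_sigma2e Optional fixed residual variance (sampled when
#'   \code{NULL}); used for conjugate checks.
#' @param fix_pi Optional fixed mixture proportions (length
#'   \code{length(mixture_variances) + 1}, spike first) instead of the
#'   Dirichlet update; e.g. \code{c(0, 1)} with a single mixture variance
#'   gives a slab-only prior for conjugate checks.
#' @param dirichlet_alpha Concentration of the symmetric Dirichlet prior on
#'   the mixture proportions. The default 0.1 encourages sparsity, which
#'   keeps null features out of the model at the moderate feature counts
#'   this package simulates; at epigenome scale the choice is immaterial.
#' @return An object of class \code{mixture_config}.
#' @export
mixture_config <- function(mixture_variances = c(0.001, 0.01, 0.1),
                           n_iter = 10000, burn_in = 5000, thinning = 5,
                           n_chains = 4, final_per_chain = 250,
                           seeds = NULL, fix_sigma2e = NULL,
                           fix_pi = NULL, dirichlet_alpha = 0.1) {
  if (any(diff(mixture_variances) <= 0) || any(mixture_variances <= 0))
    stop("mixture variances must be strictly increasing and positive")
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter")
  n_kept <- (n_iter - burn_in) %/% thinning
  if (n_kept < final_per_chain)
    stop("(n_iter - burn_in)/thinning must be >= final_per_chain")
  if (is.null(seeds)) seeds <- seq_len(n_chains) * 1000L + 7L
  stopifnot(length(seeds) == n_chains)
  if (!is.null(fix_pi)) {
    stopifnot(length(fix_pi) == length(mixture_variances) + 1,
              all(fix_pi >= 0), abs(sum(fix_pi) - 1) < 1e-9)
  }
  structure(list(mixture_variances = mixture_variances, n_iter = n_iter,
                 burn_in = burn_in, thinning = thinning,
                 n_chains = n_chains, final_per_chain = final_per_chain,
                 kept_per_chain = n_kept, seeds = as.integer(seeds),
                 fix_sigma2e = fix_sigma2e, fix_pi = fix_pi,
                 dirichlet_alpha = dirichlet_alpha),
            class = "mixture_config")
}

#' Reduced ("desk-scale") mixture configuration
#'
#' A smaller Gibbs schedule (1,000 iterations, 500 burn-in, thinning 2, two
#' chains, 250 pooled draws per chain) for analyses that must run in
#' minutes. Inference quality at the simulated problem sizes is documented
#' in the methods vignette.
#'
#' @param ... Overrides passed to [mixture_config()].
#' @export
desk_mixture_config <- function(...) {
  args <- list(n_iter = 1000, burn_in = 500, thinning = 2, n_chains = 2,
               final_per_chain = 250)
  args[names(list(...))] <- list(...)
  do.call(mixture_config, args)
}

#' Fit the spike-plus-Gaussian-mixture regression by Gibbs sampling
#'
#' Runs the mixture regression of a standardised phenotype on one or two
#' standardised feature classes (e.g. methylation probes, SNP dosages). Per
#' sweep, every feature is assigned to the null spike or one of the Gaussian
#' components (variances fixed at \code{mixture_variances}, i.e. fractions
#' of the unit phenotypic variance), its effect is drawn from the conjugate
#' conditional, mixture proportions get a sparsity-encouraging Dirichlet
#' update per class, and the residual variance a
#' scaled-inverse-chi-square update. Feature
#' update order is randomised each sweep. Chains are run with independent
#' seeds; the final \code{final_per_chain} thinned post-burn-in draws of
#' each chain are pooled.
#'
#' @param X_classes A standardised feature matrix, or a named list of one or
#'   two such matrices (feature classes).
#' @param y Standardised phenotype vector.
#' @param config A [mixture_config()].
#' @return An object of class \code{mixture_posterior} with pooled draws:
#'   \code{beta} (features x draws, standardised scale), \code{comp}
#'   (component labels, 0 = spike), \code{sigma2e}, \code{pi} (per class),
#'   plus feature names, class assignment and chain provenance.
#' @export
gibbs_fit <- function(X_classes, y, config = mixture_config()) {
  stopifnot(inherits(config, "mixture_config"))
  if (is.matrix(X_classes)) X_classes <- list(meth = X_classes)
  if (length(X_classes) > 2) stop("at most two feature classes supported")
  if (is.null(names(X_classes)))
    names(X_classes) <- c("methylation", "genetic")[seq_along(X_classes)]
  check_std <- function(M, what) {
    mu <- colMeans(M); v <- apply(M, 2, stats::var)
    if (max(abs(mu)) > 1e-6 || max(abs(v - 1)) > 1e-3)
      stop(what, " must be standardized to mean 0, variance 1")
  }
  if (abs(mean(y)) > 1e-6 || abs(stats::var(y) - 1) > 1e-3)
    stop("y must be standardized to mean 0, variance 1")
  for (nm in names(X_classes)) check_std(X_classes[[nm]], nm)
  X <- do.call(cbind, X_classes)
  class_id <- rep(seq_along(X_classes) - 1L,
                  vapply(X_classes, ncol, 1L))
  feature_names <- unlist(lapply(X_classes, colnames), use.names = FALSE)
  if (is.null(feature_names)) feature_names <- paste0("f", seq_len(ncol(X)))
  mix_list <- rep(list(config$mixture_variances), length(X_classes))
  fs <- if (is.null(config$fix_sigma2e)) -1 else config$fix_sigma2e
  fp <- if (is.null(config$fix_pi)) numeric(0) else config$fix_pi

  keep_idx <- seq(config$kept_per_chain - config$final_per_chain + 1L,
                  config$kept_per_chain)
  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seeds[ch])
    fit <- .gibbs_chain(X, y, class_id, mix_list,
                        as.integer(config$n_iter),
                        as.integer(config$burn_in),
                        as.integer(config$thinning),
                        fs, fp, config$dirichlet_alpha, 2.0, 1.0)
    chains[[ch]] <- list(beta = fit$beta[, keep_idx, drop = FALSE],
                         comp = fit$comp[, keep_idx, drop = FALSE],
                         sigma2e = fit$sigma2e[keep_idx],
                         pi = lapply(fit$pi, function(m)
                           m[, keep_idx, drop = FALSE]))
  }
  post <- list(beta = do.call(cbind, lapply(chains, `[[`, "beta")),
               comp = do.call(cbind, lapply(chains, `[[`, "comp")),
               sigma2e = unlist(lapply(chains, `[[`, "sigma2e")),
               pi = lapply(seq_along(X_classes), function(c)
                 do.call(cbind, lapply(chains, function(x) x$pi[[c]]))),
               feature_names = feature_names,
               class_id = class_id,
               class_names = names(X_classes),
               chain = rep(seq_len(config$n_chains),
                           each = config$final_per_chain),
               config = config)
  rownames(post$beta) <- rownames(post$comp) <- feature_names
  class(post) <- "mixture_posterior"
  post
}

#' Posterior inclusion probabilities
#'
#' The PIP of a feature is the fraction of pooled draws in which it is
#' assigned to any nonzero-effect component (small, medium or large), i.e.
#' not to the spike.
#'
#' @param post A \code{mixture_posterior}.
#' @return Named numeric vector of PIPs.
#' @export
compute_pip <- function(post) {
  stopifnot(inherits(post, "mixture_posterior"))
  stats::setNames(rowMeans(post$comp != 0L), post$feature_names)
}

#' Group correlated nearby probes around lead probes
#'
#' Mixture regression may spread inclusion across a correlated block,
#' diluting individual PIPs. Probes with PIP above \code{lead_pip} seed
#' groups in descending PIP order (ties broken by genomic position); each
#' group collects still-unassigned probes on the same chromosome within
#' \code{dist_bp} of the lead and with absolute Pearson correlation above
#' \code{corr} with the lead. The group PIP is the fraction of draws in
#' which at least one member is included; groups exceeding
#' \code{group_pip_thresh} are flagged significant. Each group also carries
#' its mean total squared-effect variance contribution.
#'
#' @param post A \code{mixture_posterior} (methylation class).
#' @param meth The \code{meth_set} the model was fitted to (used for probe
#'   annotation and correlations).
#' @param lead_pip PIP threshold seeding lead probes.
#' @param dist_bp Maximum distance from the lead (base pairs).
#' @param corr Minimum absolute correlation with the lead.
#' @param group_pip_thresh Group-level significance threshold.
#' @return Data frame with one row per group: lead probe, members, group
#'   PIP, variance contribution, significance flag.
#' @export
group_probes <- function(post, meth, lead_pip = 0.20, dist_bp = 2500,
                         corr = 0.5, group_pip_thresh = 0.80) {
  pip <- compute_pip(post)
  meth_idx <- post$class_id == 0L
  pip <- pip[meth_idx]
  nz <- post$comp[meth_idx, , drop = FALSE] != 0L
  probe_ids <- post$feature_names[meth_idx]
  ann <- match(probe_ids, meth$probe_ids)
  leads <- which(pip > lead_pip)
  if (!length(leads))
    return(data.frame(lead_probe = character(0), members = character(0),
                      n_members = integer(0), group_pip = numeric(0),
                      variance_contribution = numeric(0),
                      significant = logical(0)))
  if (anyNA(ann[leads]))
    stop("annotation missing for lead probe(s): ",
         paste(probe_ids[leads[is.na(ann[leads])]], collapse = ", "))
  ord <- leads[order(-pip[leads], meth$probe_pos[ann[leads]])]
  assigned <- rep(FALSE, length(pip))
  rows <- list()
  for (ld in ord) {
    if (assigned[ld]) next
    same_chr <- !is.na(ann) & meth$probe_chr[ann] == meth$probe_chr[ann[ld]]
    near <- same_chr & abs(meth$probe_pos[ann] - meth$probe_pos[ann[ld]]) <=
      dist_bp & !assigned
    cand <- which(near)
    if (length(cand) > 1) {
      r <- abs(stats::cor(meth$beta[, ann[ld]],
                          meth$beta[, ann[cand], drop = FALSE]))
      cand <- cand[drop(r) > corr | cand == ld]
    }
    assigned[cand] <- TRUE
    gp <- mean(colSums(nz[cand, , drop = FALSE]) > 0)
    vc <- mean(colSums(post$beta[meth_idx, , drop = FALSE][cand, ,
                                                           drop = FALSE]^2))
    rows[[length(rows) + 1L]] <-
      data.frame(lead_probe = probe_ids[ld],
                 members = paste(probe_ids[cand], collapse = ";"),
                 n_members = length(cand), group_pip = gp,
                 variance_contribution = vc,
                 significant = gp > group_pip_thresh,
                 stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Bayesian variance partition from pooled mixture draws
#'
#' For each feature class, the per-draw explained variance is the sum of
#' squared standardised effects over the class; the point estimate is the
#' mean over pooled draws and the 95\% credible interval is read off the
#' sorted draws at ascending ranks \code{ceiling(0.025 T)} and
#' \code{floor(0.975 T)} (ranks 25 and 975 when T = 1,000). In a joint
#' two-class fit each class's estimate is conditional on the other.
#'
#' @param post A \code{mixture_posterior}.
#' @return Data frame with component, estimate, interval bounds, method and
#'   conditioning set.
#' @export
variance_partition <- function(post) {
  stopifnot(inherits(post, "mixture_posterior"))
  T_draws <- ncol(post$beta)
  if (T_draws < 100) warning("fewer than 100 pooled draws; interval unstable")
  lo_rank <- max(1L, ceiling(0.025 * T_draws))
  hi_rank <- floor(0.975 * T_draws)
  out <- lapply(seq_along(post$class_names), function(c) {
    idx <- post$class_id == (c - 1L)
    v <- colSums(post$beta[idx, , drop = FALSE]^2)
    sv <- sort(v)
    data.frame(component = post$class_names[c], estimate = mean(v),
               lower = sv[lo_rank], upper = sv[hi_rank], method = "bayes",
               conditioning = paste(post$class_names[-c], collapse = "+"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
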