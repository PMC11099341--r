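test_that("configuration enforces the retention bookkeeping", {
  cfg <- mixture_config()
  expect_equal(cfg$kept_per_chain, 1000)        # (10000-5000)/5
  expect_equal(cfg$n_chains * cfg$final_per_chain, 1000)
  expect_error(mixture_config(burn_in = 10000), "burn_in")
  expect_error(mixture_config(final_per_chain = 1001),
               "final_per_chain")
  expect_error(mixture_config(mixture_variances = c(0.1, 0.01)),
               "strictly increasing")
})

test_that("pooled draw count equals chains times final retention", {
  set.seed(211)
  n <- 60
  X <- scale(matrix(rnorm(n * 4), n, 4))
  attr(X, "scaled:center") <- attr(X, "scaled:scale") <- NULL
  colnames(X) <- paste0("f", 1:4)
  y <- as.numeric(scale(rnorm(n)))
  post <- gibbs_fit(X, y, mixture_config())  # full published schedule
  expect_equal(ncol(post$beta), 1000)
  expect_equal(table(post$chain), table(rep(1:4, each = 250)),
               ignore_attr = TRUE)
})

test_that("non-standardized inputs are rejected", {
  n <- 50
  X <- matrix(rnorm(n * 3, mean = 2), n, 3)
  y <- as.numeric(scale(rnorm(n)))
  expect_error(gibbs_fit(X, y, desk_mixture_config()), "standardized")
  Xs <- scale(X)
  expect_error(gibbs_fit(Xs * 3, y, desk_mixture_config()), "standardized")
  expect_error(gibbs_fit(Xs, y * 2, desk_mixture_config()), "standardized")
})

test_that("null data give near-zero variance estimates and low PIPs", {
  set.seed(223)
  n <- 500; m <- 200
  X <- scale(matrix(rnorm(n * m), n, m))
  colnames(X) <- paste0("f", 1:m)
  y <- as.numeric(scale(rnorm(n)))
  post <- gibbs_fit(X, y, desk_mixture_config())
  vp <- variance_partition(post)
  expect_lt(vp$estimate, 0.05)
  expect_lt(max(compute_pip(post)), 0.2)
})

test_that("slab-only single-predictor posterior matches the conjugate form", {
  set.seed(227)
  n <- 300
  x <- as.numeric(scale(rnorm(n)))
  y <- as.numeric(scale(0.3 * x + rnorm(n)))
  X <- matrix(x, ncol = 1, dimnames = list(NULL, "f1"))
  v <- 0.5; s2e <- 1
  cfg <- mixture_config(mixture_variances = v, n_iter = 4000,
                        burn_in = 1000, thinning = 1, n_chains = 2,
                        final_per_chain = 1500, fix_sigma2e = s2e,
                        fix_pi = c(0, 1))
  post <- gibbs_fit(X, y, cfg)
  # conjugate normal posterior for a single standardized predictor
  xtx <- sum(x^2); rhs <- sum(x * y)
  mu <- rhs / (xtx + s2e / v)
  sd_post <- sqrt(s2e / (xtx + s2e / v))
  mcse <- sd(post$beta) / sqrt(ncol(post$beta))
  expect_lt(abs(mean(post$beta) - mu), 3 * mcse)
  expect_equal(sd(post$beta), sd_post, tolerance = 0.1)
})

test_that("PIP counts nonzero-component draws", {
  beta <- rbind(c(rep(0.2, 600), rep(0, 400)), rep(0, 1000))
  post <- fake_posterior(beta)
  pip <- compute_pip(post)
  expect_equal(unname(pip), c(0.6, 0))
})

test_that("a strong causal feature earns a high PIP", {
  set.seed(229)
  n <- 1000; m <- 100
  X <- scale(matrix(rnorm(n * m), n, m))
  colnames(X) <- paste0("f", 1:m)
  y0 <- sqrt(0.05) * X[, 7] + rnorm(n, 0, sqrt(0.95))
  y <- as.numeric(scale(y0))
  post <- gibbs_fit(X, y, desk_mixture_config())
  expect_gt(compute_pip(post)[7], 0.8)
})

test_that("variance partition follows the rank rule for intervals", {
  set.seed(233)
  T_ <- 1000
  v_draw <- runif(T_)
  beta <- matrix(sqrt(v_draw), nrow = 1)  # single feature, V(t) = v_draw
  post <- fake_posterior(beta, comp = matrix(1L, 1, T_))
  vp <- variance_partition(post)
  sv <- sort(v_draw)
  expect_equal(vp$estimate, mean(v_draw))
  expect_equal(vp$lower, sv[25])    # ceiling(0.025*1000)
  expect_equal(vp$upper, sv[975])   # floor(0.975*1000)
  # degenerate cases
  zero <- fake_posterior(matrix(0, 2, 200))
  vpz <- suppressWarnings(variance_partition(zero))
  expect_equal(c(vpz$estimate, vpz$lower, vpz$upper), c(0, 0, 0))
  const <- fake_posterior(matrix(0.1, 1, 200))
  expect_equal(variance_partition(const)$estimate, 0.01)
})

test_that("probe grouping follows the distance, correlation and union rules", {
  set.seed(239)
  n <- 200; T_ <- 1000
  a <- rnorm(n)
  b <- 0.9 * a + sqrt(1 - 0.81) * rnorm(n)   # |r| > 0.5 with a
  cc <- 0.95 * a + sqrt(1 - 0.9) * rnorm(n)  # correlated but far away
  B <- cbind(A = plogis(a), B = plogis(b), C = plogis(cc))
  rownames(B) <- paste0("s", 1:n)
  meth <- fake_meth(B, pos = c(100L, 1500L, 10000L))
  comp <- rbind(A = c(rep(1L, 500), rep(0L, 500)),
                B = c(rep(0L, 400), rep(1L, 500), rep(0L, 100)),
                C = rep(0L, T_))
  beta <- comp * 0.1
  post <- fake_posterior(beta, comp = comp, feature_names = c("A", "B", "C"))
  gr <- group_probes(post, meth)
  expect_equal(nrow(gr), 1)              # C has PIP 0, never a lead
  expect_equal(gr$lead_probe, "A")
  expect_setequal(strsplit(gr$members, ";")[[1]], c("A", "B"))
  # A nonzero in draws 1-500, B in 401-900: union covers 900 of 1000
  expect_equal(gr$group_pip, 0.90)
  expect_true(gr$significant)
})

test_that("a lead with no neighbours forms a singleton group", {
  set.seed(241)
  B <- matrix(plogis(rnorm(300)), 100, 3,
              dimnames = list(paste0("s", 1:100), c("A", "B", "C")))
  meth <- fake_meth(B, pos = c(100L, 50000L, 100000L))
  comp <- rbind(A = c(rep(1L, 300), rep(0L, 700)),
                B = rep(0L, 1000), C = rep(0L, 1000))
  post <- fake_posterior(comp * 0.1, comp = comp,
                         feature_names = c("A", "B", "C"))
  gr <- group_probes(post, meth)
  expect_equal(gr$n_members, 1)
  expect_equal(gr$group_pip, 0.30)   # equals the lead's own PIP
  expect_false(gr$significant)
})

test_that("group PIP is at least the maximum member PIP", {
  co <- small_cohort(seed = 243, n = 300, m = 120, s = 10)
  adj <- methylcrp:::adjust_for_variance_partition(co)
  post <- gibbs_fit(list(methylation = adj$B), adj$y,
                    desk_mixture_config())
  gr <- group_probes(post, co$meth, lead_pip = 0.1)
  if (nrow(gr) > 0) {
    pip <- compute_pip(post)
    for (i in seq_len(nrow(gr))) {
      members <- strsplit(gr$members[i], ";")[[1]]
      expect_gte(gr$group_pip[i] + 1e-12, max(pip[members]))
    }
  }
  expect_error(group_probes(post, fake_meth(co$meth$beta[, 1:5],
                                            pos = 1:5)),
               "annotation missing")
})

test_that("swapping chain seeds leaves pooled summaries within MC error", {
  co <- small_cohort(seed = 251, n = 400, m = 150, s = 10)
  adj <- methylcrp:::adjust_for_variance_partition(co)
  c1 <- desk_mixture_config(seeds = c(101L, 202L))
  c2 <- desk_mixture_config(seeds = c(202L, 101L))
  p1 <- gibbs_fit(list(methylation = adj$B), adj$y, c1)
  p2 <- gibbs_fit(list(methylation = adj$B), adj$y, c2)
  v1 <- colSums(p1$beta^2); v2 <- colSums(p2$beta^2)
  mcse <- sqrt(var(v1) / length(v1) + var(v2) / length(v2))
  expect_lt(abs(mean(v1) - mean(v2)), 3 * max(mcse, 0.01))
})

test_that("joint two-class estimates match single-class fits when classes
           are independent", {
  co <- small_cohort(seed = 257, n = 600, m = 250, s = 80)
  adj <- methylcrp:::adjust_for_variance_partition(co)
  gq <- qc_genotypes(co$geno)
  G <- methylcrp:::scale_cols(gq$dosage)
  colnames(G) <- gq$snp_ids
  cfg <- desk_mixture_config()
  single_m <- variance_partition(
    gibbs_fit(list(methylation = adj$B), adj$y, cfg))
  single_g <- variance_partition(
    gibbs_fit(list(genetic = G), adj$y, cfg))
  joint <- variance_partition(
    gibbs_fit(list(methylation = adj$B, genetic = G), adj$y, cfg))
  jm <- joint$estimate[joint$component == "methylation"]
  jg <- joint$estimate[joint$component == "genetic"]
  expect_lt(abs(jm - single_m$estimate), 0.05 + 1e-9)
  expect_lt(abs(jg - single_g$estimate), 0.05 + 1e-9)
})
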