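toy_meth <- function(n, m, seed = 1) {
  set.seed(seed)
  B <- matrix(plogis(rnorm(n * m)), n, m,
              dimnames = list(paste0("s", 1:n), sprintf("cg%03d", 1:m)))
  fake_meth(B, pos = seq_len(m) * 10000L)
}

test_that("elastic net recovers a noiseless sparse signal", {
  meth <- toy_meth(500, 40, seed = 401)
  y <- 3 * meth$beta[, 5] - 2 * meth$beta[, 17] + 1.5 * meth$beta[, 33]
  w <- train_elastic_net(meth, y, seed = 2)
  expect_true(all(c("cg005", "cg017", "cg033") %in% w$probe_ids))
  s <- project_score(w, meth)
  expect_gt(cor(s$score, y), 0.99)
})

test_that("elastic net on pure noise has near-zero out-of-sample r", {
  tr <- toy_meth(300, 50, seed = 403)
  te <- toy_meth(300, 50, seed = 404)
  set.seed(405)
  y <- rnorm(300)
  w <- train_elastic_net(tr, y, seed = 3)
  s <- project_score(w, te)
  if (sd(s$score) > 0) {
    set.seed(406)
    y_new <- rnorm(300)
    expect_lt(abs(cor(s$score, y_new)), 3 / sqrt(300))
  } else succeed("null model selected no probes")
})

test_that("glmnet solution matches an independent coordinate-descent oracle", {
  set.seed(407)
  n <- 10; p <- 5
  Z <- scale(matrix(rnorm(n * p), n, p)) * sqrt(n / (n - 1))  # unit 1/n-norm
  y <- rnorm(n)
  lam <- 0.1; alpha <- 0.5
  fit <- glmnet::glmnet(Z, y, alpha = alpha, lambda = lam,
                        standardize = FALSE, intercept = TRUE,
                        thresh = 1e-14)
  # coordinate descent on (1/2n)||y - b0 - Zb||^2 + lam(a|b|_1 + (1-a)/2|b|^2);
  # glmnet standardizes y internally (1/n sd), which leaves the L1 term at
  # lam*a but scales the ridge term by 1/sd(y)
  sy <- sd(y) * sqrt((n - 1) / n)
  b <- rep(0, p); b0 <- mean(y)
  for (it in 1:5000) {
    b0 <- mean(y - Z %*% b)
    for (j in 1:p) {
      r_j <- y - b0 - Z[, -j, drop = FALSE] %*% b[-j]
      rho <- sum(Z[, j] * r_j) / n
      zj2 <- sum(Z[, j]^2) / n
      b[j] <- sign(rho) * max(0, abs(rho) - lam * alpha) /
        (zj2 + lam * (1 - alpha) / sy)
    }
  }
  expect_equal(as.numeric(fit$beta), b, tolerance = 1e-6)
  expect_equal(as.numeric(fit$a0), b0, tolerance = 1e-6)
})

test_that("weights are stored on the raw beta scale", {
  meth <- toy_meth(200, 30, seed = 409)
  y <- 2 * meth$beta[, 3] + rnorm(200, 0, 0.05)
  w <- train_elastic_net(meth, y, seed = 4)
  # projection must equal the standardized-model predictions
  Z <- scale(meth$beta)
  cfg <- w$provenance
  expect_equal(w$n_probes, length(w$weights))
  expect_true(all(w$weights != 0))
  s <- project_score(w, meth)
  expect_gt(cor(s$score, y), 0.9)
})

test_that("PCA + elastic net composes weights back to CpG space exactly", {
  meth <- toy_meth(150, 25, seed = 411)
  set.seed(412)
  y <- drop(scale(meth$beta[, 1:6]) %*% runif(6, -1, 1)) + rnorm(150, 0, 0.3)
  pre <- data.frame(probe_id = meth$probe_ids[1:20],
                    p = rep(1e-9, 20))
  w <- train_pca_elnet(meth, y, pre, p_threshold = 1e-7, seed = 5)
  # identity: composed CpG-space scores equal component-space predictions
  B <- meth$beta[, meth$probe_ids %in% pre$probe_id, drop = FALSE]
  pc <- prcomp(B, center = TRUE, scale. = FALSE)
  comp_model_pred <- {
    set.seed(5)
    foldid <- sample(rep_len(1:20, 150))
    cv <- glmnet::cv.glmnet(pc$x, y, alpha = 0.5, foldid = foldid)
    drop(predict(cv, pc$x, s = "lambda.min"))
  }
  s <- project_score(w, meth)
  expect_equal(s$score, comp_model_pred, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("prefilter intersection restricts the training probes", {
  meth <- toy_meth(120, 80, seed = 413)
  # 100 reference sites at p < 1e-7, only 80 exist in training
  pre <- data.frame(probe_id = sprintf("cg%03d", 1:100),
                    p = rep(1e-9, 100))
  set.seed(414)
  y <- rnorm(120)
  w <- train_pca_elnet(meth, y, pre, p_threshold = 1e-7, seed = 6)
  expect_equal(w$provenance$n_prefiltered, 80)
  expect_true(all(w$probe_ids %in% meth$probe_ids))
  expect_error(train_pca_elnet(meth, y,
                               data.frame(probe_id = "cgXXX", p = 1e-9)),
               "fewer than 2")
})

test_that("a threshold sweep returns one weights object per threshold", {
  meth <- toy_meth(100, 40, seed = 415)
  set.seed(416)
  y <- drop(meth$beta[, 1:3] %*% c(2, -1, 1)) + rnorm(100, 0, 0.2)
  pre <- data.frame(probe_id = meth$probe_ids,
                    p = 10^-seq(2, 12, length.out = 40))
  sweep_out <- lapply(c(1e-3, 1e-6, 1e-9), function(th)
    train_pca_elnet(meth, y, pre, p_threshold = th, seed = 7))
  expect_length(sweep_out, 3)
  expect_true(all(vapply(sweep_out, inherits, TRUE, "predictor_weights")))
  # stricter thresholds use fewer probes
  n_pre <- vapply(sweep_out, function(w) w$provenance$n_prefiltered, 0)
  expect_true(all(diff(n_pre) <= 0))
})

test_that("EWAS-weight scores filter on the p threshold", {
  tab <- data.frame(probe_id = paste0("cg", 1:5),
                    effect = c(0.5, -0.2, 0.1, 0.3, -0.4),
                    p = c(1e-10, 1e-9, 0.5, 0.2, 1e-3))
  w <- ewas_weight_score(tab, p_threshold = 3.6e-8)
  expect_equal(w$n_probes, 2)
  expect_equal(w$intercept, 0)
  all_w <- ewas_weight_score(tab, p_threshold = 1.0000001)
  expect_equal(all_w$n_probes, 5)
  expect_error(ewas_weight_score(tab, p_threshold = 1e-20), "no probes")
})

test_that("Bayesian posterior-mean weights back-transform correctly", {
  beta <- matrix(0.1, 1, 3)  # draws {0.1, 0.1, 0.1}
  post <- fake_posterior(beta, comp = matrix(1L, 1, 3),
                         feature_names = "cg001")
  w <- bayes_weights(post, training_means = c(cg001 = 0.5),
                     training_sds = c(cg001 = 0.05))
  expect_equal(unname(w$weights), 2.0)   # 0.1 / 0.05
  expect_equal(w$intercept, -1.0)        # 0 - 2.0 * 0.5
  # zero-mean features are absent
  post2 <- fake_posterior(rbind(cg001 = c(0.1, -0.1), cg002 = c(0, 0)))
  w2 <- bayes_weights(post2, c(cg001 = 0.5, cg002 = 0.5),
                      c(cg001 = 0.1, cg002 = 0.1))
  expect_false("cg001" %in% w2$probe_ids)  # mean exactly zero
  expect_equal(w2$n_probes, 0)
  expect_error(bayes_weights(post, c(x = 1), c(x = 1)), "missing")
})

test_that("projection handles missing probes by omission or imputation", {
  meth <- toy_meth(50, 1468, seed = 417)
  set.seed(418)
  ids <- meth$probe_ids
  w <- methylcrp:::new_weights("elnet", 0.3, ids, rnorm(1468),
                               colMeans(meth$beta),
                               apply(meth$beta, 2, sd))
  # remove 193 of the 1468 weight probes from the cohort
  drop_idx <- sort(sample(1468, 193))
  meth_miss <- meth
  meth_miss$beta <- meth$beta[, -drop_idx]
  meth_miss$probe_ids <- ids[-drop_idx]
  s <- project_score(w, meth_miss, missing_policy = "omit")
  expect_equal(s$frac_missing[1], 193 / 1468)
  expect_equal(s$n_probes_used[1], 1468 - 193)
  # partial-sum oracle
  pres <- match(meth_miss$probe_ids, w$probe_ids)
  oracle <- 0.3 + drop(meth_miss$beta %*% w$weights[pres])
  expect_equal(s$score, oracle, tolerance = 1e-12, ignore_attr = TRUE)
  # mean imputation adds the missing probes' training-mean contributions
  si <- project_score(w, meth_miss, missing_policy = "mean_impute")
  shift <- sum(w$weights[drop_idx] * w$training_means[drop_idx])
  expect_equal(si$score, s$score + shift, tolerance = 1e-10)
})

test_that("projection floor and zero-weight invariances hold", {
  meth <- toy_meth(30, 20, seed = 419)
  w0 <- methylcrp:::new_weights("elnet", 1.25, meth$probe_ids,
                                rep(0, 20), colMeans(meth$beta),
                                apply(meth$beta, 2, sd))
  s0 <- project_score(w0, meth)           # all-zero weights
  expect_true(all(s0$score == 1.25))
  w <- methylcrp:::new_weights("elnet", 0, meth$probe_ids[1:10],
                               rnorm(10), colMeans(meth$beta)[1:10],
                               apply(meth$beta, 2, sd)[1:10])
  # removing a probe the weights do not reference changes nothing
  meth2 <- meth
  meth2$beta <- meth$beta[, -15]; meth2$probe_ids <- meth$probe_ids[-15]
  expect_equal(project_score(w, meth)$score, project_score(w, meth2)$score)
  # floor: drop more than half the weight probes
  meth3 <- meth
  keep <- c(1:4, 11:20)
  meth3$beta <- meth$beta[, keep]; meth3$probe_ids <- meth$probe_ids[keep]
  expect_error(project_score(w, meth3, min_present = 0.5), "floor")
})

test_that("weights round-trip through serialization bit-exactly", {
  set.seed(421)
  w <- methylcrp:::new_weights("bayes", pi, sprintf("cg%04d", 1:50),
                               rnorm(50) * 1e-7, runif(50), runif(50))
  path <- tempfile(fileext = ".tsv")
  write_weights(w, path)
  w2 <- read_weights(path)
  expect_identical(w2$weights, w$weights)
  expect_identical(w2$intercept, w$intercept)
  expect_identical(w2$training_means, w$training_means)
  expect_identical(w2$probe_ids, w$probe_ids)
  unlink(path)
})

test_that("in-sample projection reproduces fitted values", {
  meth <- toy_meth(120, 40, seed = 423)
  set.seed(424)
  y <- drop(meth$beta[, 1:5] %*% runif(5, -2, 2)) + rnorm(120, 0, 0.2)
  w <- train_elastic_net(meth, y, seed = 8)
  Z <- scale(meth$beta)
  set.seed(8)
  foldid <- sample(rep_len(1:20, 120))
  cv <- glmnet::cv.glmnet(Z, y, alpha = 0.5, foldid = foldid,
                          standardize = FALSE)
  fitted <- drop(predict(cv, Z, s = "lambda.min"))
  expect_equal(project_score(w, meth)$score, fitted, tolerance = 1e-8,
               ignore_attr = TRUE)
})
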