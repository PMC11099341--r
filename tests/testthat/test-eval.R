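test_that("correlation evaluation returns exact and null results", {
  set.seed(501)
  ph <- data.frame(sample_id = paste0("s", 1:200),
                   log_crp = rnorm(200))
  perfect <- data.frame(sample_id = ph$sample_id, score = ph$log_crp)
  ce <- correlation_eval(perfect, ph)
  expect_equal(ce$r, 1)
  noise <- data.frame(sample_id = ph$sample_id, score = rnorm(200))
  expect_lt(abs(correlation_eval(noise, ph)$r), 3 / sqrt(200))
  expect_error(correlation_eval(
    data.frame(sample_id = ph$sample_id, score = 1), ph), "zero variance")
})

test_that("Fisher-z interval brackets the correlation", {
  set.seed(503)
  ph <- data.frame(sample_id = paste0("s", 1:500), log_crp = rnorm(500))
  sc <- data.frame(sample_id = ph$sample_id,
                   score = 0.5 * ph$log_crp + rnorm(500, 0, 0.8))
  ce <- correlation_eval(sc, ph)
  expect_lt(ce$ci_low, ce$r)
  expect_gt(ce$ci_high, ce$r)
})

test_that("incremental R2 equals the two-regression oracle", {
  set.seed(507)
  d <- data.frame(age = c(61, 72, 55, 68, 70, 59, 74, 66, 63, 69, 58, 71),
                  sex = rep(0:1, 6))
  y <- 0.02 * d$age + 0.3 * d$sex + rnorm(12)
  x <- rnorm(12)
  got <- incremental_r2(y, d, x)
  r2_null <- summary(lm(y ~ age + sex, data = d))$r.squared
  r2_full <- summary(lm(y ~ age + sex + x, data = d))$r.squared
  expect_equal(got$delta_r2, r2_full - r2_null, tolerance = 1e-10)
  expect_equal(got$r2_null, r2_null, tolerance = 1e-10)
})

test_that("incremental R2 limits: orthogonal addition and residual addition", {
  set.seed(509)
  n <- 400
  d <- data.frame(age = rnorm(n), sex = rbinom(n, 1, 0.5))
  y <- 0.5 * d$age + rnorm(n)
  expect_lt(incremental_r2(y, d, rnorm(n))$delta_r2, 2 / n * 3)
  res <- residualize(y, d)
  got <- incremental_r2(y, d, res)
  expect_equal(got$delta_r2, 1 - got$r2_null, tolerance = 1e-9)
  expect_gte(got$delta_r2, 0)
  expect_error(incremental_r2(y, d, d$age), "rank deficient")
})

test_that("stacked additions give the marginal gain over prior additions", {
  set.seed(511)
  n <- 300
  d <- data.frame(age = rnorm(n), sex = rbinom(n, 1, 0.5))
  g <- rnorm(n); m <- 0.6 * g + rnorm(n)
  y <- 0.5 * g + 0.5 * m + rnorm(n)
  full <- incremental_r2(y, d, m, prior_additions = g)
  alone <- incremental_r2(y, d, m)
  expect_lt(full$delta_r2, alone$delta_r2)  # overlap absorbed by g
})

test_that("ICC2k matches an ANOVA mean-squares oracle and its limits", {
  M <- matrix(c(9, 2, 5, 8, 6, 1,
                10, 4, 7, 9, 7, 2,
                8, 2, 6, 9, 8, 3), 6, 3)
  got <- icc2k(M)$icc2k
  # oracle from aov() mean squares (two-way, subjects x waves)
  d <- data.frame(y = as.vector(M),
                  subj = factor(rep(1:6, 3)),
                  wave = factor(rep(1:3, each = 6)))
  ms <- anova(lm(y ~ subj + wave, data = d))[["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  oracle <- (msr - mse) / (msr + (msc - mse) / 6)
  expect_equal(got, oracle, tolerance = 1e-10)
  # identical columns -> 1
  same <- matrix(rnorm(8), 8, 3)[, c(1, 1, 1)]
  same <- matrix(rep(rnorm(8), 3), 8, 3)
  expect_equal(icc2k(same)$icc2k, 1, tolerance = 1e-9)
  # independent columns -> near 0 on average
  set.seed(513)
  iccs <- replicate(40, icc2k(matrix(rnorm(60), 20, 3))$icc2k)
  expect_lt(abs(mean(iccs)), 0.15)
  expect_error(icc2k(matrix(1, 5, 1)), "2 waves")
  expect_error(icc2k(matrix(1, 3, 2)), "5 complete")
})

test_that("ICC2k uses complete cases only", {
  set.seed(517)
  M <- matrix(rnorm(30), 10, 3)
  M2 <- rbind(M, c(NA, 1, 2))
  expect_equal(icc2k(M2)$icc2k, icc2k(M)$icc2k)
  expect_equal(icc2k(M2)$n_subjects, 10)
})

test_that("longitudinal mixed model finds no interaction under the null", {
  set.seed(519)
  n <- 150
  base <- rnorm(n)
  long <- do.call(rbind, lapply(1:3, function(w)
    data.frame(sample_id = paste0("s", 1:n), wave = w,
               log_crp = rnorm(n) + rep(rnorm(n, 0, 0.5), 1),
               age = 70 + 3 * (w - 1) + rnorm(n, 0, 0.3),
               sex = rep(rbinom(n, 1, 0.5), 1))))
  r <- longitudinal_lmm(long, setNames(base, paste0("s", 1:n)))
  expect_lt(abs(r$effect / r$se), 4)
})

test_that("decline of high-baseline subjects yields a negative interaction", {
  set.seed(521)
  n <- 200
  subj <- paste0("s", 1:n)
  base <- rnorm(n)
  u <- rnorm(n, 0, 0.4)
  rows <- lapply(1:3, function(w) {
    age <- 70 + 3 * (w - 1)
    # high-baseline subjects decline faster with age
    y <- 0.8 * base - 0.06 * base * (age - 70) + u + rnorm(n, 0, 0.3)
    data.frame(sample_id = subj, wave = w, log_crp = y, age = age,
               sex = rep(0:1, n / 2))
  })
  long <- do.call(rbind, rows)
  r <- longitudinal_lmm(long, setNames(base, subj))
  expect_lt(r$effect, 0)
  expect_lt(r$p, 0.01)
})

test_that("random-intercept variance is recovered on simulated data", {
  set.seed(523)
  n <- 250
  subj <- paste0("s", 1:n)
  u <- rnorm(n, 0, sqrt(0.3))
  long <- do.call(rbind, lapply(1:4, function(w)
    data.frame(sample_id = subj, wave = w,
               log_crp = u + rnorm(n, 0, sqrt(0.5)),
               age = 70 + 3 * (w - 1), sex = rep(0:1, n / 2))))
  r <- longitudinal_lmm(long, setNames(rnorm(n), subj))
  vc <- as.data.frame(lme4::VarCorr(r$model))
  est <- vc$vcov[vc$grp == "sample_id"]
  se_approx <- est * sqrt(2 / n)
  expect_lt(abs(est - 0.3), 4 * se_approx)
})

test_that("BH adjustment matches the step-up hand computation", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.123), 0.123)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_length(bh_fdr(numeric(0)), 0)
  # permutation invariance
  set.seed(527)
  p <- runif(30)
  perm <- sample(30)
  expect_equal(bh_fdr(p)[perm], bh_fdr(p[perm]))
  # monotone in p
  q <- bh_fdr(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("outcome battery recovers logistic and Cox effects", {
  set.seed(529)
  n <- 5000
  x <- rnorm(n)
  pheno <- data.frame(sample_id = paste0("s", 1:n), age = rnorm(n, 70, 3),
                      sex = rbinom(n, 1, 0.5))
  pheno$outcome_b1 <- rbinom(n, 1, plogis(qlogis(0.25) + log(1.5) * x))
  t_event <- rexp(n, 0.05 * exp(log(1.5) * x))
  t_cens <- quantile(t_event, 0.7) * runif(n, 0.8, 1.2)
  pheno$survival_time <- pmin(t_event, t_cens)
  pheno$death_event <- as.integer(t_event <= t_cens)
  pheno$outcome_c01 <- 0.2 * x + rnorm(n)
  res <- outcome_battery(list(score = x), pheno,
                         continuous = "outcome_c01", binary = "outcome_b1")
  or_row <- res[res$model == "logistic", ]
  expect_equal(exp(or_row$effect), 1.5, tolerance = 0.15 / 1.5)
  hr_row <- res[res$model == "cox", ]
  expect_equal(exp(hr_row$effect), 1.5, tolerance = 0.15 / 1.5)
  expect_true(all(res$q >= res$p - 1e-12, na.rm = TRUE))
})

test_that("battery flags rare binary outcomes and controls the null FDR", {
  set.seed(531)
  n <- 400
  pheno <- data.frame(sample_id = paste0("s", 1:n), age = rnorm(n, 70, 3),
                      sex = rbinom(n, 1, 0.5))
  for (k in 1:21) pheno[[sprintf("outcome_c%02d", k)]] <- rnorm(n)
  for (k in 1:4) pheno[[sprintf("outcome_b%d", k)]] <- rbinom(n, 1, 0.3)
  pheno$outcome_b1 <- c(1, rep(0, n - 1))  # 1 event only
  pheno$survival_time <- rexp(n, 0.05)
  pheno$death_event <- rbinom(n, 1, 0.4)
  res <- outcome_battery(list(score = rnorm(n)), pheno)
  expect_true(res$flagged[res$outcome == "outcome_b1"])
  expect_equal(sum(res$q < 0.05, na.rm = TRUE), 0)
})

test_that("height covariate applies to designated outcomes", {
  set.seed(533)
  n <- 300
  pheno <- data.frame(sample_id = paste0("s", 1:n), age = rnorm(n, 70, 3),
                      sex = rbinom(n, 1, 0.5), height = rnorm(n, 168, 8))
  pheno$outcome_c01 <- 0.05 * pheno$height + rnorm(n)
  x <- rnorm(n)
  with_h <- outcome_battery(list(s = x), pheno, continuous = "outcome_c01",
                            binary = character(0), survival = FALSE,
                            height_outcomes = "outcome_c01")
  without_h <- outcome_battery(list(s = x), pheno,
                               continuous = "outcome_c01",
                               binary = character(0), survival = FALSE)
  expect_false(isTRUE(all.equal(with_h$se, without_h$se)))
})

test_that("polygenic score weights, thresholds and allele flips are honored", {
  g <- structure(list(sample_ids = c("a", "b"),
                      snp_ids = c("rs1", "rs2", "rs3", "rs4"),
                      dosage = matrix(c(2, 1, 0, 2, 1, 0, 2, 2), 2, 4,
                                      dimnames = list(c("a", "b"), NULL)),
                      maf = rep(0.3, 4),
                      effect_allele = c("A", "C", "G", "T"),
                      other_allele = c("G", "T", "A", "A"),
                      missing_rate = rep(0, 4), hwe_p = rep(0.5, 4)),
                 class = "geno_set")
  gwas1 <- data.frame(snp_id = "rs1", effect_allele = "A",
                      other_allele = "G", effect = 0.3, p = 1e-10)
  s <- polygenic_score(g, gwas1)
  expect_equal(s$score[s$sample_id == "a"], 0.6)  # dosage 2 x 0.3
  # sub-threshold SNP excluded
  gwas2 <- rbind(gwas1, data.frame(snp_id = "rs2", effect_allele = "C",
                                   other_allele = "T", effect = 1,
                                   p = 1e-7))
  expect_equal(polygenic_score(g, gwas2)$score, s$score)
  # swapped alleles flip the effect sign
  gwas3 <- data.frame(snp_id = "rs1", effect_allele = "G",
                      other_allele = "A", effect = 0.3, p = 1e-10)
  s3 <- polygenic_score(g, gwas3)
  expect_equal(s3$score, -s$score)
  # unresolvable alleles are dropped with a warning
  gwas4 <- rbind(gwas1, data.frame(snp_id = "rs3", effect_allele = "C",
                                   other_allele = "T", effect = 5,
                                   p = 1e-10))
  expect_warning(s4 <- polygenic_score(g, gwas4), "mismatch")
  expect_equal(s4$score, s$score)
})
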