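#' Configuration for the synthetic inflammation cohort generator
#'
#' Defines the generative law for a cohort with the statistical structure the
#' CRP analyses assume: CpG probes organised in correlated blocks within
#' 2.5 kb windows, a methylation-linked and a genetic variance component of
#' log CRP, confounder paths (BMI, smoking, lifestyle, cell composition,
#' batch), assay-sensitivity behaviour and downstream health outcomes.
#'
#' The variance budget is expressed on the standardised log-CRP scale: the
#' methylation-linked component contributes \code{var_dnam}, the additive
#' genetic score \code{var_snp}, each confounder path the square of its entry
#' in \code{confounder_effects}, and the residual takes the remainder. The
#' defaults target the architecture reported for population-scale blood CRP:
#' roughly half of the variance attributable to methylation and 13\% to
#' common genetic variation.
#'
#' @param n_samples Number of individuals.
#' @param n_probes Number of CpG probes.
#' @param n_snps Number of SNPs.
#' @param block_size_range Length-2 integer vector; block sizes are drawn
#'   uniformly from this range. Blocks are placed within 2.5 kb windows.
#' @param within_block_corr Pairwise latent correlation of probes sharing a
#'   block, in \[0, 1).
#' @param frac_causal_probes Fraction of probes loading on the
#'   methylation-linked CRP component.
#' @param frac_causal_snps Fraction of SNPs with nonzero effect on CRP.
#' @param var_dnam Target fraction of log-CRP variance from the
#'   methylation-linked component.
#' @param var_snp Target fraction from the additive genetic score.
#' @param confounder_effects Named numeric vector of standardised effect
#'   scales for \code{bmi}, \code{smoking}, \code{alcohol},
#'   \code{deprivation}, \code{education}, \code{age}, \code{sex},
#'   \code{cells}, \code{batch}. Contribution to the variance budget is the
#'   square of each entry.
#' @param frac_confounded_probes Fraction of non-causal probes that carry BMI
#'   and smoking signal (creating confounded EWAS associations).
#' @param confounder_probe_loading Loading scale of BMI/smoking on confounded
#'   probe latents.
#' @param n_batches Number of experimental batches.
#' @param n_waves Number of longitudinal waves the phenotype design supports.
#' @param assay_per_wave Character vector (recycled to \code{n_waves}) of CRP
#'   assay types per wave: \code{"high"}, \code{"low"} or \code{"wide"}.
#' @param probes_missing_in_test Default number of probes absent from a
#'   derived test cohort.
#' @param log_crp_mean,log_crp_sd Location and scale mapping the standardised
#'   latent to log CRP (mg/L scale); defaults give a cohort mean near
#'   3.3 mg/L.
#' @param outcome_effects_cont Length-21 vector of standardised effects of
#'   latent inflammation on the continuous outcomes.
#' @param outcome_effects_bin Length-4 vector of log odds ratios per SD for
#'   the binary outcomes.
#' @param hazard_log_hr Log hazard ratio per SD of latent inflammation for
#'   all-cause mortality.
#' @param seed Master seed; fans out to named substreams (probes, genotypes,
#'   phenotype, outcomes, waves).
#' @return An object of class \code{sim_config}.
#' @export
sim_config <- function(n_samples = 1000,
                       n_probes = 2000,
                       n_snps = 500,
                       block_size_range = c(1L, 5L),
                       within_block_corr = 0.7,
                       frac_causal_probes = 0.05,
                       frac_causal_snps = 0.10,
                       var_dnam = 0.50,
                       var_snp = 0.13,
                       confounder_effects = c(bmi = 0.30, smoking = 0.20,
                                              alcohol = 0.10, deprivation = 0.10,
                                              education = 0.10, age = 0.15,
                                              sex = 0.10, cells = 0.10,
                                              batch = 0.05),
                       frac_confounded_probes = 0.15,
                       confounder_probe_loading = 0.6,
                       n_batches = 5,
                       n_waves = 1,
                       assay_per_wave = "high",
                       probes_missing_in_test = 0,
                       log_crp_mean = 0.8,
                       log_crp_sd = 0.9,
                       outcome_effects_cont = seq(0.10, 0.40, length.out = 21),
                       outcome_effects_bin = rep(log(1.5), 4),
                       hazard_log_hr = log(1.5),
                       seed = 1) {
  stopifnot(n_samples >= 2, n_probes >= 2, n_snps >= 1, n_waves >= 1)
  if (within_block_corr < 0 || within_block_corr >= 1)
    stop("within_block_corr must lie in [0, 1)")
  eff <- confounder_effects
  needed <- c("bmi", "smoking", "alcohol", "deprivation", "education",
              "age", "sex", "cells", "batch")
  missing_names <- setdiff(needed, names(eff))
  if (length(missing_names))
    stop("confounder_effects missing entries: ",
         paste(missing_names, collapse = ", "))
  var_conf <- sum(eff[needed]^2)
  var_resid <- 1 - var_dnam - var_snp - var_conf
  if (var_dnam < 0 || var_snp < 0)
    stop("variance fractions must be non-negative")
  if (var_resid < -1e-9)
    stop(sprintf(paste0("infeasible variance budget: var_dnam + var_snp + ",
                        "confounder variance = %.3f exceeds 1"),
                 var_dnam + var_snp + var_conf))
  var_resid <- max(var_resid, 0)
  assay <- rep_len(match.arg(assay_per_wave, c("high", "low", "wide"),
                             several.ok = TRUE), n_waves)
  cfg <- list(n_samples = as.integer(n_samples),
              n_probes = as.integer(n_probes),
              n_snps = as.integer(n_snps),
              block_size_range = as.integer(block_size_range),
              within_block_corr = within_block_corr,
              frac_causal_probes = frac_causal_probes,
              frac_causal_snps = frac_causal_snps,
              var_dnam = var_dnam, var_snp = var_snp,
              confounder_effects = eff[needed],
              var_conf = var_conf, var_resid = var_resid,
              frac_confounded_probes = frac_confounded_probes,
              confounder_probe_loading = confounder_probe_loading,
              n_batches = as.integer(n_batches),
              n_waves = as.integer(n_waves),
              assay_per_wave = assay,
              probes_missing_in_test = as.integer(probes_missing_in_test),
              log_crp_mean = log_crp_mean, log_crp_sd = log_crp_sd,
              outcome_effects_cont = rep_len(outcome_effects_cont, 21),
              outcome_effects_bin = rep_len(outcome_effects_bin, 4),
              hazard_log_hr = hazard_log_hr,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# Named substream seeds derived from the master seed so each generator
# component is reproducible independently.
fan_out_seeds <- function(seed) {
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, 6L)
  names(s) <- c("law", "samples", "genotypes", "phenotype", "outcomes",
                "waves")
  s
}

# The generative law: probe-level and SNP-level parameters shared by the
# training cohort and any derived test cohort.
build_law <- function(config) {
  set.seed(fan_out_seeds(config$seed)[["law"]])
  m <- config$n_probes
  bs <- config$block_size_range
  sizes <- integer(0)
  while (sum(sizes) < m)
    sizes <- c(sizes, sample(seq(bs[1], bs[2]), 1L))
  extra <- sum(sizes) - m
  if (extra > 0) sizes[length(sizes)] <- sizes[length(sizes)] - extra
  sizes <- sizes[sizes > 0]
  n_blocks <- length(sizes)
  block_of <- rep(seq_len(n_blocks), sizes)
  chr <- paste0("chr", ((seq_len(n_blocks) - 1L) %% 22L) + 1L)[block_of]
  # blocks spaced 100 kb apart; members confined to a 2.5 kb window
  block_start <- (seq_len(n_blocks) - 1L) * 100000L + 1L
  pos <- integer(m)
  for (b in seq_len(n_blocks)) {
    idx <- which(block_of == b)
    pos[idx] <- block_start[b] + sort(sample.int(2500L, length(idx)))
  }
  probe_ids <- sprintf("cg%07d", seq_len(m))
  probe_mu <- stats::rnorm(m, 0, 1.5)

  n_causal <- max(1L, round(config$frac_causal_probes * m))
  if (config$var_dnam == 0) n_causal <- 0L
  causal_probes <- sort(sample.int(m, n_causal))
  causal_w <- stats::rnorm(n_causal)

  # confounder, cell and batch structure loads on non-causal probes only,
  # keeping the truth components of the variance budget orthogonal
  non_causal <- setdiff(seq_len(m), causal_probes)
  n_conf <- round(config$frac_confounded_probes * length(non_causal))
  conf_probes <- sort(sample(non_causal, n_conf))
  bmi_load <- smk_load <- numeric(m)
  bmi_load[conf_probes] <- stats::rnorm(n_conf, 0,
                                        config$confounder_probe_loading)
  smk_load[conf_probes] <- stats::rnorm(n_conf, 0,
                                        config$confounder_probe_loading / 2)
  cell_load <- numeric(m)
  cell_idx <- sample(non_causal, round(0.2 * length(non_causal)))
  cell_load[cell_idx] <- stats::rnorm(length(cell_idx), 0, 0.3)
  batch_shift <- matrix(stats::rnorm(m * config$n_batches, 0, 0.15),
                        m, config$n_batches)
  batch_shift[causal_probes, ] <- 0

  maf <- stats::runif(config$n_snps, 0.05, 0.5)
  snp_ids <- sprintf("rs%06d", seq_len(config$n_snps))
  n_causal_snp <- max(1L, round(config$frac_causal_snps * config$n_snps))
  if (config$var_snp == 0) n_causal_snp <- 0L
  causal_snps <- sort(sample.int(config$n_snps, n_causal_snp))
  snp_w <- stats::rnorm(n_causal_snp)
  alleles <- matrix(sample(c("A", "C", "G", "T"), 2L * config$n_snps,
                           replace = TRUE), ncol = 2L)

  list(config = config, probe_ids = probe_ids, probe_chr = chr,
       probe_pos = pos, probe_mu = probe_mu, block_of = block_of,
       n_blocks = n_blocks, causal_probes = causal_probes,
       causal_w = causal_w, bmi_load = bmi_load, smk_load = smk_load,
       cell_load = cell_load, batch_shift = batch_shift,
       maf = maf, snp_ids = snp_ids, causal_snps = causal_snps,
       snp_w = snp_w, effect_allele = alleles[, 1],
       other_allele = alleles[, 2])
}

scale_cols <- function(X) {
  X <- as.matrix(X)
  sds <- apply(X, 2, stats::sd)
  sds[sds == 0] <- 1
  sweep(sweep(X, 2, colMeans(X)), 2, sds, "/")
}

std_vec <- function(x) {
  s <- stats::sd(x)
  if (s == 0) return(x - mean(x))
  (x - mean(x)) / s
}

# Draw the per-sample latent probe matrix (pre-logistic scale) given sample
# level inputs; shared by cross-sectional and longitudinal generation.
draw_probe_latents <- function(law, u_block, e_probe, bmi, smoking,
                               gran, batch) {
  cfg <- law$config
  n <- length(bmi)
  rho <- cfg$within_block_corr
  x <- sqrt(rho) * u_block[, law$block_of, drop = FALSE] +
    sqrt(1 - rho) * e_probe
  x <- x +
    outer(bmi, law$bmi_load) +
    outer(smoking, law$smk_load) +
    outer(std_vec(gran), law$cell_load) +
    t(law$batch_shift[, batch, drop = FALSE])
  # modest per-probe dynamic range: keeps the logistic map near-linear so
  # beta-scale correlations track the latent ones, and matches the small
  # within-probe SDs typical of array beta-values
  sweep(0.6 * x, 2, law$probe_mu, "+")
}

#' Generate a synthetic cohort with known CRP architecture
#'
#' Draws a samples-by-probes beta-value matrix (correlated blocks on a
#' logistic latent scale), an additively coded SNP dosage matrix in
#' Hardy-Weinberg proportions, a phenotype table (CRP in mg/L with assay
#' tag, demographics, lifestyle covariates, six cell proportions, batch,
#' ancestry components, survival follow-up and 25 health outcomes), and a
#' ground-truth record of the causal sets and realized variance
#' decomposition.
#'
#' The methylation-linked CRP component is a fixed weighted combination of
#' the standardised causal-probe beta-values, so the recorded variance
#' fraction is exactly the linearly recoverable one; the genetic component is
#' defined analogously from standardised dosages. Below-detection readings on
#' low-sensitivity assays (< 3 mg/L) are stored with their raw value and a
#' flag; imputation is left to [transform_crp()].
#'
#' @param config A [sim_config()] object.
#' @return A list of class \code{crp_cohort} with elements \code{meth}
#'   (beta matrix plus probe annotation), \code{geno}, \code{pheno}
#'   (data frame) and \code{truth}.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  law <- build_law(config)
  cohort <- draw_cohort(law, n = config$n_samples,
                        seed = fan_out_seeds(config$seed)[["samples"]],
                        array_tag = "EPIC_synthetic")
  attr(cohort, "law") <- law
  cohort
}

draw_cohort <- function(law, n, seed, array_tag, age_shift = 0) {
  cfg <- law$config
  set.seed(seed)
  m <- cfg$n_probes
  sample_ids <- sprintf("S%05d", seq_len(n))

  age <- stats::rnorm(n, 50 + age_shift, 10)
  sex <- stats::rbinom(n, 1, 0.5)
  bmi <- stats::rnorm(n)
  smoking <- stats::rnorm(n)
  alcohol <- stats::rnorm(n)
  deprivation <- stats::rnorm(n)
  education <- stats::rnorm(n)
  anc <- matrix(stats::rnorm(n * 20), n, 20,
                dimnames = list(NULL, paste0("anc", 1:20)))
  batch <- sample.int(cfg$n_batches, n, replace = TRUE)
  # cell proportions via gamma-normalised Dirichlet
  alpha <- c(bcell = 0.06, cd4t = 0.16, cd8t = 0.08, gran = 0.55,
             mono = 0.08, nk = 0.07) * 60
  g <- matrix(stats::rgamma(n * 6, shape = rep(alpha, each = n)), n, 6)
  cells <- g / rowSums(g)
  colnames(cells) <- names(alpha)

  u_block <- matrix(stats::rnorm(n * law$n_blocks), n, law$n_blocks)
  e_probe <- matrix(stats::rnorm(n * m), n, m)
  x <- draw_probe_latents(law, u_block, e_probe, bmi, smoking,
                          cells[, "gran"], batch)
  beta <- stats::plogis(x)
  colnames(beta) <- law$probe_ids
  rownames(beta) <- sample_ids

  dosage <- matrix(stats::rbinom(n * cfg$n_snps, 2L, rep(law$maf, each = n)),
                   n, cfg$n_snps, dimnames = list(sample_ids, law$snp_ids))

  # methylation-linked and genetic components defined on observed data
  if (length(law$causal_probes)) {
    D <- std_vec(scale_cols(beta[, law$causal_probes, drop = FALSE]) %*%
                   law$causal_w)
  } else D <- numeric(n)
  if (length(law$causal_snps)) {
    G <- std_vec(scale_cols(dosage[, law$causal_snps, drop = FALSE]) %*%
                   law$snp_w)
  } else G <- numeric(n)

  eff <- cfg$confounder_effects
  batch_eff <- stats::rnorm(cfg$n_batches)
  conf_paths <- cbind(bmi = std_vec(bmi), smoking = std_vec(smoking),
                      alcohol = std_vec(alcohol),
                      deprivation = std_vec(deprivation),
                      education = std_vec(education), age = std_vec(age),
                      sex = std_vec(sex), cells = std_vec(cells[, "gran"]),
                      batch = std_vec(batch_eff[batch]))
  conf_part <- drop(conf_paths %*% eff)
  noise <- std_vec(stats::rnorm(n))
  z <- sqrt(cfg$var_dnam) * D + sqrt(cfg$var_snp) * G + conf_part +
    sqrt(cfg$var_resid) * noise

  log_crp <- cfg$log_crp_mean + cfg$log_crp_sd * z
  crp <- pmax(exp(log_crp) - 0.01, 0)
  assay <- cfg$assay_per_wave[1]
  below_detection <- assay == "low" & crp < 3

  lat <- z  # latent inflammation, reused for outcomes
  oc <- sapply(seq_len(21), function(k) {
    e <- cfg$outcome_effects_cont[k]
    e * lat + sqrt(max(0, 1 - e^2)) * stats::rnorm(n)
  })
  colnames(oc) <- sprintf("outcome_c%02d", 1:21)
  ob <- sapply(seq_len(4), function(k) {
    lp <- stats::qlogis(0.2) + cfg$outcome_effects_bin[k] * lat
    stats::rbinom(n, 1, stats::plogis(lp))
  })
  colnames(ob) <- sprintf("outcome_b%d", 1:4)
  rate <- 0.03 * exp(cfg$hazard_log_hr * lat)
  t_event <- stats::rexp(n, rate)
  t_cens <- stats::runif(n, 5, 15)
  survival_time <- pmin(t_event, t_cens)
  death_event <- as.integer(t_event <= t_cens)

  pheno <- data.frame(sample_id = sample_ids, wave = 1L,
                      crp_mg_per_l = crp, assay = assay,
                      below_detection = below_detection,
                      age = age, sex = sex, bmi = bmi,
                      smoking_score = smoking, alcohol = alcohol,
                      deprivation = deprivation, education = education,
                      batch = factor(batch),
                      survival_time = survival_time,
                      death_event = death_event,
                      stringsAsFactors = FALSE)
  pheno <- cbind(pheno, as.data.frame(cells), as.data.frame(anc),
                 as.data.frame(oc), as.data.frame(ob))

  # realized decomposition: component contributions have empirical variance
  # equal to their budget share by construction; cross-covariances make the
  # total differ from 1 only by O(1/sqrt(n))
  vz <- stats::var(z)
  realized <- c(dnam = stats::var(sqrt(cfg$var_dnam) * D) / vz,
                snp = stats::var(sqrt(cfg$var_snp) * G) / vz,
                conf = stats::var(conf_part) / vz,
                resid = stats::var(sqrt(cfg$var_resid) * noise) / vz)

  truth <- list(causal_probe_ids = law$probe_ids[law$causal_probes],
                causal_probe_effects = law$causal_w,
                causal_snp_ids = law$snp_ids[law$causal_snps],
                causal_snp_effects = law$snp_w,
                true_var_dnam = cfg$var_dnam, true_var_snp = cfg$var_snp,
                realized_var = realized,
                confounder_effects = eff,
                block_of = law$block_of,
                dnam_component = D, genetic_score = G,
                confounder_part = conf_part, latent = z)

  meth <- list(sample_ids = sample_ids, probe_ids = law$probe_ids,
               beta = beta, probe_chr = law$probe_chr,
               probe_pos = law$probe_pos, array_tag = array_tag)
  class(meth) <- "meth_set"
  geno <- list(sample_ids = sample_ids, snp_ids = law$snp_ids,
               dosage = dosage, maf = law$maf,
               effect_allele = law$effect_allele,
               other_allele = law$other_allele,
               missing_rate = rep(0, cfg$n_snps),
               hwe_p = hwe_test(dosage))
  class(geno) <- "geno_set"
  out <- list(meth = meth, geno = geno, pheno = pheno, truth = truth)
  class(out) <- "crp_cohort"
  out
}

#' Derive an external test cohort from a training cohort's generative law
#'
#' Draws fresh samples from the same law, optionally shifts the age
#' distribution, and removes a configured number of probes from the
#' methylation matrix to emulate an external cohort on a different array.
#'
#' @param train A cohort from [generate_cohort()].
#' @param probes_missing Number of randomly chosen probes absent from the
#'   test methylation data.
#' @param age_shift Years added to the mean age.
#' @param seed Seed for the new sample draw and the missing-probe choice.
#' @param n_samples Test-cohort size (defaults to the training size).
#' @return A \code{crp_cohort} whose methylation matrix lacks
#'   \code{probes_missing} probes.
#' @export
derive_test_cohort <- function(train, probes_missing = NULL, age_shift = 0,
                               seed = 1, n_samples = NULL) {
  law <- attr(train, "law")
  if (is.null(law)) stop("train must carry its generative law")
  cfg <- law$config
  if (is.null(probes_missing)) probes_missing <- cfg$probes_missing_in_test
  if (probes_missing >= cfg$n_probes)
    stop("probes_missing must be smaller than the number of probes")
  if (is.null(n_samples)) n_samples <- cfg$n_samples
  test <- draw_cohort(law, n = n_samples, seed = seed,
                      array_tag = "450K_synthetic", age_shift = age_shift)
  if (probes_missing > 0) {
    set.seed(seed + 1L)
    drop_idx <- sort(sample.int(cfg$n_probes, probes_missing))
    test$meth$beta <- test$meth$beta[, -drop_idx, drop = FALSE]
    test$meth$probe_ids <- test$meth$probe_ids[-drop_idx]
    test$meth$probe_chr <- test$meth$probe_chr[-drop_idx]
    test$meth$probe_pos <- test$meth$probe_pos[-drop_idx]
  }
  attr(test, "law") <- law
  test
}

#' Generate multi-wave longitudinal CRP (and methylation) measurements
#'
#' Per-subject latent inflammation follows an AR(1) path with wave-to-wave
#' correlation \code{tracking_corr} on its phasic part, while the
#' methylation state persists with correlation \code{dnam_tracking}; each
#' wave's CRP reading passes through that wave's assay rule (low-sensitivity
#' assays flag readings below 3 mg/L as below detection).
#'
#' @param cohort A \code{crp_cohort}.
#' @param n_waves Number of waves (>= 2).
#' @param tracking_corr AR(1) correlation of the phasic inflammation
#'   component between adjacent waves, in \[0, 1\].
#' @param assay_per_wave Assay type per wave, recycled to \code{n_waves}.
#' @param seed Seed for wave innovations.
#' @param dnam_tracking AR(1) correlation of the methylation latents between
#'   adjacent waves (methylation is far more stable than CRP).
#' @param years_per_wave Age increment between waves.
#' @return A list with \code{pheno} (long-format phenotype table),
#'   \code{meth} (list of per-wave \code{meth_set}s) and \code{latent}
#'   (subjects x waves matrix of the latent log-CRP scale).
#' @export
generate_longitudinal <- function(cohort, n_waves, tracking_corr,
                                  assay_per_wave = "high", seed = 1,
                                  dnam_tracking = 0.95,
                                  years_per_wave = 3) {
  if (n_waves < 2) stop("n_waves must be at least 2")
  if (tracking_corr < 0 || tracking_corr > 1)
    stop("tracking_corr must lie in [0, 1]")
  law <- attr(cohort, "law")
  if (is.null(law)) stop("cohort must carry its generative law")
  cfg <- law$config
  n <- nrow(cohort$pheno)
  assay <- rep_len(assay_per_wave, n_waves)
  set.seed(fan_out_seeds(seed)[["waves"]])

  p <- cohort$pheno
  batch <- as.integer(as.character(p$batch))
  conf_part <- cohort$truth$confounder_part
  G <- cohort$truth$genetic_score

  # initial states reproduce wave 1 up to fresh probe noise
  u <- matrix(stats::rnorm(n * law$n_blocks), n, law$n_blocks)
  e <- matrix(stats::rnorm(n * cfg$n_probes), n, cfg$n_probes)
  eta <- std_vec(stats::rnorm(n))  # phasic component

  pheno_rows <- list()
  meth_waves <- list()
  latent <- matrix(NA_real_, n, n_waves)
  for (w in seq_len(n_waves)) {
    if (w > 1) {
      rr <- dnam_tracking
      u <- rr * u + sqrt(1 - rr^2) *
        matrix(stats::rnorm(n * law$n_blocks), n, law$n_blocks)
      e <- rr * e + sqrt(1 - rr^2) *
        matrix(stats::rnorm(n * cfg$n_probes), n, cfg$n_probes)
      tc <- tracking_corr
      eta <- tc * eta + sqrt(max(0, 1 - tc^2)) * stats::rnorm(n)
    }
    x <- draw_probe_latents(law, u, e, p$bmi, p$smoking_score,
                            p[["gran"]], batch)
    beta_w <- stats::plogis(x)
    colnames(beta_w) <- law$probe_ids
    rownames(beta_w) <- p$sample_id
    if (length(law$causal_probes)) {
      D_w <- std_vec(scale_cols(beta_w[, law$causal_probes, drop = FALSE]) %*%
                       law$causal_w)
    } else D_w <- numeric(n)
    z_w <- sqrt(cfg$var_dnam) * D_w + sqrt(cfg$var_snp) * G + conf_part +
      sqrt(cfg$var_resid) * eta
    latent[, w] <- z_w
    log_crp <- cfg$log_crp_mean + cfg$log_crp_sd * z_w
    crp <- pmax(exp(log_crp) - 0.01, 0)
    below <- assay[w] == "low" & crp < 3
    pheno_rows[[w]] <- data.frame(sample_id = p$sample_id, wave = w,
                                  crp_mg_per_l = crp, assay = assay[w],
                                  below_detection = below,
                                  age = p$age + (w - 1) * years_per_wave,
                                  sex = p$sex, stringsAsFactors = FALSE)
    meth_w <- list(sample_ids = p$sample_id, probe_ids = law$probe_ids,
                   beta = beta_w, probe_chr = law$probe_chr,
                   probe_pos = law$probe_pos,
                   array_tag = cohort$meth$array_tag)
    class(meth_w) <- "meth_set"
    meth_waves[[w]] <- meth_w
  }
  list(pheno = do.call(rbind, pheno_rows), meth = meth_waves,
       latent = latent)
}

# Exact 1-df chi-square HWE test per SNP from genotype counts.
hwe_test <- function(dosage) {
  apply(dosage, 2, function(g) {
    g <- g[!is.na(g)]
    n <- length(g)
    n2 <- sum(g == 2); n1 <- sum(g == 1); n0 <- sum(g == 0)
    p <- (2 * n2 + n1) / (2 * n)
    if (p == 0 || p == 1) return(1)
    e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
    x2 <- sum((c(n0, n1, n2) - e)^2 / e)
    stats::pchisq(x2, df = 1, lower.tail = FALSE)
  })
}
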