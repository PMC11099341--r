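# Shared fixtures built in code. Sizes are kept small; statistical checks
# use fixed seeds so they are deterministic.

small_cohort <- function(seed = 11, n = 400, m = 300, s = 100, ...) {
  generate_cohort(sim_config(n_samples = n, n_probes = m, n_snps = s,
                             seed = seed, ...))
}

# cohort with no signal and no confounding: log CRP is pure noise
null_cohort <- function(seed = 13, n = 400, m = 200, s = 50) {
  eff <- c(bmi = 0, smoking = 0, alcohol = 0, deprivation = 0,
           education = 0, age = 0, sex = 0, cells = 0, batch = 0)
  generate_cohort(sim_config(n_samples = n, n_probes = m, n_snps = s,
                             var_dnam = 0, var_snp = 0,
                             confounder_effects = eff, seed = seed))
}

# minimal hand-built mixture_posterior for bookkeeping-level operations
fake_posterior <- function(beta, comp = NULL, class_id = NULL,
                           class_names = "methylation",
                           feature_names = NULL) {
  if (is.null(comp)) comp <- (beta != 0) * 1L
  if (is.null(feature_names))
    feature_names <- if (!is.null(rownames(beta))) rownames(beta)
                     else paste0("f", seq_len(nrow(beta)))
  if (is.null(class_id)) class_id <- rep(0L, nrow(beta))
  rownames(beta) <- rownames(comp) <- feature_names
  structure(list(beta = beta, comp = comp, sigma2e = rep(1, ncol(beta)),
                 pi = list(), feature_names = feature_names,
                 class_id = class_id, class_names = class_names,
                 chain = rep(1L, ncol(beta)),
                 config = desk_mixture_config()),
            class = "mixture_posterior")
}

# minimal meth_set
fake_meth <- function(beta, pos, chr = NULL, ids = NULL) {
  m <- ncol(beta)
  if (is.null(chr)) chr <- rep("chr1", m)
  if (is.null(ids)) ids <- colnames(beta)
  structure(list(sample_ids = rownames(beta), probe_ids = ids, beta = beta,
                 probe_chr = chr, probe_pos = pos, array_tag = "toy"),
            class = "meth_set")
}
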