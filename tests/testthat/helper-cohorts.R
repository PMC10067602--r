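# Shared cohort builders for tests. All deterministic given a seed.

# Cohort with a configurable number of planted pairs among decoy genes.
planted_cohort <- function(n = 400, coefs = 1.0, n_genes = 20, seed = 1,
                           censoring = 0.3, subtypes = 1, shift = 0) {
  k <- length(coefs)
  stopifnot(n_genes >= 2 * k + 2)
  pp <- if (k > 0) {
    data.frame(gene_a = sprintf("G%03d", seq(1, 2 * k, by = 2)),
               gene_b = sprintf("G%03d", seq(2, 2 * k, by = 2)),
               coefficient = coefs)
  } else NULL
  simulate_cohort(sim_config(
    n_samples = n, n_genes = n_genes,
    n_signature_genes = max(2, min(n_genes, 10)),
    n_subtypes = subtypes, subtype_shift = shift,
    planted_pairs = pp, censoring_target = censoring, seed = seed
  ))
}

# Simple uncensored exponential two-group survival frame.
exp_surv <- function(n_per_group, hr, seed) {
  set.seed(seed)
  data.frame(
    sample = sprintf("P%03d", seq_len(2 * n_per_group)),
    time = c(rexp(n_per_group, 1), rexp(n_per_group, hr)),
    event = 1L,
    group = rep(c("a", "b"), each = n_per_group)
  )
}

# Well-separated 3-class blobs as a genes x samples matrix.
blob_data <- function(n_per_class = 30, n_genes = 12, sep = 4, seed = 1) {
  set.seed(seed)
  centers <- matrix(rnorm(3 * n_genes), nrow = 3) * sep
  labels <- rep(1:3, each = n_per_class)
  x <- t(centers[labels, ] + matrix(rnorm(length(labels) * n_genes),
                                    ncol = n_genes))
  dimnames(x) <- list(paste0("B", seq_len(n_genes)),
                      sprintf("S%03d", seq_along(labels)))
  list(expr = x, labels = labels)
}
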