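#' Configure a synthetic survival cohort
#'
#' Describes the statistical structure the downstream analysis assumes: a
#' few hundred samples from a small number of expression subtypes, a
#' signature-gene block carrying the subtype signal, a handful of planted
#' prognostic gene pairs driving survival through a Weibull
#' proportional-hazards model, independent censoring calibrated to a target
#' rate, and an optional per-sample distortion standing in for
#' platform/batch effects.
#'
#' Defaults emulate a colon-cancer style cohort: 400 samples, 200 genes of
#' which 66 form the prognostic signature, 3 subtypes with proportions
#' 0.48/0.42/0.10 (the uneven split seen in published colon-cancer
#' consensus clusters), subtype mean shifts of 1.5 log-units on signature
#' genes, a Weibull baseline with shape 1.2 and scale 1500 days (median
#' survival around 4 years), and a 40% censoring target.
#'
#' @param n_samples,n_genes Cohort dimensions.
#' @param n_signature_genes Number of signature genes (first
#'   `n_signature_genes` gene ids); must not exceed `n_genes`.
#' @param n_subtypes Number of planted expression subtypes.
#' @param subtype_proportions Simplex vector of length `n_subtypes`
#'   (`NULL`: 0.48/0.42/0.10 for 3 subtypes, uniform otherwise).
#' @param subtype_shift Log-scale magnitude of the per-subtype mean shifts
#'   applied to signature genes (0 removes the subtype signal).
#' @param planted_pairs Data frame with columns `gene_a`, `gene_b`,
#'   `coefficient`: the true log hazard ratios attached to the pair
#'   indicators. Empty (default) gives a null cohort.
#' @param baseline_shape,baseline_scale Weibull baseline hazard parameters
#'   (shape k > 0, scale lambda > 0, in days).
#' @param censoring_target Target censored fraction, strictly inside (0, 1).
#' @param batch_distortion One of `"none"`, `"per-sample-monotone"`
#'   (a random strictly increasing map `a * x^b + c`, a,b > 0, per sample)
#'   or `"additive-shift"` (a random per-sample constant added).
#' @param seed Integer seed; the whole cohort is a deterministic function
#'   of the configuration.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_samples = 400L, n_genes = 200L,
                       n_signature_genes = 66L, n_subtypes = 3L,
                       subtype_proportions = NULL, subtype_shift = 1.5,
                       planted_pairs = NULL,
                       baseline_shape = 1.2, baseline_scale = 1500,
                       censoring_target = 0.4,
                       batch_distortion = c("none", "per-sample-monotone",
                                            "additive-shift"),
                       seed = 1L) {
  batch_distortion <- match.arg(batch_distortion)
  n_samples <- as.integer(n_samples); n_genes <- as.integer(n_genes)
  n_signature_genes <- as.integer(n_signature_genes)
  n_subtypes <- as.integer(n_subtypes)
  stopifnot(n_samples >= 2L, n_genes >= 2L,
            n_signature_genes >= 1L, n_signature_genes <= n_genes,
            n_subtypes >= 1L, baseline_shape > 0, baseline_scale > 0)
  if (!(censoring_target > 0 && censoring_target < 1)) {
    stop("censoring_target must be strictly inside (0, 1)")
  }
  if (is.null(subtype_proportions)) {
    subtype_proportions <- if (n_subtypes == 3L) c(0.48, 0.42, 0.10) else
      rep(1 / n_subtypes, n_subtypes)
  }
  if (length(subtype_proportions) != n_subtypes ||
      abs(sum(subtype_proportions) - 1) > 1e-9 || any(subtype_proportions <= 0)) {
    stop("subtype_proportions must be a positive simplex vector of length n_subtypes")
  }
  gene_ids <- sprintf("G%03d", seq_len(n_genes))
  if (is.null(planted_pairs)) {
    planted_pairs <- data.frame(gene_a = character(0), gene_b = character(0),
                                coefficient = numeric(0), stringsAsFactors = FALSE)
  }
  planted_pairs <- as.data.frame(planted_pairs, stringsAsFactors = FALSE)
  if (nrow(planted_pairs) > 0L) {
    stopifnot(all(c("gene_a", "gene_b", "coefficient") %in% colnames(planted_pairs)))
    missing_genes <- setdiff(unique(c(planted_pairs$gene_a, planted_pairs$gene_b)),
                             gene_ids)
    if (length(missing_genes) > 0L) {
      stop("planted pair gene(s) not among the simulated gene ids: ",
           paste(missing_genes, collapse = ", "))
    }
    if (!all(is.finite(planted_pairs$coefficient))) {
      stop("planted coefficients must be finite")
    }
  }
  structure(list(n_samples = n_samples, n_genes = n_genes,
                 n_signature_genes = n_signature_genes,
                 n_subtypes = n_subtypes,
                 subtype_proportions = subtype_proportions,
                 subtype_shift = subtype_shift,
                 planted_pairs = planted_pairs,
                 baseline_shape = baseline_shape,
                 baseline_scale = baseline_scale,
                 censoring_target = censoring_target,
                 batch_distortion = batch_distortion,
                 seed = as.integer(seed), gene_ids = gene_ids),
            class = "sim_config")
}

# Calibrate an exponential censoring rate by bisection so that the realized
# censored fraction (given fixed event times and fixed uniform draws for the
# censoring quantiles) hits the target. The realized fraction is monotone
# non-decreasing in the rate, so bisection on log-rate converges.
calibrate_censoring <- function(event_times, u_cens, target, tol = 0.01) {
  frac <- function(rate) mean((-log(u_cens) / rate) < event_times)
  lo <- 1e-12; hi <- 1e6
  if (frac(hi) < target || frac(lo) > target) {
    stop("censoring target not attainable for these event times")
  }
  for (i in seq_len(200L)) {
    mid <- sqrt(lo * hi)
    if (frac(mid) < target) lo <- mid else hi <- mid
    if (abs(frac(mid) - target) <= tol) break
  }
  mid
}

#' Simulate a cohort with planted subtypes and prognostic gene pairs
#'
#' Generates expression, survival and ground truth from a [sim_config()]:
#' log-expression is normal with gene-specific baselines, subtype mean
#' shifts on the signature genes and unit residual noise (so expression is
#' log-normal: positive and right-skewed); each sample's true linear
#' predictor is the sum of planted coefficients times the observed pair
#' indicators; survival times follow a Weibull proportional-hazards model
#' with hazard `h0(t) * exp(eta)`; censoring is independent exponential
#' with its rate calibrated by bisection to the configured censored
#' fraction; an optional strictly increasing per-sample distortion is
#' applied to the expression values last (so the same seed with and
#' without distortion yields identical survival and truth).
#'
#' @param config A [sim_config()].
#' @return An object of class `sim_cohort`: list with `expression`
#'   (genes x samples matrix), `survival` (data frame `sample`, `time`,
#'   `event`), `true_subtype` (named integer vector), `true_eta`,
#'   `true_pair_indicators` (planted pairs x samples), `signature_genes`,
#'   `realized_censoring`, and the `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  restore <- local_seed(config$seed); on.exit(restore())
  n <- config$n_samples; p <- config$n_genes
  genes <- config$gene_ids
  samples <- sprintf("S%04d", seq_len(n))
  K <- config$n_subtypes

  subtype <- sample.int(K, n, replace = TRUE, prob = config$subtype_proportions)
  names(subtype) <- samples

  mu <- runif(p, 2, 8)                       # gene-specific log baselines
  # Planted pairs are meant to be learnable by a pipeline that only keeps
  # frequency-balanced pairs, so the two genes of a planted pair share a
  # baseline: the indicator then splits the cohort roughly in half.
  if (nrow(config$planted_pairs) > 0L) {
    mu[match(config$planted_pairs$gene_b, genes)] <-
      mu[match(config$planted_pairs$gene_a, genes)]
  }
  # Each subtype up-shifts its own block of signature genes (round-robin
  # assignment), the marker-gene structure subtype discovery relies on;
  # blocks make the subtypes equidistant in expression space.
  shift <- matrix(0, nrow = K, ncol = p)
  sig_idx <- seq_len(config$n_signature_genes)
  if (K > 1L && config$subtype_shift != 0) {
    block <- ((sig_idx - 1L) %% K) + 1L
    for (k in seq_len(K)) {
      shift[k, sig_idx[block == k]] <- config$subtype_shift
    }
  }
  logx <- matrix(rnorm(p * n), nrow = p, ncol = n) + mu +
    t(shift[subtype, , drop = FALSE])
  expr <- exp(logx)
  dimnames(expr) <- list(genes, samples)

  pp <- config$planted_pairs
  if (nrow(pp) > 0L) {
    true_ind <- (expr[pp$gene_a, , drop = FALSE] >
                   expr[pp$gene_b, , drop = FALSE]) * 1L
    rownames(true_ind) <- paste(pp$gene_a, pp$gene_b, sep = "|")
    eta <- as.vector(crossprod(true_ind, pp$coefficient))
  } else {
    true_ind <- matrix(0L, nrow = 0L, ncol = n,
                       dimnames = list(character(0), samples))
    eta <- rep(0, n)
  }
  names(eta) <- samples

  # Weibull PH: S(t | eta) = exp(-(t/scale)^shape * e^eta)
  u <- runif(n)
  t_event <- config$baseline_scale *
    (-log(u) / exp(eta))^(1 / config$baseline_shape)
  u_cens <- runif(n)
  rate <- calibrate_censoring(t_event, u_cens, config$censoring_target)
  t_cens <- -log(u_cens) / rate
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)

  if (config$batch_distortion == "per-sample-monotone") {
    a <- runif(n, 0.5, 2); b <- runif(n, 0.5, 2); cc <- runif(n, 0, 5)
    expr <- sweep(sweep(sweep(expr, 2, b, "^"), 2, a, "*"), 2, cc, "+")
  } else if (config$batch_distortion == "additive-shift") {
    cc <- runif(n, 0, 5)
    expr <- sweep(expr, 2, cc, "+")
  }

  structure(list(expression = expr,
                 survival = data.frame(sample = samples, time = time,
                                       event = event, stringsAsFactors = FALSE),
                 true_subtype = subtype,
                 true_eta = eta,
                 true_pair_indicators = true_ind,
                 signature_genes = genes[sig_idx],
                 realized_censoring = mean(event == 0L),
                 config = config),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("Simulated cohort: %d gene(s) x %d sample(s)\n",
              nrow(x$expression), ncol(x$expression)))
  cat(sprintf("  subtypes: %d, planted pairs: %d, censoring: %.1f%% (target %.0f%%)\n",
              x$config$n_subtypes, nrow(x$config$planted_pairs),
              100 * x$realized_censoring, 100 * x$config$censoring_target))
  cat(sprintf("  batch distortion: %s\n", x$config$batch_distortion))
  invisible(x)
}

#' Simulate per-sample somatic mutation calls
#'
#' Draws Poisson mutation counts per sample (rate `lambda`, optionally
#' per-sample) and assigns each mutation a random gene and a nonsynonymous
#' variant class, producing a MAF-lite style table for mutation-burden
#' analyses.
#'
#' @param sample_ids Character vector of samples.
#' @param lambda Expected mutation count per sample (scalar or per-sample).
#' @param genes Gene symbols to draw from.
#' @param seed Integer seed.
#' @return A data frame with columns `sample`, `gene`,
#'   `variant_classification`.
#' @export
simulate_mutations <- function(sample_ids, lambda = 100,
                               genes = sprintf("G%03d", 1:200), seed = 1L) {
  restore <- local_seed(seed); on.exit(restore())
  lambda <- rep_len(lambda, length(sample_ids))
  counts <- rpois(length(sample_ids), lambda)
  total <- sum(counts)
  data.frame(
    sample = rep(sample_ids, counts),
    gene = sample(genes, total, replace = TRUE),
    variant_classification = sample(maf_nonsynonymous, total, replace = TRUE),
    stringsAsFactors = FALSE
  )
}
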