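#' Single-sample gene-set enrichment scores
#'
#' Per-sample ssGSEA: genes are ranked by expression within each sample
#' and the enrichment score of a gene set is the running-sum integral of
#' the difference between the weighted in-set empirical CDF (weights
#' `rank^weight_exponent`) and the uniform out-of-set ECDF, walking the
#' ranked list from the most to the least expressed gene. Scores depend on
#' the expression values only through their within-sample ranks, so they
#' are invariant to any strictly increasing per-sample transform. Genes of
#' a set absent from the matrix are dropped with a warning; a set with no
#' genes in the matrix gets `NA` scores.
#'
#' @param expr Genes-by-samples expression matrix.
#' @param gene_sets Named list of gene symbol vectors (see [read_gmt()]).
#' @param weight_exponent Rank weighting exponent (default 0.25, the
#'   original ssGSEA choice).
#' @param normalize `"none"` (default) or `"minmax"` (divide all scores by
#'   the overall score range, a cross-sample normalisation).
#' @return A gene-set-by-sample numeric matrix of enrichment scores.
#' @export
ssgsea_score <- function(expr, gene_sets, weight_exponent = 0.25,
                         normalize = c("none", "minmax")) {
  normalize <- match.arg(normalize)
  stopifnot(is.matrix(expr), is.list(gene_sets), !is.null(names(gene_sets)))
  N <- nrow(expr)
  sets <- lapply(gene_sets, function(gs) {
    idx <- match(unique(gs), rownames(expr))
    idx[!is.na(idx)]
  })
  dropped <- vapply(gene_sets, function(gs) sum(!unique(gs) %in% rownames(expr)),
                    integer(1))
  if (any(dropped > 0L)) {
    warning(sprintf("dropped genes absent from the matrix in %d set(s): %s",
                    sum(dropped > 0L),
                    paste(names(gene_sets)[dropped > 0L], collapse = ", ")))
  }
  empty <- vapply(sets, length, integer(1)) == 0L
  if (any(empty)) {
    warning("gene set(s) with no genes in the matrix score NA: ",
            paste(names(gene_sets)[empty], collapse = ", "))
  }
  out <- matrix(NA_real_, nrow = length(gene_sets), ncol = ncol(expr),
                dimnames = list(names(gene_sets), colnames(expr)))
  for (s in seq_len(ncol(expr))) {
    r <- rank(expr[, s], ties.method = "average")
    ord <- order(-r, seq_len(N))        # most expressed first; stable on ties
    w <- r[ord]^weight_exponent
    for (k in seq_along(sets)) {
      if (empty[k]) next
      inset <- logical(N)
      inset[sets[[k]]] <- TRUE
      inset <- inset[ord]
      n_in <- sum(inset)
      if (n_in == N) { out[k, s] <- 0; next }   # degenerate: set = all genes
      p_in <- cumsum(w * inset) / sum(w[inset])
      p_out <- cumsum(!inset) / (N - n_in)
      out[k, s] <- sum(p_in - p_out)
    }
  }
  if (normalize == "minmax") {
    rng <- range(out, na.rm = TRUE)
    out <- out / (rng[2] - rng[1])
  }
  out
}

#' Tumour mutation burden per sample
#'
#' Counts, per sample, the mutation records whose variant classification
#' belongs to `counted_classes` (default: the conventional nonsynonymous
#' classes) and divides by the exome territory in megabases. The 38 Mb
#' default denominator is the conventional whole-exome size and is
#' configurable, as is the class list. Samples in `sample_roster` without
#' records get a burden of zero.
#'
#' @param mut Mutation table: data frame with `sample`, `gene`,
#'   `variant_classification` (see [read_maf_lite()]).
#' @param exome_size_mb Sequenced territory in megabases (> 0).
#' @param counted_classes Variant classes that count toward the burden.
#' @param sample_roster Optional character vector of samples to report
#'   (zero-filled); default: samples present in `mut`.
#' @return Data frame `sample`, `mutation_count`, `tmb`.
#' @export
compute_tmb <- function(mut, exome_size_mb = 38,
                        counted_classes = maf_nonsynonymous,
                        sample_roster = NULL) {
  stopifnot(is.data.frame(mut),
            all(c("sample", "variant_classification") %in% colnames(mut)))
  if (!(is.numeric(exome_size_mb) && exome_size_mb > 0)) {
    stop("exome_size_mb must be positive")
  }
  counted <- mut[mut$variant_classification %in% counted_classes, , drop = FALSE]
  if (is.null(sample_roster)) sample_roster <- unique(mut$sample)
  counts <- table(factor(counted$sample, levels = sample_roster))
  data.frame(sample = sample_roster,
             mutation_count = as.integer(counts),
             tmb = as.numeric(counts) / exome_size_mb,
             stringsAsFactors = FALSE)
}

#' Two-group and contingency comparisons
#'
#' The two comparison tests used around the risk groups: a two-sided
#' Wilcoxon rank-sum test (normal approximation with tie correction, no
#' continuity correction) for a numeric value split by two groups, or a
#' plain Pearson chi-square test (no Yates correction) when a contingency
#' table is supplied instead.
#'
#' @param values Numeric vector (ignored when `contingency` is given).
#' @param groups Two-level grouping aligned with `values`.
#' @param contingency Optional contingency table/matrix for the
#'   chi-square branch.
#' @return List with `method`, `statistic`, `p_value`.
#' @export
group_compare <- function(values = NULL, groups = NULL, contingency = NULL) {
  if (!is.null(contingency)) {
    ht <- suppressWarnings(chisq.test(as.matrix(contingency), correct = FALSE))
    return(list(method = "chi-square", statistic = unname(ht$statistic),
                p_value = ht$p.value))
  }
  stopifnot(!is.null(values), !is.null(groups), length(values) == length(groups))
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) != 2L) stop("need exactly two non-empty groups")
  tab <- table(droplevels(groups))
  if (any(tab == 0L)) stop("empty group")
  sp <- split(values, droplevels(groups))
  ht <- wilcox.test(sp[[1L]], sp[[2L]], exact = FALSE, correct = FALSE)
  list(method = "wilcoxon", statistic = unname(ht$statistic),
       p_value = ht$p.value)
}
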