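#' Enumerate all unordered gene pairs
#'
#' Emits every unordered pair of the supplied gene identifiers exactly once,
#' in canonical orientation (`gene_a` lexicographically before `gene_b`,
#' C-locale radix order so the orientation is platform-stable). For `n`
#' genes the result has `n * (n - 1) / 2` rows; 66 genes give 2,145 pairs.
#' The orientation is information-neutral: reversing a pair flips its
#' indicator, and the sign is absorbed by the downstream regression.
#'
#' @param gene_ids Character vector of at least two unique gene symbols.
#' @return A data frame with columns `gene_a`, `gene_b`.
#' @export
enumerate_pairs <- function(gene_ids) {
  gene_ids <- as.character(gene_ids)
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  }
  if (length(gene_ids) < 2L) stop("need at least two genes to form pairs")
  g <- sort(gene_ids, method = "radix")
  idx <- utils::combn(length(g), 2L)
  data.frame(gene_a = g[idx[1L, ]], gene_b = g[idx[2L, ]],
             stringsAsFactors = FALSE)
}

#' Encode within-sample gene-pair order indicators
#'
#' The pair feature "A|B" is 1 for a sample when gene A's expression
#' strictly exceeds gene B's in that sample, and 0 otherwise — ties fall in
#' the 0 branch. Because the indicator only compares two measurements taken
#' on the same sample, it is invariant to any strictly increasing per-sample
#' transform of the expression values (quantile normalisation, log, scaling
#' — the batch-robustness this encoding exists for).
#'
#' @param expr Numeric genes-by-samples matrix with rownames.
#' @param pairs Data frame with columns `gene_a`, `gene_b` (directed; see
#'   [enumerate_pairs()] for the canonical enumeration).
#' @return An object of class `pair_features`: a list with `pairs`,
#'   `sample_ids`, the integer 0/1 `indicators` matrix (pairs x samples,
#'   rownames `"A|B"`), and per-pair `frequency` of the 1 label.
#' @export
encode_pairs <- function(expr, pairs) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (!all(c("gene_a", "gene_b") %in% colnames(pairs))) {
    stop("pairs must have columns gene_a and gene_b")
  }
  missing_genes <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)), rownames(expr))
  if (length(missing_genes) > 0L) {
    stop("pair gene(s) absent from expression matrix: ",
         paste(missing_genes, collapse = ", "))
  }
  ind <- (expr[pairs$gene_a, , drop = FALSE] >
            expr[pairs$gene_b, , drop = FALSE]) * 1L
  storage.mode(ind) <- "integer"
  rownames(ind) <- paste(pairs$gene_a, pairs$gene_b, sep = "|")
  structure(list(pairs = pairs,
                 sample_ids = colnames(expr),
                 indicators = ind,
                 frequency = rowMeans(ind)),
            class = "pair_features")
}

#' Keep informative gene pairs
#'
#' Removes pairs whose 1-label frequency in the cohort is below `low` or
#' above `high`; a pair at exactly the bound survives (the removal rule is
#' strict: frequency < low or > high). Pairs with frequency near 0 or 1
#' order the same way in (almost) every sample and carry no classification
#' information. Pair order is preserved and the deleted count recorded.
#' Frequencies should be computed on the training cohort only; the
#' surviving pair list is then frozen and reused to encode test cohorts.
#'
#' @param pfm A `pair_features` object.
#' @param low,high Inclusive frequency bounds, `0 <= low < high <= 1`.
#' @return A filtered `pair_features` object with attribute `n_deleted`.
#' @export
filter_informative <- function(pfm, low = 0.2, high = 0.8) {
  stopifnot(inherits(pfm, "pair_features"))
  if (!(low >= 0 && low < high && high <= 1)) {
    stop("bounds must satisfy 0 <= low < high <= 1")
  }
  keep <- pfm$frequency >= low & pfm$frequency <= high
  out <- structure(list(pairs = pfm$pairs[keep, , drop = FALSE],
                        sample_ids = pfm$sample_ids,
                        indicators = pfm$indicators[keep, , drop = FALSE],
                        frequency = pfm$frequency[keep]),
                   class = "pair_features")
  attr(out, "n_deleted") <- sum(!keep)
  if (sum(keep) == 0L) {
    warning("no pairs survive the informative-frequency filter")
  }
  out
}

#' @export
print.pair_features <- function(x, ...) {
  cat(sprintf("Gene-pair feature matrix: %d pair(s) x %d sample(s)\n",
              nrow(x$indicators), length(x$sample_ids)))
  if (nrow(x$indicators) > 0L) {
    cat(sprintf("  1-label frequency: min %.3f, median %.3f, max %.3f\n",
                min(x$frequency), median(x$frequency), max(x$frequency)))
  }
  nd <- attr(x, "n_deleted")
  if (!is.null(nd)) cat(sprintf("  (%d pair(s) removed by frequency filter)\n", nd))
  invisible(x)
}

#' @export
`[.pair_features` <- function(x, i, ...) {
  structure(list(pairs = x$pairs[i, , drop = FALSE],
                 sample_ids = x$sample_ids,
                 indicators = x$indicators[i, , drop = FALSE],
                 frequency = x$frequency[i]),
            class = "pair_features")
}
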