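#' Consensus clustering with PAM over signature genes
#'
#' Repeated subsampled partitioning-around-medoids (Euclidean distance on
#' per-gene standardised expression) for each candidate `k`. The consensus
#' matrix entry for a sample pair is the fraction of co-subsampled runs in
#' which the two samples landed in the same cluster; final labels per `k`
#' come from an average-linkage hierarchical cut of `1 - consensus`. The
#' number of clusters is chosen from the consensus CDF: the proportion of
#' ambiguous consensus values (PAC, `CDF(0.9) - CDF(0.1)`) is computed per
#' k and the chosen k is the largest k that still clusters stably
#' (PAC at most 0.1), or the PAC minimiser when no k is stable; the CDF
#' area per k is also reported.
#'
#' @param expr Genes-by-samples expression matrix.
#' @param genes Signature genes to cluster on (default: all rows).
#' @param k_range Candidate cluster numbers (default 2:6).
#' @param reps Number of subsampled runs per k (default 1000).
#' @param subsample Fraction of samples drawn per run (default 0.8).
#' @param seed Integer seed.
#' @return An object of class `consensus_result`: list with `k_range`,
#'   `consensus` (one matrix per k), `labels` (samples x k_range),
#'   `cdf_area`, `pac`, `chosen_k` and `labels_chosen`.
#' @export
consensus_cluster <- function(expr, genes = NULL, k_range = 2:6,
                              reps = 1000L, subsample = 0.8, seed = 1L) {
  stopifnot(is.matrix(expr))
  if (is.null(genes)) genes <- rownames(expr)
  missing_genes <- setdiff(genes, rownames(expr))
  if (length(missing_genes) > 0L) {
    stop("signature gene(s) missing from expression matrix: ",
         paste(missing_genes, collapse = ", "))
  }
  n <- ncol(expr)
  k_range <- sort(unique(as.integer(k_range)))
  if (max(k_range) + 1L > n) stop("k_range exceeds the number of samples")
  x <- t(scale(t(expr[genes, , drop = FALSE])))   # z-scale genes
  x[!is.finite(x)] <- 0                            # constant genes carry no signal
  xs <- t(x)                                       # samples x genes
  m <- max(2L, floor(subsample * n))
  restore <- local_seed(seed); on.exit(restore())

  consensus <- vector("list", length(k_range))
  names(consensus) <- paste0("k", k_range)
  labels <- matrix(NA_integer_, nrow = n, ncol = length(k_range),
                   dimnames = list(colnames(expr), paste0("k", k_range)))
  cdf_area <- pac <- setNames(numeric(length(k_range)), paste0("k", k_range))

  for (kk in seq_along(k_range)) {
    k <- k_range[kk]
    conn <- matrix(0, n, n); both <- matrix(0, n, n)
    for (r in seq_len(reps)) {
      idx <- sample.int(n, m)
      cl <- cluster::pam(xs[idx, , drop = FALSE], k = k,
                         cluster.only = TRUE, pamonce = 5)
      same <- outer(cl, cl, "==") * 1
      conn[idx, idx] <- conn[idx, idx] + same
      both[idx, idx] <- both[idx, idx] + 1
    }
    cons <- conn / both
    cons[both == 0] <- NA
    diag(cons) <- 1
    dimnames(cons) <- list(colnames(expr), colnames(expr))
    consensus[[kk]] <- cons
    cons_filled <- cons
    cons_filled[is.na(cons_filled)] <- 0.5   # never co-sampled: uninformative
    hc <- hclust(as.dist(1 - cons_filled), method = "average")
    labels[, kk] <- cutree(hc, k = k)
    vals <- cons[upper.tri(cons)]
    vals <- vals[!is.na(vals)]
    cdf_area[kk] <- 1 - mean(vals)          # area under the consensus CDF
    pac[kk] <- mean(vals > 0.1 & vals < 0.9)
  }
  # A k at or below the truth clusters stably (low PAC) because the merges
  # are deterministic; any k above the truth forces arbitrary splits and
  # the consensus turns ambiguous. The chosen k is therefore the largest
  # stable k (PAC <= 0.1), falling back to the PAC minimum when no k is
  # stable.
  stable <- which(pac <= 0.1)
  chosen_k <- if (length(stable) > 0L) k_range[max(stable)] else
    k_range[which.min(pac)]
  structure(list(k_range = k_range, consensus = consensus, labels = labels,
                 cdf_area = cdf_area, pac = pac, chosen_k = chosen_k,
                 labels_chosen = setNames(labels[, paste0("k", chosen_k)],
                                          colnames(expr))),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("Consensus clustering (PAM, Euclidean)\n")
  tab <- data.frame(k = x$k_range, cdf_area = unname(x$cdf_area),
                    pac = unname(x$pac))
  print(tab, row.names = FALSE, digits = 3)
  cat(sprintf("  chosen k = %d; cluster sizes: %s\n", x$chosen_k,
              paste(table(x$labels_chosen), collapse = "/")))
  invisible(x)
}

#' Nearest-medoid subtype classifier
#'
#' `medoid_classifier_train` freezes per-gene standardisation constants
#' from the training cohort and stores, per class, the medoid — the
#' training sample minimising the summed Euclidean distance to its class
#' members (consistent with PAM). `medoid_classify` assigns a new sample
#' the label of its nearest medoid in the standardised space, breaking
#' exact ties by the lowest class index.
#'
#' @param expr Genes-by-samples training expression matrix.
#' @param labels Class labels, one per training sample.
#' @param genes Signature genes to use (default: all rows).
#' @return `medoid_classifier_train`: an object of class
#'   `medoid_classifier`. `medoid_classify`: a vector of predicted labels.
#' @export
medoid_classifier_train <- function(expr, labels, genes = NULL) {
  stopifnot(is.matrix(expr), length(labels) == ncol(expr))
  if (is.null(genes)) genes <- rownames(expr)
  labels <- as.factor(labels)
  if (any(table(labels) == 0L)) stop("every class must be non-empty")
  ctr <- rowMeans(expr[genes, , drop = FALSE])
  scl <- apply(expr[genes, , drop = FALSE], 1, sd)
  scl[scl == 0] <- 1
  xs <- t((expr[genes, , drop = FALSE] - ctr) / scl)   # samples x genes
  classes <- levels(labels)
  medoids <- matrix(NA_real_, nrow = length(classes), ncol = length(genes),
                    dimnames = list(classes, genes))
  medoid_sample <- character(length(classes))
  for (ci in seq_along(classes)) {
    members <- which(labels == classes[ci])
    d <- as.matrix(dist(xs[members, , drop = FALSE]))
    best <- members[which.min(rowSums(d))]
    medoids[ci, ] <- xs[best, ]
    medoid_sample[ci] <- colnames(expr)[best]
  }
  structure(list(genes = genes, center = ctr, scale = scl,
                 medoids = medoids, classes = classes,
                 medoid_sample = medoid_sample),
            class = "medoid_classifier")
}

#' @rdname medoid_classifier_train
#' @param clf A `medoid_classifier`.
#' @param new_expr Genes-by-samples matrix to classify.
#' @export
medoid_classify <- function(clf, new_expr) {
  stopifnot(inherits(clf, "medoid_classifier"), is.matrix(new_expr))
  missing_genes <- setdiff(clf$genes, rownames(new_expr))
  if (length(missing_genes) > 0L) {
    stop("signature gene(s) missing from new data: ",
         paste(missing_genes, collapse = ", "))
  }
  xs <- t((new_expr[clf$genes, , drop = FALSE] - clf$center) / clf$scale)
  d2 <- outer(rowSums(xs^2), rowSums(clf$medoids^2), "+") -
    2 * xs %*% t(clf$medoids)
  idx <- apply(d2, 1, which.min)    # which.min takes the first (lowest) index on ties
  setNames(clf$classes[idx], colnames(new_expr))
}

#' @export
print.medoid_classifier <- function(x, ...) {
  cat(sprintf("Nearest-medoid classifier: %d class(es) over %d gene(s)\n",
              length(x$classes), length(x$genes)))
  cat("  medoid samples:", paste(x$medoid_sample, collapse = ", "), "\n")
  invisible(x)
}

#' Compare subtype classifiers by survival separation
#'
#' Classifies a test cohort with both classifiers, runs a log-rank test
#' across the predicted labels of each, and reports the winner (the
#' smaller p-value; a tie goes to the first classifier). A classifier
#' whose predictions collapse to a single class is reported as not
#' evaluable rather than crashing.
#'
#' @param clf_a,clf_b Trained classifiers (`medoid_classifier` or
#'   `mlp_classifier`), trained on the same signature genes.
#' @param test_expr Genes-by-samples test expression matrix.
#' @param test_survival Data frame with `sample`, `time`, `event` covering
#'   the test samples.
#' @return List with per-classifier predicted labels and log-rank p, and
#'   `winner` (1, 2 or `NA` when neither is evaluable).
#' @export
compare_classifiers <- function(clf_a, clf_b, test_expr, test_survival) {
  classify <- function(clf) {
    if (inherits(clf, "medoid_classifier")) medoid_classify(clf, test_expr)
    else if (inherits(clf, "mlp_classifier")) predict(clf, test_expr)
    else stop("unsupported classifier class")
  }
  surv <- test_survival[match(colnames(test_expr), test_survival$sample), ]
  if (anyNA(surv$time)) stop("test sample(s) without survival records")
  eval_one <- function(labels) {
    if (length(unique(labels)) < 2L) {
      return(list(labels = labels, p_value = NA_real_,
                  note = "not evaluable: single predicted class"))
    }
    lr <- logrank_test(surv, labels)
    list(labels = labels, p_value = lr$p_value, chi_square = lr$chi_square)
  }
  a <- eval_one(classify(clf_a))
  b <- eval_one(classify(clf_b))
  winner <- if (is.na(a$p_value) && is.na(b$p_value)) NA_integer_
    else if (is.na(b$p_value)) 1L
    else if (is.na(a$p_value)) 2L
    else if (a$p_value <= b$p_value) 1L else 2L
  list(classifier_a = a, classifier_b = b, winner = winner,
       tie = isTRUE(a$p_value == b$p_value))
}
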