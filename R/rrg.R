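#' Differential expression between two groups
#'
#' Moderated two-group test with empirical-Bayes variance shrinkage
#' (limma's linear-model machinery) and Benjamini-Hochberg adjustment;
#' genes are flagged as differential at adjusted p below the threshold.
#' Genes constant within both groups cannot be tested and get p = 1 with
#' a warning.
#'
#' @param expr Genes-by-samples expression matrix (assumed on a roughly
#'   log-like scale, used as-is).
#' @param groups Two-level grouping, one label per sample.
#' @param adj_p_threshold DEG flag threshold on the adjusted p (default
#'   0.01).
#' @return Data frame per gene: `gene`, `effect` (group mean difference),
#'   `t`, `p_value`, `adj_p`, `deg`.
#' @export
differential_expression <- function(expr, groups, adj_p_threshold = 0.01) {
  stopifnot(is.matrix(expr), length(groups) == ncol(expr))
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2L) stop("need exactly two groups")
  if (any(table(groups) < 2L)) stop("each group needs at least two samples")
  within_var <- vapply(seq_len(nrow(expr)), function(i) {
    max(tapply(expr[i, ], groups, var))
  }, numeric(1))
  constant <- within_var == 0
  p <- rep(NA_real_, nrow(expr)); tt <- rep(NA_real_, nrow(expr))
  eff <- rep(NA_real_, nrow(expr))
  if (any(!constant)) {
    design <- model.matrix(~groups)
    fit <- limma::lmFit(expr[!constant, , drop = FALSE], design)
    fit <- limma::eBayes(fit)
    p[!constant] <- fit$p.value[, 2L]
    tt[!constant] <- fit$t[, 2L]
    eff[!constant] <- fit$coefficients[, 2L]
  }
  if (any(constant)) {
    warning(sprintf("%d zero-variance gene(s) set to p = 1", sum(constant)))
    p[constant] <- 1; tt[constant] <- 0
    eff[constant] <- vapply(which(constant), function(i) {
      diff(rev(tapply(expr[i, ], groups, mean)))
    }, numeric(1))
  }
  adj <- p.adjust(p, method = "BH")
  data.frame(gene = rownames(expr), effect = eff, t = tt, p_value = p,
             adj_p = adj, deg = adj < adj_p_threshold,
             stringsAsFactors = FALSE)
}

#' Risk-related gene selection by LASSO / random-forest intersection
#'
#' Two independent selectors regress a per-sample risk target on the
#' expression of candidate (differentially expressed) genes: (a) an
#' L1-penalised regression with the penalty chosen by cross-validated
#' error at its minimiser, keeping the genes with nonzero coefficients;
#' (b) a random-forest regression whose feature count is chosen by
#' minimising cross-validated RMSE over importance-ranked gene subsets.
#' The final risk-related genes are the intersection of the two
#' selections; an empty intersection is a valid (logged) outcome.
#'
#' @param expr Genes-by-samples matrix restricted to the candidate genes
#'   (at least two).
#' @param target Per-sample risk target. The default analysis regresses
#'   on the continuous risk linear predictor; a binary 0/1 group label is
#'   also accepted via `mode = "binary"` (logistic LASSO,
#'   classification forest).
#' @param seed Integer seed (fold splits and forests).
#' @param mode `"continuous"` (default) or `"binary"`.
#' @param n_folds Cross-validation folds (default 5).
#' @param rf_trees Trees for the importance forest (default 500).
#' @return An object of class `rrg_result`: list with `lasso_selected`,
#'   `rf_selected`, `final`, the per-size RF cross-validation table
#'   `rf_cv`, the ranked `rf_importance`, and the chosen `lambda`.
#' @export
select_rrg <- function(expr, target, seed = 1L,
                       mode = c("continuous", "binary"),
                       n_folds = 5L, rf_trees = 500L) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(expr), length(target) == ncol(expr))
  if (nrow(expr) < 2L) stop("need at least two candidate genes")
  x <- t(expr)
  restore <- local_seed(seed); on.exit(restore())

  # (a) L1-penalised regression, lambda by CV at the error minimiser
  fam <- if (mode == "binary") "binomial" else "gaussian"
  yy <- if (mode == "binary") factor(target) else as.numeric(target)
  foldid <- sample(rep_len(seq_len(n_folds), ncol(expr)))
  cv <- glmnet::cv.glmnet(x, yy, family = fam, alpha = 1, foldid = foldid)
  beta <- as.matrix(coef(cv, s = "lambda.min"))
  lasso_selected <- rownames(beta)[-1L][beta[-1L, 1L] != 0]

  # (b) random forest: permutation importance ranking, then subset size
  # by cross-validated RMSE (misclassification rate in binary mode)
  rf_full <- randomForest::randomForest(x, yy, ntree = rf_trees,
                                        importance = TRUE)
  imp <- randomForest::importance(rf_full, type = 1L)[, 1L]
  ranked <- names(sort(imp, decreasing = TRUE))
  sizes <- unique(pmin(nrow(expr),
                       c(1L, 2L, 3L, 5L, 8L, 12L, 18L, 25L, nrow(expr))))
  cv_err <- vapply(sizes, function(m) {
    genes_m <- ranked[seq_len(m)]
    errs <- vapply(seq_len(n_folds), function(f) {
      tr <- foldid != f
      fit <- randomForest::randomForest(x[tr, genes_m, drop = FALSE],
                                        if (mode == "binary") yy[tr] else yy[tr],
                                        ntree = 200L)
      pred <- predict(fit, x[!tr, genes_m, drop = FALSE])
      if (mode == "binary") mean(pred != yy[!tr])
      else sqrt(mean((as.numeric(pred) - yy[!tr])^2))
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  m_best <- sizes[which.min(cv_err)]
  rf_selected <- ranked[seq_len(m_best)]

  final <- intersect(lasso_selected, rf_selected)
  if (length(final) == 0L) message("empty intersection: no risk-related genes")
  structure(list(lasso_selected = lasso_selected, rf_selected = rf_selected,
                 final = final,
                 rf_cv = data.frame(size = sizes, cv_error = cv_err),
                 rf_importance = imp[ranked], lambda = cv$lambda.min,
                 mode = mode),
            class = "rrg_result")
}

#' @export
print.rrg_result <- function(x, ...) {
  cat(sprintf("Risk-related gene selection (%s target)\n", x$mode))
  cat(sprintf("  LASSO: %d gene(s); random forest: %d gene(s); intersection: %d\n",
              length(x$lasso_selected), length(x$rf_selected), length(x$final)))
  if (length(x$final) > 0L) cat("  final:", paste(x$final, collapse = ", "), "\n")
  invisible(x)
}
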