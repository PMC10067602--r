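new_mkpc <- function(terms, cutoff, funnel = NULL, screen = NULL,
                     pairs_informative = NULL, train_scores = NULL,
                     metadata = list()) {
  stopifnot(is.data.frame(terms),
            all(c("gene_a", "gene_b", "coefficient") %in% colnames(terms)))
  if (anyDuplicated(paste(terms$gene_a, terms$gene_b, sep = "|"))) {
    stop("model terms must be unique gene pairs")
  }
  if (nrow(terms) > 0L && !all(is.finite(terms$coefficient))) {
    stop("model coefficients must be finite")
  }
  if (!(is.numeric(cutoff) && length(cutoff) == 1L && cutoff > 0)) {
    stop("cutoff must be a single positive number (it thresholds an exponential)")
  }
  structure(list(terms = terms, cutoff = cutoff, funnel = funnel,
                 screen = screen, pairs_informative = pairs_informative,
                 train_scores = train_scores, metadata = metadata),
            class = "mkpc")
}

align_survival <- function(pfm, survival) {
  stopifnot(inherits(pfm, "pair_features"), is.data.frame(survival),
            all(c("sample", "time", "event") %in% colnames(survival)))
  idx <- match(pfm$sample_ids, survival$sample)
  if (anyNA(idx)) {
    stop("sample(s) without survival records: ",
         paste(head(pfm$sample_ids[is.na(idx)], 5L), collapse = ", "))
  }
  survival[idx, , drop = FALSE]
}

#' Univariate proportional-hazards screen of pair features
#'
#' Fits one single-covariate Cox model (Breslow tie handling) per gene
#' pair and flags pairs with Wald p below `alpha`. Pairs with zero
#' variance across samples cannot be fit and are skipped with a warning
#' (they cannot occur after [filter_informative()], but are guarded).
#'
#' @param pfm A `pair_features` object.
#' @param survival Data frame with `sample`, `time`, `event` covering the
#'   samples of `pfm`.
#' @param alpha Wald p-value threshold (default 0.05).
#' @return A data frame, one row per pair: `gene_a`, `gene_b`, `pair`,
#'   `coefficient`, `hr`, `se`, `p_value`, `pass`.
#' @export
univariate_screen <- function(pfm, survival, alpha = 0.05) {
  surv <- align_survival(pfm, survival)
  if (sum(surv$event) < 2L) stop("need at least two observed events")
  y <- survival::Surv(surv$time, surv$event)
  ctrl <- survival::coxph.control()
  np <- nrow(pfm$indicators)
  coefs <- ses <- ps <- rep(NA_real_, np)
  skipped <- logical(np)
  for (i in seq_len(np)) {
    x <- pfm$indicators[i, ]
    if (var(x) == 0) { skipped[i] <- TRUE; next }
    fit <- survival::coxph.fit(matrix(as.numeric(x), ncol = 1L), y,
                               strata = NULL, offset = NULL, init = 0,
                               control = ctrl, weights = NULL,
                               method = "breslow", rownames = NULL)
    coefs[i] <- fit$coefficients[1L]
    ses[i] <- sqrt(fit$var[1L, 1L])
    ps[i] <- 2 * pnorm(-abs(coefs[i] / ses[i]))
  }
  if (any(skipped)) {
    warning(sprintf("%d zero-variance pair(s) skipped", sum(skipped)))
  }
  out <- data.frame(gene_a = pfm$pairs$gene_a, gene_b = pfm$pairs$gene_b,
                    pair = rownames(pfm$indicators),
                    coefficient = coefs, hr = exp(coefs), se = ses,
                    p_value = ps,
                    pass = !is.na(ps) & ps < alpha,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' L1-penalised Cox selection of pair features
#'
#' Fits an L1-penalised Cox model over the supplied pairs with the penalty
#' chosen by cross-validated partial likelihood at its maximiser (the
#' `lambda.min` convention) and returns the pairs with nonzero
#' coefficients. The fold assignment is drawn deterministically from
#' `seed`; if a fold ends up without any event the split is redrawn (up to
#' five attempts) before giving up. A single-pair input is returned as-is:
#' the penalty path cannot meaningfully zero the only feature.
#'
#' @param pfm A `pair_features` object (typically restricted to the pairs
#'   that passed [univariate_screen()]).
#' @param survival Data frame with `sample`, `time`, `event`.
#' @param n_folds Number of cross-validation folds (default 10).
#' @param seed Integer seed for the fold split.
#' @return Data frame of selected pairs (`gene_a`, `gene_b`), attribute
#'   `lambda` carrying the chosen penalty.
#' @export
lasso_select <- function(pfm, survival, n_folds = 10L, seed = 1L) {
  surv <- align_survival(pfm, survival)
  np <- nrow(pfm$indicators)
  if (np < 1L) stop("need at least one pair")
  if (np == 1L) {
    out <- pfm$pairs
    attr(out, "lambda") <- NA_real_
    return(out)
  }
  n <- length(pfm$sample_ids)
  n_folds <- min(as.integer(n_folds), n)
  restore <- local_seed(seed); on.exit(restore())
  foldid <- NULL
  for (attempt in seq_len(5L)) {
    cand <- sample(rep_len(seq_len(n_folds), n))
    ok <- all(tapply(surv$event, cand, sum) >= 1L)
    if (ok) { foldid <- cand; break }
  }
  if (is.null(foldid)) stop("could not build folds with at least one event each")
  x <- t(pfm$indicators)
  y <- survival::Surv(surv$time, surv$event)
  cv <- glmnet::cv.glmnet(x, y, family = "cox", alpha = 1, foldid = foldid)
  beta <- as.vector(coef(cv, s = "lambda.min"))
  keep <- which(beta != 0)
  out <- pfm$pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "lambda") <- cv$lambda.min
  out
}

#' Multivariate Cox assembly of a pair risk model
#'
#' Jointly fits the selected pairs in a Cox model (Breslow ties), performs
#' one backward-elimination step — pairs whose multivariate Wald p is at or
#' above `keep_alpha` are dropped and the model refit once — and freezes
#' the risk cutoff at the median risk score of the training cohort. If no
#' pair survives, an empty model is returned with a message rather than an
#' error.
#'
#' @param selected_pairs Data frame `gene_a`, `gene_b` (from
#'   [lasso_select()]).
#' @param pfm The training `pair_features` object (must contain the
#'   selected pairs).
#' @param survival Data frame with `sample`, `time`, `event`.
#' @param keep_alpha Wald p threshold for the single backward step.
#' @return An object of class `mkpc`.
#' @export
multivariate_fit <- function(selected_pairs, pfm, survival, keep_alpha = 0.05) {
  surv <- align_survival(pfm, survival)
  labels <- paste(selected_pairs$gene_a, selected_pairs$gene_b, sep = "|")
  missing_pairs <- setdiff(labels, rownames(pfm$indicators))
  if (length(missing_pairs) > 0L) {
    stop("selected pair(s) absent from feature matrix: ",
         paste(missing_pairs, collapse = ", "))
  }
  y <- survival::Surv(surv$time, surv$event)
  fit_once <- function(labs) {
    x <- t(pfm$indicators[labs, , drop = FALSE])
    fit <- survival::coxph(y ~ x, ties = "breslow",
                           control = survival::coxph.control(iter.max = 100))
    if (!is.null(fit$fail)) stop("multivariate Cox fit failed: ", fit$fail)
    beta <- coef(fit)
    se <- sqrt(diag(fit$var))
    p <- 2 * pnorm(-abs(beta / se))
    list(beta = unname(beta), se = unname(se), p = unname(p))
  }
  empty_model <- function() {
    message("no prognostic pairs: returning an empty model")
    new_mkpc(terms = data.frame(gene_a = character(0), gene_b = character(0),
                                coefficient = numeric(0), stringsAsFactors = FALSE),
             cutoff = 1,
             metadata = list(source = "trained", note = "no prognostic pairs"))
  }
  if (length(labels) == 0L) return(empty_model())
  f1 <- fit_once(labels)
  keep <- f1$p < keep_alpha
  if (!any(keep)) return(empty_model())
  if (!all(keep)) {
    labels <- labels[keep]
    f1 <- fit_once(labels)
  }
  idx <- match(labels, paste(pfm$pairs$gene_a, pfm$pairs$gene_b, sep = "|"))
  terms <- data.frame(gene_a = pfm$pairs$gene_a[idx],
                      gene_b = pfm$pairs$gene_b[idx],
                      coefficient = f1$beta, stringsAsFactors = FALSE)
  ls <- as.vector(crossprod(pfm$indicators[labels, , drop = FALSE], f1$beta))
  cutoff <- median(exp(ls))
  new_mkpc(terms = terms, cutoff = cutoff,
           screen = data.frame(pair = labels, coefficient = f1$beta,
                               se = f1$se, p_value = f1$p,
                               stringsAsFactors = FALSE),
           train_scores = data.frame(sample = pfm$sample_ids,
                                     linear_sum = ls, mkpc_score = exp(ls),
                                     stringsAsFactors = FALSE),
           metadata = list(source = "trained"))
}

#' Fit a gene-pair prognostic risk model
#'
#' The full model-building funnel on a training cohort: enumerate all
#' gene pairs, encode the within-sample order indicators, remove
#' uninformative pairs (1-label frequency outside `[low, high]`), screen
#' each pair with a univariate Cox model, reduce the survivors with
#' L1-penalised Cox regression (penalty by `n_folds`-fold cross-validated
#' partial likelihood), and assemble the final model with a multivariate
#' Cox fit plus one backward-elimination step. The risk score of a sample
#' is `exp(sum of coefficient * indicator)` and the high/low risk cutoff
#' is the median training score.
#'
#' @param x A genes-by-samples expression matrix, or a `pair_features`
#'   object (in which case enumeration/encoding is skipped).
#' @param survival Data frame with `sample`, `time`, `event`.
#' @param genes Optional subset of genes to pair (defaults to all rows of
#'   the expression matrix).
#' @param low,high Informative-frequency bounds (default 0.2 / 0.8).
#' @param alpha Univariate screen threshold (default 0.05).
#' @param n_folds Cross-validation folds for the penalty choice.
#' @param keep_alpha Multivariate backward-step threshold.
#' @param seed Integer seed (drives the cross-validation split).
#' @return An object of class `mkpc` with components `terms` (pair
#'   coefficients), `cutoff`, `funnel` (feature counts at every reduction
#'   step), `screen` (univariate screen table), `pairs_informative` (the
#'   frozen training pair list used to encode test cohorts),
#'   `train_scores`, and `metadata`.
#' @seealso [predict.mkpc()], [score_mkpc()], [published_mkpc()],
#'   [write_model()]
#' @examples
#' cohort <- make_worked_fixture()
#' pfm <- encode_pairs(cohort$expression, enumerate_pairs(rownames(cohort$expression)))
#' pfm <- filter_informative(pfm)
#' @export
mkpc <- function(x, survival, genes = NULL, low = 0.2, high = 0.8,
                 alpha = 0.05, n_folds = 10L, keep_alpha = 0.05, seed = 1L) {
  if (inherits(x, "pair_features")) {
    pfm_all <- x
    n_enum <- nrow(pfm_all$pairs)
  } else {
    stopifnot(is.matrix(x))
    if (is.null(genes)) genes <- rownames(x)
    pairs <- enumerate_pairs(genes)
    pfm_all <- encode_pairs(x, pairs)
    n_enum <- nrow(pairs)
  }
  pfm <- filter_informative(pfm_all, low = low, high = high)
  funnel <- c(enumerated = n_enum, informative = nrow(pfm$pairs),
              screened = NA_integer_, selected = NA_integer_,
              final = NA_integer_)
  empty <- function(funnel) {
    message("no prognostic pairs: returning an empty model")
    m <- new_mkpc(terms = data.frame(gene_a = character(0),
                                     gene_b = character(0),
                                     coefficient = numeric(0),
                                     stringsAsFactors = FALSE),
                  cutoff = 1, funnel = funnel,
                  metadata = list(source = "trained",
                                  note = "no prognostic pairs"))
    m
  }
  if (nrow(pfm$pairs) == 0L) return(empty(funnel))
  screen <- univariate_screen(pfm, survival, alpha = alpha)
  funnel["screened"] <- sum(screen$pass)
  if (!any(screen$pass)) return(empty(funnel))
  pfm_pass <- pfm[which(screen$pass)]
  selected <- lasso_select(pfm_pass, survival, n_folds = n_folds, seed = seed)
  funnel["selected"] <- nrow(selected)
  if (nrow(selected) == 0L) return(empty(funnel))
  model <- multivariate_fit(selected, pfm, survival, keep_alpha = keep_alpha)
  funnel["final"] <- nrow(model$terms)
  model$funnel <- funnel
  model$pairs_informative <- pfm$pairs
  model$screen_univariate <- screen
  model$metadata <- c(model$metadata,
                      list(alpha = alpha, n_folds = n_folds,
                           keep_alpha = keep_alpha, low = low, high = high,
                           seed = seed, lambda = attr(selected, "lambda")))
  model
}

#' Score samples with a pair risk model
#'
#' Computes, per sample, the linear sum of model coefficients times pair
#' indicators, the risk score `exp(linear_sum)`, and the risk group
#' (`high` when the score strictly exceeds the model cutoff). Scoring is
#' deterministic and — because the indicators compare genes within a
#' sample — invariant to any strictly increasing per-sample transform of
#' the expression values.
#'
#' @param model An `mkpc` object.
#' @param newdata A genes-by-samples expression matrix (the model's term
#'   genes must all be present; missing genes are an error, never silently
#'   imputed) or a `pair_features` object containing the model's pairs.
#' @return A data frame: `sample`, `linear_sum`, `mkpc_score`,
#'   `risk_group`.
#' @export
score_mkpc <- function(model, newdata) {
  stopifnot(inherits(model, "mkpc"))
  if (inherits(newdata, "pair_features")) {
    labels <- paste(model$terms$gene_a, model$terms$gene_b, sep = "|")
    missing_pairs <- setdiff(labels, rownames(newdata$indicators))
    if (length(missing_pairs) > 0L) {
      stop("model pair(s) absent from feature matrix: ",
           paste(missing_pairs, collapse = ", "))
    }
    ind <- newdata$indicators[labels, , drop = FALSE]
    samples <- newdata$sample_ids
  } else {
    stopifnot(is.matrix(newdata))
    need <- unique(c(model$terms$gene_a, model$terms$gene_b))
    missing_genes <- setdiff(need, rownames(newdata))
    if (length(missing_genes) > 0L) {
      stop("gene(s) required by the model are missing: ",
           paste(missing_genes, collapse = ", "))
    }
    ind <- (newdata[model$terms$gene_a, , drop = FALSE] >
              newdata[model$terms$gene_b, , drop = FALSE]) * 1L
    samples <- colnames(newdata)
  }
  ls <- if (nrow(model$terms) == 0L) rep(0, length(samples)) else
    as.vector(crossprod(ind, model$terms$coefficient))
  score <- exp(ls)
  data.frame(sample = samples, linear_sum = ls, mkpc_score = score,
             risk_group = ifelse(score > model$cutoff, "high", "low"),
             stringsAsFactors = FALSE)
}

#' @rdname score_mkpc
#' @param object An `mkpc` object.
#' @param ... Unused.
#' @export
predict.mkpc <- function(object, newdata, ...) score_mkpc(object, newdata)

#' @export
coef.mkpc <- function(object, ...) {
  setNames(object$terms$coefficient,
           paste(object$terms$gene_a, object$terms$gene_b, sep = "|"))
}

#' @export
print.mkpc <- function(x, ...) {
  cat("Gene-pair prognostic risk model (risk score = exp(Sum))\n")
  if (nrow(x$terms) == 0L) {
    cat("  <empty model: no prognostic pairs>\n")
  } else {
    co <- x$terms$coefficient
    piece <- sprintf("%s%.6g * %s|%s",
                     ifelse(seq_along(co) == 1L,
                            ifelse(co < 0, "-", ""),
                            ifelse(co < 0, "- ", "+ ")),
                     abs(co), x$terms$gene_a, x$terms$gene_b)
    cat("  Sum =", paste(piece, collapse = " "), "\n")
  }
  cat(sprintf("  cutoff (median training score): %.6g\n", x$cutoff))
  if (!is.null(x$funnel)) {
    f <- x$funnel
    cat(sprintf("  funnel: %s pairs -> %s informative -> %s screened -> %s selected -> %s final\n",
                f["enumerated"], f["informative"], f["screened"],
                f["selected"], f["final"]))
  }
  invisible(x)
}

#' @export
summary.mkpc <- function(object, ...) {
  out <- object$terms
  if (nrow(out) > 0L) {
    out$hr <- exp(out$coefficient)
    out$effect <- ifelse(out$hr > 1, "risk", "protective")
  }
  structure(list(terms = out, cutoff = object$cutoff,
                 funnel = object$funnel, metadata = object$metadata),
            class = "summary.mkpc")
}

#' @export
print.summary.mkpc <- function(x, ...) {
  cat("Pair risk model summary\n")
  if (nrow(x$terms) > 0L) print(x$terms, row.names = FALSE) else
    cat("  <empty model>\n")
  cat(sprintf("  cutoff: %.6g\n", x$cutoff))
  if (!is.null(x$funnel)) {
    cat("  funnel counts:\n"); print(x$funnel)
  }
  invisible(x)
}

#' The bundled published colon-cancer pair risk model
#'
#' Returns, verbatim, the published seven-term colon-cancer gene-pair risk
#' score: five risk terms (positive coefficients) and two protective terms
#' (negative coefficients), with the published risk cutoff 1.0544 (the
#' median training-cohort score of the original study). The source
#' publication's text mentions eight pairs while its printed formula lists
#' seven; the model is bundled exactly as printed, with no invented
#' eighth term.
#'
#' @return An `mkpc` object.
#' @export
published_mkpc <- function() {
  terms <- data.frame(
    gene_a = c("MPP2", "PPARGC1A", "NOG", "GAMT", "GSR", "NGF", "CRIP2"),
    gene_b = c("CPT1C", "CD36", "CD1B", "CCL22", "MAGEF1", "CD1B", "ACTR8"),
    coefficient = c(1.028064, -1.09876, 0.573201, 0.661607, -0.57286,
                    0.593767, 0.927301),
    stringsAsFactors = FALSE
  )
  new_mkpc(terms = terms, cutoff = 1.0544,
           metadata = list(source = "published colon-cancer MKPC score",
                           cutoff_rule = "median training score"))
}
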