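# Multilayer perceptron with three hidden layers (16, 64, 64) and a
# softmax output, trained by minimising mean cross-entropy plus an L2
# penalty alpha/(2n) * sum(W^2) on the weights (biases unpenalised).
# Three optimisers are provided: full-batch L-BFGS (via optim), minibatch
# SGD with momentum, and Adam.

mlp_act <- function(z, kind) {
  switch(kind,
         identity = z,
         logistic = 1 / (1 + exp(-z)),
         tanh = tanh(z),
         relu = pmax(z, 0),
         stop("unknown activation: ", kind))
}

# derivative of the activation expressed through its output a
mlp_act_grad <- function(a, kind) {
  switch(kind,
         identity = 1,
         logistic = a * (1 - a),
         tanh = 1 - a^2,
         relu = (a > 0) * 1)
}

mlp_shapes <- function(d, hidden, C) {
  sizes <- c(d, hidden, C)
  lapply(seq_len(length(sizes) - 1L), function(i) c(sizes[i], sizes[i + 1L]))
}

mlp_init <- function(shapes) {
  lapply(shapes, function(s) {
    lim <- sqrt(6 / (s[1] + s[2]))
    list(W = matrix(runif(s[1] * s[2], -lim, lim), s[1], s[2]),
         b = rep(0, s[2]))
  })
}

mlp_flatten <- function(params) {
  unlist(lapply(params, function(p) c(as.vector(p$W), p$b)))
}

mlp_unflatten <- function(vec, shapes) {
  out <- vector("list", length(shapes)); pos <- 0L
  for (i in seq_along(shapes)) {
    s <- shapes[[i]]; nw <- s[1] * s[2]
    out[[i]] <- list(W = matrix(vec[pos + seq_len(nw)], s[1], s[2]),
                     b = vec[pos + nw + seq_len(s[2])])
    pos <- pos + nw + s[2]
  }
  out
}

mlp_forward <- function(params, X, activation) {
  L <- length(params)
  acts <- vector("list", L + 1L)
  acts[[1L]] <- X
  for (i in seq_len(L - 1L)) {
    z <- acts[[i]] %*% params[[i]]$W
    z <- sweep(z, 2, params[[i]]$b, "+")
    acts[[i + 1L]] <- mlp_act(z, activation)
  }
  z <- acts[[L]] %*% params[[L]]$W
  z <- sweep(z, 2, params[[L]]$b, "+")
  z <- z - apply(z, 1, max)
  p <- exp(z); p <- p / rowSums(p)
  acts[[L + 1L]] <- p
  acts
}

# loss and gradient on (X, Y one-hot); returns list(loss, grad params list)
mlp_loss_grad <- function(params, X, Y, activation, alpha) {
  n <- nrow(X); L <- length(params)
  acts <- mlp_forward(params, X, activation)
  P <- acts[[L + 1L]]
  ce <- -sum(Y * log(pmax(P, 1e-300))) / n
  l2 <- sum(vapply(params, function(p) sum(p$W^2), numeric(1)))
  loss <- ce + alpha * l2 / (2 * n)
  delta <- (P - Y) / n
  grads <- vector("list", L)
  for (i in L:1) {
    grads[[i]] <- list(W = crossprod(acts[[i]], delta) + alpha * params[[i]]$W / n,
                       b = colSums(delta))
    if (i > 1L) {
      delta <- (delta %*% t(params[[i]]$W)) * mlp_act_grad(acts[[i]], activation)
    }
  }
  list(loss = loss, grads = grads)
}

mlp_train_core <- function(X, Y, activation, alpha, solver, max_iter,
                           hidden = c(16L, 64L, 64L)) {
  shapes <- mlp_shapes(ncol(X), hidden, ncol(Y))
  params <- mlp_init(shapes)
  n <- nrow(X)
  if (solver == "lbfgs") {
    fn <- function(v) mlp_loss_grad(mlp_unflatten(v, shapes), X, Y,
                                    activation, alpha)$loss
    gr <- function(v) mlp_flatten(mlp_loss_grad(mlp_unflatten(v, shapes), X, Y,
                                                activation, alpha)$grads)
    opt <- optim(mlp_flatten(params), fn, gr, method = "L-BFGS-B",
                 control = list(maxit = max_iter))
    params <- mlp_unflatten(opt$par, shapes)
  } else {
    batch <- min(32L, n)
    lr <- if (solver == "sgd") 0.05 else 0.001
    mom <- lapply(shapes, function(s) list(W = matrix(0, s[1], s[2]), b = rep(0, s[2])))
    v2 <- lapply(shapes, function(s) list(W = matrix(0, s[1], s[2]), b = rep(0, s[2])))
    step <- 0L
    for (epoch in seq_len(max_iter)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = batch)) {
        idx <- ord[start:min(start + batch - 1L, n)]
        lg <- mlp_loss_grad(params, X[idx, , drop = FALSE],
                            Y[idx, , drop = FALSE], activation, alpha)
        step <- step + 1L
        for (i in seq_along(params)) {
          gW <- lg$grads[[i]]$W; gb <- lg$grads[[i]]$b
          if (solver == "sgd") {
            mom[[i]]$W <- 0.9 * mom[[i]]$W - lr * gW
            mom[[i]]$b <- 0.9 * mom[[i]]$b - lr * gb
            params[[i]]$W <- params[[i]]$W + mom[[i]]$W
            params[[i]]$b <- params[[i]]$b + mom[[i]]$b
          } else {  # adam
            mom[[i]]$W <- 0.9 * mom[[i]]$W + 0.1 * gW
            mom[[i]]$b <- 0.9 * mom[[i]]$b + 0.1 * gb
            v2[[i]]$W <- 0.999 * v2[[i]]$W + 0.001 * gW^2
            v2[[i]]$b <- 0.999 * v2[[i]]$b + 0.001 * gb^2
            mhW <- mom[[i]]$W / (1 - 0.9^step); mhb <- mom[[i]]$b / (1 - 0.9^step)
            vhW <- v2[[i]]$W / (1 - 0.999^step); vhb <- v2[[i]]$b / (1 - 0.999^step)
            params[[i]]$W <- params[[i]]$W - lr * mhW / (sqrt(vhW) + 1e-8)
            params[[i]]$b <- params[[i]]$b - lr * mhb / (sqrt(vhb) + 1e-8)
          }
        }
      }
    }
  }
  params
}

#' Train a multilayer-perceptron subtype classifier
#'
#' A three-hidden-layer perceptron (16, 64 and 64 neurons) with softmax
#' output, trained on per-gene standardised expression (constants frozen
#' from the training cohort). The loss is mean cross-entropy with an L2
#' weight penalty `alpha`; `solver` is full-batch L-BFGS, minibatch SGD
#' with momentum, or Adam.
#'
#' @param expr Genes-by-samples training expression matrix.
#' @param labels Class labels, one per training sample; every class must
#'   be present.
#' @param genes Signature genes used as inputs (default: all rows).
#' @param activation Hidden-layer activation: `"identity"`, `"logistic"`,
#'   `"tanh"` or `"relu"`.
#' @param alpha L2 penalty strength.
#' @param solver `"lbfgs"`, `"sgd"` or `"adam"`.
#' @param seed Integer seed (weight initialisation and batch order).
#' @param max_iter L-BFGS iterations or SGD/Adam epochs.
#' @return An object of class `mlp_classifier`.
#' @export
mlp_fit <- function(expr, labels, genes = NULL, activation = "logistic",
                    alpha = 0.01, solver = "lbfgs", seed = 1L,
                    max_iter = 100L) {
  stopifnot(is.matrix(expr), length(labels) == ncol(expr))
  if (is.null(genes)) genes <- rownames(expr)
  labels <- as.factor(labels)
  if (any(table(labels) == 0L)) stop("every class must be present in training")
  ctr <- rowMeans(expr[genes, , drop = FALSE])
  scl <- apply(expr[genes, , drop = FALSE], 1, sd)
  scl[scl == 0] <- 1
  X <- t((expr[genes, , drop = FALSE] - ctr) / scl)
  Y <- diag(nlevels(labels))[as.integer(labels), , drop = FALSE]
  restore <- local_seed(seed); on.exit(restore())
  params <- mlp_train_core(X, Y, activation, alpha, solver, max_iter)
  structure(list(genes = genes, center = ctr, scale = scl,
                 classes = levels(labels), layer_sizes = c(16L, 64L, 64L),
                 activation = activation, alpha = alpha, solver = solver,
                 weights = params, seed = seed, max_iter = max_iter,
                 cv_accuracy = NA_real_, grid = NULL),
            class = "mlp_classifier")
}

#' @export
predict.mlp_classifier <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  stopifnot(is.matrix(newdata))
  missing_genes <- setdiff(object$genes, rownames(newdata))
  if (length(missing_genes) > 0L) {
    stop("signature gene(s) missing from new data: ",
         paste(missing_genes, collapse = ", "))
  }
  X <- t((newdata[object$genes, , drop = FALSE] - object$center) / object$scale)
  P <- mlp_forward(object$weights, X, object$activation)[[length(object$weights) + 1L]]
  colnames(P) <- object$classes
  rownames(P) <- colnames(newdata)
  if (type == "prob") return(P)
  setNames(object$classes[max.col(P, ties.method = "first")], colnames(newdata))
}

#' @export
print.mlp_classifier <- function(x, ...) {
  cat(sprintf("MLP classifier (%s): %d classes, hidden layers %s\n",
              paste0("activation=", x$activation, ", alpha=", x$alpha,
                     ", solver=", x$solver),
              length(x$classes), paste(x$layer_sizes, collapse = "/")))
  if (!is.na(x$cv_accuracy)) {
    cat(sprintf("  cross-validated accuracy: %.3f\n", x$cv_accuracy))
  }
  invisible(x)
}

# Stratified fold assignment: shuffle within class, deal folds round-robin.
stratified_folds <- function(labels, folds) {
  labels <- as.factor(labels)
  fold <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

#' Grid search for the MLP subtype classifier
#'
#' Exhaustive search over the 4 x 5 x 3 = 60 combinations of activation
#' (`identity`, `logistic`, `tanh`, `relu`), L2 penalty alpha (1e-5, 1e-4,
#' 1e-3, 1e-2, 0.1) and solver (`lbfgs`, `sgd`, `adam`). Each combination
#' is scored by stratified cross-validated accuracy — correctly predicted
#' patients over all patients, pooled across folds — and the best
#' combination (ties to the first in grid order) is refit on the full
#' training set. Deterministic given `seed`. Classes with fewer than two
#' members per fold are warned about.
#'
#' @inheritParams mlp_fit
#' @param folds Number of cross-validation folds (default 10).
#' @param max_iter Training iterations per fit.
#' @return An `mlp_classifier` whose `cv_accuracy` is the winning
#'   combination's CV accuracy and whose `grid` holds the full 60-row
#'   result table (attribute `n_evaluated`).
#' @export
mlp_grid_search <- function(expr, labels, genes = NULL, folds = 10L,
                            seed = 1L, max_iter = 100L) {
  stopifnot(is.matrix(expr), length(labels) == ncol(expr))
  if (is.null(genes)) genes <- rownames(expr)
  labels <- as.factor(labels)
  if (any(table(labels) == 0L)) stop("every class must be present in training")
  if (any(table(labels) < 2L)) {
    warning("class(es) with fewer than 2 samples: CV accuracy will be unstable")
  }
  grid <- expand.grid(activation = c("identity", "logistic", "tanh", "relu"),
                      alpha = c(1e-5, 1e-4, 1e-3, 1e-2, 1e-1),
                      solver = c("lbfgs", "sgd", "adam"),
                      stringsAsFactors = FALSE)
  ctr <- rowMeans(expr[genes, , drop = FALSE])
  scl <- apply(expr[genes, , drop = FALSE], 1, sd)
  scl[scl == 0] <- 1
  X <- t((expr[genes, , drop = FALSE] - ctr) / scl)
  yint <- as.integer(labels)
  C <- nlevels(labels)
  n <- nrow(X)
  restore <- local_seed(seed); on.exit(restore())
  fold <- stratified_folds(labels, min(folds, min(table(labels))))
  accs <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    correct <- 0L
    for (f in sort(unique(fold))) {
      tr <- fold != f; te <- !tr
      Ytr <- diag(C)[yint[tr], , drop = FALSE]
      set.seed(derive_seed(seed, paste0("mlp", g, "fold", f)))
      params <- mlp_train_core(X[tr, , drop = FALSE], Ytr,
                               grid$activation[g], grid$alpha[g],
                               grid$solver[g], max_iter)
      P <- mlp_forward(params, X[te, , drop = FALSE],
                       grid$activation[g])[[length(params) + 1L]]
      correct <- correct + sum(max.col(P, ties.method = "first") == yint[te])
    }
    accs[g] <- correct / n
  }
  best <- which.max(accs)
  set.seed(derive_seed(seed, "mlp-final"))
  params <- mlp_train_core(X, diag(C)[yint, , drop = FALSE],
                           grid$activation[best], grid$alpha[best],
                           grid$solver[best], max_iter)
  grid$cv_accuracy <- accs
  attr(grid, "n_evaluated") <- nrow(grid)
  structure(list(genes = genes, center = ctr, scale = scl,
                 classes = levels(labels), layer_sizes = c(16L, 64L, 64L),
                 activation = grid$activation[best], alpha = grid$alpha[best],
                 solver = grid$solver[best], weights = params, seed = seed,
                 max_iter = max_iter, cv_accuracy = accs[best], grid = grid),
            class = "mlp_classifier")
}
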