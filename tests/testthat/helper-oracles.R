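# Independent oracles: deliberately naive implementations used to check
# the package's fast paths. Loops and literal formulas only.

# Breslow partial likelihood, gradient and Hessian; Newton maximisation.
oracle_cox_loglik <- function(beta, x, time, event) {
  x <- as.matrix(x)
  ll <- 0
  for (t0 in sort(unique(time[event == 1]))) {
    d <- which(time == t0 & event == 1)
    risk <- which(time >= t0)
    eta <- drop(x %*% beta)
    ll <- ll + sum(eta[d]) - length(d) * log(sum(exp(eta[risk])))
  }
  ll
}

oracle_cox_newton <- function(x, time, event, tol = 1e-10, maxit = 50) {
  x <- as.matrix(x)
  p <- ncol(x)
  beta <- rep(0, p)
  for (it in seq_len(maxit)) {
    g <- rep(0, p); H <- matrix(0, p, p)
    eta <- drop(x %*% beta)
    w <- exp(eta)
    for (t0 in sort(unique(time[event == 1]))) {
      d <- which(time == t0 & event == 1)
      risk <- which(time >= t0)
      sw <- sum(w[risk])
      mu <- colSums(x[risk, , drop = FALSE] * w[risk]) / sw
      m2 <- crossprod(x[risk, , drop = FALSE] * sqrt(w[risk])) / sw
      g <- g + colSums(x[d, , drop = FALSE]) - length(d) * mu
      H <- H - length(d) * (m2 - tcrossprod(mu))
    }
    step <- solve(-H, g)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  beta
}

# Product-limit estimator by direct product over risk sets.
oracle_km <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = ts, survival = NA_real_)
  for (i in seq_along(ts)) {
    n_risk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d / n_risk)
    out$survival[i] <- s
  }
  out
}

# Two-group log-rank by literal observed-minus-expected sums.
oracle_logrank2 <- function(time, event, group) {
  group <- as.integer(as.factor(group))
  o_minus_e <- 0; v <- 0
  for (t0 in sort(unique(time[event == 1]))) {
    at_risk <- time >= t0
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == 1L)
    d <- sum(time == t0 & event == 1)
    d1 <- sum(time == t0 & event == 1 & group == 1L)
    o_minus_e <- o_minus_e + (d1 - d * n1 / n)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- o_minus_e^2 / v
  list(chi_square = chisq, p_value = pchisq(chisq, 1, lower.tail = FALSE))
}

# Benjamini-Hochberg by explicit sort and cummin.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

# ssGSEA running sum for one sample, literal loop.
oracle_ssgsea_one <- function(values, set_genes, tau = 0.25) {
  genes <- names(values)
  r <- rank(values, ties.method = "average")
  ord <- order(-r, seq_along(values))
  es <- 0; run_in <- 0; run_out <- 0
  w <- r[ord]^tau
  inset <- genes[ord] %in% set_genes
  wsum <- sum(w[inset])
  n_out <- sum(!inset)
  for (i in seq_along(ord)) {
    if (inset[i]) run_in <- run_in + w[i] / wsum else run_out <- run_out + 1 / n_out
    es <- es + (run_in - run_out)
  }
  unname(es)
}

# Uncensored cumulative/dynamic AUC: plain concordance count at horizon.
oracle_auc_uncensored <- function(scores, time, t0) {
  case <- which(time <= t0)
  ctrl <- which(time > t0)
  tot <- 0
  for (i in case) for (j in ctrl) {
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  }
  tot / (length(case) * length(ctrl))
}

# Pair enumeration by double loop over a sorted id list.
oracle_pairs <- function(gene_ids) {
  g <- sort(gene_ids, method = "radix")
  out <- NULL
  for (i in seq_along(g)) for (j in seq_along(g)) {
    if (i < j) out <- rbind(out, data.frame(gene_a = g[i], gene_b = g[j]))
  }
  out
}

# Indicator table by triple loop.
oracle_encode <- function(expr, pairs) {
  out <- matrix(0L, nrow = nrow(pairs), ncol = ncol(expr),
                dimnames = list(paste(pairs$gene_a, pairs$gene_b, sep = "|"),
                                colnames(expr)))
  for (k in seq_len(nrow(pairs))) for (s in seq_len(ncol(expr))) {
    if (expr[pairs$gene_a[k], s] > expr[pairs$gene_b[k], s]) out[k, s] <- 1L
  }
  out
}
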