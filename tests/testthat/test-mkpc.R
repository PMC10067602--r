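test_that("univariate screen matches brute-force Newton maximisation of the Breslow partial likelihood", {
  set.seed(21)
  n <- 25
  surv <- data.frame(sample = sprintf("s%02d", 1:n),
                     time = sample(seq(10, 1000, by = 10), n),  # distinct times
                     event = rbinom(n, 1, 0.7))
  ind <- matrix(rbinom(3 * n, 1, 0.5), nrow = 3,
                dimnames = list(c("A|B", "C|D", "E|F"), surv$sample))
  pfm <- structure(list(pairs = data.frame(gene_a = c("A", "C", "E"),
                                           gene_b = c("B", "D", "F")),
                        sample_ids = surv$sample, indicators = ind,
                        frequency = rowMeans(ind)), class = "pair_features")
  scr <- univariate_screen(pfm, surv)
  for (i in 1:3) {
    bf <- oracle_cox_newton(matrix(as.numeric(ind[i, ])), surv$time, surv$event)
    expect_equal(scr$coefficient[i], unname(bf), tolerance = 1e-6)
  }
  expect_true(all(scr$p_value >= 0 & scr$p_value <= 1))
  expect_identical(scr$pass, scr$p_value < 0.05)
})

test_that("a strongly planted pair passes the univariate screen near its true effect", {
  co <- planted_cohort(n = 400, coefs = 1.0, n_genes = 12, seed = 31)
  pfm <- encode_pairs(co$expression, enumerate_pairs(rownames(co$expression)))
  pfm <- filter_informative(pfm)
  scr <- univariate_screen(pfm, co$survival)
  row <- scr[scr$pair == "G001|G002", ]
  expect_true(row$pass)
  expect_lt(abs(row$coefficient - 1.0), 3 * row$se)
})

test_that("zero-variance pairs are skipped with a warning, not fit", {
  surv <- data.frame(sample = paste0("s", 1:10),
                     time = seq(10, 100, by = 10), event = rep(1L, 10))
  ind <- rbind("A|B" = rep(0L, 10), "C|D" = rep(c(0L, 1L), 5))
  pfm <- structure(list(pairs = data.frame(gene_a = c("A", "C"),
                                           gene_b = c("B", "D")),
                        sample_ids = surv$sample, indicators = ind,
                        frequency = rowMeans(ind)), class = "pair_features")
  expect_warning(scr <- univariate_screen(pfm, surv), "zero-variance")
  expect_true(is.na(scr$p_value[1]))
  expect_false(scr$pass[1])
})

test_that("penalised selection keeps a lone informative pair and is seed-reproducible", {
  co <- planted_cohort(n = 200, coefs = 1.2, n_genes = 12, seed = 41)
  pfm <- filter_informative(
    encode_pairs(co$expression, enumerate_pairs(rownames(co$expression))))
  scr <- univariate_screen(pfm, co$survival)
  pfm_pass <- pfm[which(scr$pass)]
  sel1 <- lasso_select(pfm_pass, co$survival, seed = 5)
  sel2 <- lasso_select(pfm_pass, co$survival, seed = 5)
  expect_identical(sel1, sel2)
  # single-pair input comes straight back
  single <- pfm["G001|G002" == rownames(pfm$indicators)]
  expect_identical(lasso_select(single, co$survival, seed = 1)$gene_a, "G001")
})

test_that("multivariate assembly matches the brute-force oracle on small instances", {
  set.seed(55)
  n <- 28
  surv <- data.frame(sample = sprintf("s%02d", 1:n),
                     time = sample(seq(5, 800, by = 7), n),
                     event = rbinom(n, 1, 0.8))
  p <- 4
  ind <- matrix(rbinom(p * n, 1, 0.5), nrow = p)
  rownames(ind) <- paste0(LETTERS[seq_len(p)], "|", letters[seq_len(p)])
  pfm <- structure(list(pairs = data.frame(gene_a = LETTERS[seq_len(p)],
                                           gene_b = letters[seq_len(p)]),
                        sample_ids = surv$sample, indicators = ind,
                        frequency = rowMeans(ind)), class = "pair_features")
  model <- multivariate_fit(pfm$pairs, pfm, surv, keep_alpha = 1)  # keep all
  bf <- oracle_cox_newton(t(ind), surv$time, surv$event)
  expect_equal(model$terms$coefficient, unname(bf), tolerance = 1e-6)
})

test_that("the model cutoff is the brute-force median of training risk scores", {
  co <- planted_cohort(n = 150, coefs = c(1, -0.8), n_genes = 14, seed = 61)
  m <- mkpc(co$expression, co$survival, seed = 2)
  expect_gt(nrow(m$terms), 0)
  sc <- score_mkpc(m, co$expression)
  expect_equal(m$cutoff, median(sort(sc$mkpc_score)))
  expect_identical(sc$risk_group, ifelse(sc$mkpc_score > m$cutoff, "high", "low"))
})

test_that("the funnel reduces monotonically and records its counts", {
  co <- planted_cohort(n = 200, coefs = c(1, 1), n_genes = 14, seed = 71)
  m <- mkpc(co$expression, co$survival, seed = 3)
  f <- m$funnel
  expect_equal(unname(f["enumerated"]), 14 * 13 / 2)
  expect_true(f["informative"] <= f["enumerated"])
  expect_true(f["screened"] <= f["informative"])
  expect_true(f["selected"] <= f["screened"])
  expect_true(f["final"] <= f["selected"])
})

test_that("an all-decoy cohort yields an empty model, not a crash", {
  co <- planted_cohort(n = 60, coefs = numeric(0), n_genes = 6, seed = 81)
  expect_message(m <- mkpc(co$expression, co$survival, alpha = 1e-6, seed = 4),
                 "no prognostic pairs")
  expect_s3_class(m, "mkpc")
  expect_equal(nrow(m$terms), 0L)
  sc <- score_mkpc(m, co$expression)
  expect_true(all(sc$mkpc_score == 1))
  expect_true(all(sc$risk_group == "low"))
})

test_that("scoring follows the exponential-sum definition exactly", {
  pub <- published_mkpc()
  genes <- unique(c(pub$terms$gene_a, pub$terms$gene_b))
  # all indicators zero: every gene_b above its gene_a
  expr0 <- matrix(seq_along(genes), ncol = 1,
                  dimnames = list(genes, "s1"))
  expr0[pub$terms$gene_a, 1] <- 1
  expr0[pub$terms$gene_b, 1] <- 2
  sc0 <- score_mkpc(pub, expr0)
  expect_identical(sc0$linear_sum, 0)
  expect_identical(sc0$mkpc_score, 1)
  # flipping exactly one indicator multiplies the score by exp(coefficient)
  expr1 <- expr0
  expr1["MPP2", 1] <- 3   # now MPP2 > CPT1C only
  sc1 <- score_mkpc(pub, expr1)
  expect_identical(sc1$mkpc_score, exp(1.028064))
  expect_equal(sc1$mkpc_score / sc0$mkpc_score, exp(1.028064))
})

test_that("risk grouping thresholds strictly at the cutoff", {
  pub <- published_mkpc()
  fake <- pub
  # a score of 1.06 against the published cutoff 1.0544 is high risk
  expect_identical(ifelse(1.06 > pub$cutoff, "high", "low"), "high")
  expect_identical(ifelse(1.05 > pub$cutoff, "high", "low"), "low")
})

test_that("the bundled published model is exactly as printed", {
  pub <- published_mkpc()
  expect_equal(nrow(pub$terms), 7L)
  expect_identical(sum(pub$terms$coefficient < 0), 2L)
  expect_setequal(pub$terms$coefficient[pub$terms$coefficient < 0],
                  c(-1.09876, -0.57286))
  expect_identical(pub$cutoff, 1.0544)
  s <- summary(pub)
  expect_identical(s$terms$hr, exp(pub$terms$coefficient))
  expect_identical(sign(s$terms$hr - 1), sign(pub$terms$coefficient))
})

test_that("scores are identical between a cohort and its monotone distortion", {
  cfg_a <- sim_config(n_samples = 100, n_genes = 20, n_signature_genes = 8,
                      planted_pairs = data.frame(gene_a = "G001",
                                                 gene_b = "G002",
                                                 coefficient = 1),
                      seed = 91, batch_distortion = "none")
  cfg_b <- sim_config(n_samples = 100, n_genes = 20, n_signature_genes = 8,
                      planted_pairs = data.frame(gene_a = "G001",
                                                 gene_b = "G002",
                                                 coefficient = 1),
                      seed = 91, batch_distortion = "per-sample-monotone")
  plain <- simulate_cohort(cfg_a); warp <- simulate_cohort(cfg_b)
  m <- mkpc(plain$expression, plain$survival, seed = 6)
  expect_identical(score_mkpc(m, plain$expression),
                   score_mkpc(m, warp$expression))
})

test_that("missing model genes are an error, never silently imputed", {
  pub <- published_mkpc()
  expr <- matrix(1:4, nrow = 2, dimnames = list(c("MPP2", "CPT1C"),
                                                c("s1", "s2")))
  expect_error(score_mkpc(pub, expr), "PPARGC1A")
})
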