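test_that("simulation is a deterministic function of its configuration", {
  cfg <- sim_config(n_samples = 60, n_genes = 30, n_signature_genes = 10,
                    seed = 11)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$expression, b$expression)
  expect_identical(a$survival, b$survival)
  expect_identical(a$true_subtype, b$true_subtype)
})

test_that("a cohort without planted pairs is a null model", {
  co <- planted_cohort(n = 100, coefs = numeric(0), n_genes = 10, seed = 2)
  expect_true(all(co$true_eta == 0))
  expect_equal(nrow(co$true_pair_indicators), 0L)
})

test_that("censoring calibration lands within five points of the target", {
  for (target in c(0.2, 0.4, 0.6)) {
    co <- simulate_cohort(sim_config(n_samples = 300, n_genes = 10,
                                     n_signature_genes = 4,
                                     censoring_target = target,
                                     seed = round(100 * target)))
    expect_lt(abs(co$realized_censoring - target), 0.05)
  }
  expect_error(sim_config(censoring_target = 0), "strictly inside")
  expect_error(sim_config(censoring_target = 1), "strictly inside")
})

test_that("a planted pair's hazard ratio is recovered by an oracle fit on the true indicator", {
  co <- planted_cohort(n = 400, coefs = 1.0, n_genes = 10, seed = 5)
  fit <- survival::coxph(
    survival::Surv(co$survival$time, co$survival$event) ~ ind,
    data = data.frame(ind = as.vector(co$true_pair_indicators[1, ])),
    ties = "breslow")
  beta <- unname(coef(fit)); se <- sqrt(fit$var[1, 1])
  expect_lt(abs(beta - 1.0), 3 * se)
  # and the brute-force Newton oracle agrees with that fit
  bf <- oracle_cox_newton(matrix(as.numeric(co$true_pair_indicators[1, ])),
                          co$survival$time, co$survival$event)
  expect_equal(unname(bf), beta, tolerance = 1e-8)
})

test_that("the planted effect size is recovered without bias across replicates", {
  est <- vapply(1:200, function(r) {
    co <- planted_cohort(n = 400, coefs = 1.0, n_genes = 6, seed = 1000 + r)
    y <- survival::Surv(co$survival$time, co$survival$event)
    x <- matrix(as.numeric(co$true_pair_indicators[1, ]), ncol = 1)
    survival::coxph.fit(x, y, strata = NULL, offset = NULL, init = 0,
                        control = survival::coxph.control(), weights = NULL,
                        method = "breslow", rownames = NULL)$coefficients[1]
  }, numeric(1))
  expect_lt(abs(mean(est) - 1.0), 0.1)
})

test_that("per-sample monotone distortion changes expression but not encodings or survival", {
  cfg_plain <- sim_config(n_samples = 80, n_genes = 25, n_signature_genes = 8,
                          seed = 9, batch_distortion = "none")
  cfg_warp <- sim_config(n_samples = 80, n_genes = 25, n_signature_genes = 8,
                         seed = 9, batch_distortion = "per-sample-monotone")
  plain <- simulate_cohort(cfg_plain)
  warp <- simulate_cohort(cfg_warp)
  expect_identical(plain$survival, warp$survival)
  expect_false(identical(plain$expression, warp$expression))
  pairs <- enumerate_pairs(rownames(plain$expression))
  expect_identical(encode_pairs(warp$expression, pairs)$indicators,
                   encode_pairs(plain$expression, pairs)$indicators)
})

test_that("the worked fixture is deterministic, tied where designed, and file-stable", {
  fx1 <- make_worked_fixture()
  fx2 <- make_worked_fixture()
  expect_identical(fx1$expression, fx2$expression)
  expect_equal(dim(fx1$expression), c(8L, 12L))
  expect_equal(nrow(fx1$survival), 12L)
  # contains at least one tied pair within a sample
  ties <- sum(apply(fx1$expression, 2, function(v) any(duplicated(v))))
  expect_gte(ties, 1)
  # survives an expression TSV round-trip
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(gene = rownames(fx1$expression), fx1$expression,
                         check.names = FALSE),
              f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_expression(f), fx1$expression)
})

test_that("simulated mutation tables have Poisson-like per-sample counts", {
  mut <- simulate_mutations(sprintf("S%03d", 1:200), lambda = 50, seed = 3)
  counts <- table(factor(mut$sample, levels = sprintf("S%03d", 1:200)))
  expect_equal(mean(counts), 50, tolerance = 0.05)
  expect_true(all(mut$variant_classification %in%
                    pairprog:::maf_nonsynonymous))
})
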