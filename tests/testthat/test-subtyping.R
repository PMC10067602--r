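# Agreement between two labelings up to permutation (adjusted Rand index).
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_i <- sum(choose(rowSums(tab), 2))
  sum_j <- sum(choose(colSums(tab), 2))
  expected <- sum_i * sum_j / choose(n, 2)
  (sum_ij - expected) / ((sum_i + sum_j) / 2 - expected)
}

test_that("consensus clustering recovers well-separated planted subtypes", {
  co <- simulate_cohort(sim_config(n_samples = 120, n_genes = 60,
                                   n_signature_genes = 30, n_subtypes = 3,
                                   subtype_shift = 2,
                                   subtype_proportions = c(0.45, 0.35, 0.20),
                                   seed = 17))
  cr <- consensus_cluster(co$expression, genes = co$signature_genes,
                          k_range = 2:5, reps = 100, seed = 3)
  expect_equal(cr$chosen_k, 3)
  expect_gte(adjusted_rand(cr$labels_chosen, co$true_subtype), 0.9)
  # consensus matrices are symmetric with unit diagonal
  for (cm in cr$consensus) {
    expect_true(all(abs(cm - t(cm)) < 1e-12, na.rm = TRUE))
    expect_true(all(diag(cm) == 1))
    expect_true(all(cm >= 0 & cm <= 1, na.rm = TRUE))
  }
})

test_that("the chosen k tracks the true number of subtypes, not just the largest candidate", {
  co2 <- simulate_cohort(sim_config(n_samples = 120, n_genes = 60,
                                    n_signature_genes = 30, n_subtypes = 2,
                                    subtype_shift = 2,
                                    subtype_proportions = c(0.55, 0.45),
                                    seed = 17))
  cr2 <- consensus_cluster(co2$expression, genes = co2$signature_genes,
                           k_range = 2:5, reps = 100, seed = 3)
  expect_identical(cr2$chosen_k, 2L)
  co4 <- simulate_cohort(sim_config(n_samples = 150, n_genes = 60,
                                    n_signature_genes = 40, n_subtypes = 4,
                                    subtype_shift = 2,
                                    subtype_proportions = rep(0.25, 4),
                                    seed = 5))
  cr4 <- consensus_cluster(co4$expression, genes = co4$signature_genes,
                           k_range = 2:6, reps = 100, seed = 3)
  expect_identical(cr4$chosen_k, 4L)
})

test_that("a single repetition degenerates to one PAM run with 0/1/NA consensus", {
  co <- simulate_cohort(sim_config(n_samples = 40, n_genes = 20,
                                   n_signature_genes = 10, seed = 23))
  cr <- consensus_cluster(co$expression, genes = co$signature_genes,
                          k_range = 2, reps = 1, seed = 1)
  vals <- cr$consensus[[1]][upper.tri(cr$consensus[[1]])]
  expect_true(all(vals %in% c(0, 1) | is.na(vals)))
})

test_that("duplicated samples always co-cluster", {
  co <- simulate_cohort(sim_config(n_samples = 30, n_genes = 20,
                                   n_signature_genes = 10, n_subtypes = 2,
                                   subtype_shift = 2, seed = 29))
  dup <- cbind(co$expression, co$expression)
  colnames(dup) <- c(colnames(co$expression),
                     paste0(colnames(co$expression), "_dup"))
  cr <- consensus_cluster(dup, genes = co$signature_genes, k_range = 2,
                          reps = 80, seed = 2)
  lab <- cr$labels_chosen
  expect_identical(unname(lab[1:30]), unname(lab[31:60]))
  expect_error(consensus_cluster(co$expression, genes = co$signature_genes,
                                 k_range = 2:40, seed = 1),
               "exceeds")
})

test_that("medoids are fixed points of the nearest-medoid classifier", {
  co <- simulate_cohort(sim_config(n_samples = 60, n_genes = 30,
                                   n_signature_genes = 15, n_subtypes = 3,
                                   subtype_shift = 2, seed = 37))
  clf <- medoid_classifier_train(co$expression, co$true_subtype,
                                 genes = co$signature_genes)
  med_expr <- co$expression[, clf$medoid_sample, drop = FALSE]
  pred <- medoid_classify(clf, med_expr)
  expect_identical(unname(pred), clf$classes)
})

test_that("classification picks the nearest center in a one-gene toy", {
  expr <- matrix(c(0, 0, 0, 10, 10, 10), nrow = 1,
                 dimnames = list("g1", paste0("s", 1:6)))
  labels <- c(1, 1, 1, 2, 2, 2)
  clf <- medoid_classifier_train(expr, labels)
  newx <- matrix(c(2, 9), nrow = 1, dimnames = list("g1", c("n1", "n2")))
  pred <- medoid_classify(clf, newx)
  expect_identical(unname(pred), c("1", "2"))
  expect_error(medoid_classify(clf, matrix(1, 1, 1, dimnames = list("zz", "n"))),
               "missing")
})

test_that("the stored medoid is the brute-force within-cluster distance minimiser", {
  co <- simulate_cohort(sim_config(n_samples = 40, n_genes = 12,
                                   n_signature_genes = 6, n_subtypes = 2,
                                   subtype_shift = 1, seed = 43))
  clf <- medoid_classifier_train(co$expression, co$true_subtype,
                                 genes = co$signature_genes)
  xs <- t((co$expression[clf$genes, ] - clf$center) / clf$scale)
  for (ci in seq_along(clf$classes)) {
    members <- which(co$true_subtype == clf$classes[ci])
    sums <- vapply(members, function(m) {
      tot <- 0
      for (o in members) tot <- tot + sqrt(sum((xs[m, ] - xs[o, ])^2))
      tot
    }, numeric(1))
    best <- members[which.min(sums)]
    expect_identical(clf$medoid_sample[ci], colnames(co$expression)[best])
  }
})

test_that("held-out classification beats chance at strong separation", {
  co <- simulate_cohort(sim_config(n_samples = 300, n_genes = 60,
                                   n_signature_genes = 30, n_subtypes = 3,
                                   subtype_shift = 1.5, seed = 51))
  train_idx <- seq_len(150); test_idx <- 151:300
  clf <- medoid_classifier_train(co$expression[, train_idx],
                                 co$true_subtype[train_idx],
                                 genes = co$signature_genes)
  pred <- medoid_classify(clf, co$expression[, test_idx])
  acc <- mean(as.integer(pred) == unname(co$true_subtype[test_idx]))
  expect_gte(acc, 0.8)
})

test_that("classifier comparison reports ties, winners and non-evaluable cases", {
  co <- simulate_cohort(sim_config(n_samples = 80, n_genes = 30,
                                   n_signature_genes = 15, n_subtypes = 2,
                                   subtype_shift = 2, seed = 61))
  clf <- medoid_classifier_train(co$expression, co$true_subtype,
                                 genes = co$signature_genes)
  cmp <- compare_classifiers(clf, clf, co$expression, co$survival)
  expect_identical(cmp$classifier_a$p_value, cmp$classifier_b$p_value)
  expect_true(cmp$tie)
  expect_identical(cmp$winner, 1L)
  # a degenerate classifier that predicts one class is surfaced, not fatal
  one_class <- clf
  one_class$medoids <- clf$medoids[1, , drop = FALSE]
  one_class$classes <- clf$classes[1]
  cmp2 <- compare_classifiers(one_class, clf, co$expression, co$survival)
  expect_true(is.na(cmp2$classifier_a$p_value))
  expect_identical(cmp2$winner, 2L)
})
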