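test_that("pair enumeration yields n(n-1)/2 canonical pairs", {
  p66 <- enumerate_pairs(sprintf("G%02d", 1:66))
  expect_equal(nrow(p66), 2145L)
  expect_equal(nrow(enumerate_pairs(c("A", "B"))), 1L)
  # brute-force double-loop oracle on 5 genes
  genes5 <- c("TP53", "KRAS", "APC", "NOG", "GSR")
  expect_equal(enumerate_pairs(genes5), oracle_pairs(genes5),
               ignore_attr = TRUE)
  expect_true(all(p66$gene_a < p66$gene_b))
  expect_error(enumerate_pairs(c("A", "A", "B")), "duplicate")
  expect_error(enumerate_pairs("A"), "at least two")
})

test_that("indicator encoding follows the strict-inequality rule with ties to zero", {
  expr <- matrix(c(5, 3,
                   4, 4), nrow = 2, byrow = TRUE,
                 dimnames = list(c("A", "B"), c("s1", "s2")))
  pfm <- encode_pairs(expr, data.frame(gene_a = "A", gene_b = "B"))
  expect_identical(unname(pfm$indicators["A|B", ]), c(1L, 0L))
  expect_error(encode_pairs(expr, data.frame(gene_a = "A", gene_b = "Z")), "Z")
})

test_that("worked fixture encoding matches the hand-enumeration oracle bit for bit", {
  fx <- make_worked_fixture()
  pairs <- enumerate_pairs(rownames(fx$expression))
  pfm <- encode_pairs(fx$expression, pairs)
  expect_identical(pfm$indicators, oracle_encode(fx$expression, pairs))
  # the designed ties fall in the zero branch
  expect_equal(fx$expression["G1", "S01"], fx$expression["G2", "S01"])
  expect_identical(pfm$indicators["G1|G2", "S01"], 0L)
  expect_equal(fx$expression["G3", "S05"], fx$expression["G4", "S05"])
  expect_identical(pfm$indicators["G3|G4", "S05"], 0L)
})

test_that("complement law: A|B and B|A indicators sum to one without ties", {
  set.seed(42)
  expr <- matrix(runif(8 * 20), nrow = 8,
                 dimnames = list(paste0("g", 1:8), paste0("s", 1:20)))
  fwd <- encode_pairs(expr, data.frame(gene_a = "g1", gene_b = "g5"))
  rev <- encode_pairs(expr, data.frame(gene_a = "g5", gene_b = "g1"))
  expect_true(all(fwd$indicators + rev$indicators == 1L))
})

test_that("encoding is invariant to strictly increasing per-sample transforms", {
  set.seed(7)
  expr <- matrix(rexp(12 * 15) + 0.1, nrow = 12,
                 dimnames = list(paste0("g", 1:12), paste0("s", 1:15)))
  pairs <- enumerate_pairs(rownames(expr))
  base <- encode_pairs(expr, pairs)
  a <- runif(15, 0.5, 2); b <- runif(15, 0.5, 2); cc <- runif(15, 0, 5)
  warped <- sweep(sweep(sweep(expr, 2, b, "^"), 2, a, "*"), 2, cc, "+")
  expect_identical(encode_pairs(warped, pairs)$indicators, base$indicators)
  expect_identical(encode_pairs(log(expr), pairs)$indicators, base$indicators)
})

test_that("frequency filter keeps the closed interval and drops the rest", {
  set.seed(3)
  ind <- rbind(rep(1L, 10),                      # frequency 1.0 -> dropped
               c(rep(1L, 2), rep(0L, 8)),        # 0.2 -> kept (inclusive)
               c(rep(1L, 8), rep(0L, 2)),        # 0.8 -> kept (inclusive)
               c(rep(1L, 1), rep(0L, 9)),        # 0.1 -> dropped
               matrix(rbinom(6 * 10, 1, 0.5), nrow = 6))
  expr <- NULL
  pfm <- structure(list(
    pairs = data.frame(gene_a = paste0("a", 1:10), gene_b = paste0("b", 1:10)),
    sample_ids = paste0("s", 1:10),
    indicators = ind, frequency = rowMeans(ind)), class = "pair_features")
  rownames(pfm$indicators) <- paste(pfm$pairs$gene_a, pfm$pairs$gene_b, sep = "|")
  kept <- filter_informative(pfm)
  # brute-force scan oracle
  expect_keep <- which(rowMeans(ind) >= 0.2 & rowMeans(ind) <= 0.8)
  expect_identical(kept$pairs$gene_a, pfm$pairs$gene_a[expect_keep])
  expect_equal(attr(kept, "n_deleted"), 10L - length(expect_keep))
  expect_false("a1|b1" %in% rownames(kept$indicators))
  expect_true(all(c("a2|b2", "a3|b3") %in% rownames(kept$indicators)))
})

test_that("frequency filter is idempotent and flags an empty result", {
  fx <- make_worked_fixture()
  pfm <- encode_pairs(fx$expression, enumerate_pairs(rownames(fx$expression)))
  once <- filter_informative(pfm)
  twice <- filter_informative(once)
  expect_identical(once$indicators, twice$indicators)
  expect_equal(attr(twice, "n_deleted"), 0L)
  all_one <- encode_pairs(
    matrix(c(2, 2, 1, 1), nrow = 2, byrow = TRUE,
           dimnames = list(c("A", "B"), c("s1", "s2"))),
    data.frame(gene_a = "A", gene_b = "B"))
  expect_warning(filter_informative(all_one), "no pairs survive")
})
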