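test_that("median-of-ratios size factors match the hand-computed example", {
  m <- matrix(c(10, 20, 20, 40, 30, 60), 3, 2, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  nrm <- normalize_median_of_ratios(m)
  # geometric means (14.14, 28.28, 42.43); ratios give medians 1/sqrt(2), sqrt(2)
  expect_equal(unname(nrm$size_factors), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-10)
  expect_equal(nrm$normalized[, "s1"], nrm$normalized[, "s2"])

  single <- matrix(c(5, 8, 13), 3, 1, dimnames = list(c("a", "b", "c"), "s1"))
  expect_equal(unname(normalize_median_of_ratios(single)$size_factors), 1)

  # permuting gene order leaves size factors unchanged
  perm <- m[c(3, 1, 2), ]
  expect_equal(normalize_median_of_ratios(perm)$size_factors,
               nrm$size_factors)
})

test_that("doubling one sample's counts is absorbed exactly by its size factor", {
  set.seed(8)
  m <- matrix(rpois(60, 50) + 1, 12, 5,
              dimnames = list(sprintf("g%02d", 1:12), sprintf("s%d", 1:5)))
  m2 <- m
  m2[, 3] <- 2 * m2[, 3]
  n1 <- normalize_median_of_ratios(m)
  n2 <- normalize_median_of_ratios(m2)
  # relative to the other samples, sample 3's factor exactly doubles; the
  # geometric-mean reference shifts all factors by the common 2^(1/m)
  expect_equal(n2$size_factors[3] / n2$size_factors[1],
               2 * n1$size_factors[3] / n1$size_factors[1],
               tolerance = 1e-12)
  expect_equal(n2$normalized / n1$normalized,
               matrix(2^(1 / 5), 12, 5, dimnames = dimnames(m)),
               tolerance = 1e-12)

  allzero <- matrix(c(0, 5, 4, 0), 2, 2,
                    dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(normalize_median_of_ratios(allzero), "positive_subset")
  expect_silent(normalize_median_of_ratios(allzero, positive_subset = TRUE))
})

test_that("bh_fdr follows the step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.05), 0.05)
  expect_equal(bh_fdr(rep(0.02, 4)), rep(0.02, 4))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_fdr(c(0.5, -0.1)), "\\[0, 1\\]")

  set.seed(31)
  for (i in 1:20) {
    p <- runif(sample(1:200, 1))
    q <- bh_fdr(p)
    expect_equal(q, oracle_bh(p))
    # monotone along sorted p, permutation-equivariant
    expect_true(all(diff(q[order(p)]) >= -1e-12))
    perm <- sample(length(p))
    expect_equal(bh_fdr(p[perm]), q[perm])
  }
})

test_that("a signal-free gene gets fold change 1 and p = 1", {
  m <- matrix(rep(c(30, 50, 80, 120), each = 6), 4, 6, byrow = TRUE,
              dimnames = list(sprintf("g%d", 1:4), sprintf("s%d", 1:6)))
  ann <- sample_annotation(colnames(m), rep(c("A", "B"), each = 3))
  deg <- test_differential(expression_matrix(m, "counts"), ann)
  expect_equal(deg$log2_fc, rep(0, 4))
  expect_equal(deg$p_value, rep(1, 4))
})

test_that("swapping groups inverts the fold change and preserves p", {
  sim <- simulate_counts(200, 5, dispersion = 0.1, seed = 2L,
                         planted_degs = data.frame(gene = 1:20, log2fc = 1))
  ab <- test_differential(sim$matrix, sim$annotation,
                          group_a = "A", group_b = "B")
  ba <- test_differential(sim$matrix, sim$annotation,
                          group_a = "B", group_b = "A")
  expect_equal(ab$log2_fc, -ba$log2_fc, tolerance = 1e-9)
  expect_equal(ab$p_value, ba$p_value, tolerance = 1e-9)

  # relabeling samples within a group changes nothing
  ann2 <- sim$annotation[c(2, 1, 3:10), ]
  expect_equal(test_differential(sim$matrix, ann2)$p_value, ab$p_value)
})

test_that("DEG gates classify on the printed inequality directions", {
  rec <- data.frame(gene_id = c("a", "b", "c", "d", "e"),
                    base_mean = 100, fold_change = c(1.25, 0.80, 1.50, 1.2, 1.3),
                    log2_fc = log2(c(1.25, 0.80, 1.50, 1.2, 1.3)),
                    p_value = 0.01, fdr = c(0.10, 0.10, 0.30, 0.10, 0.20),
                    status = NA_character_, stringsAsFactors = FALSE)
  gates <- deg_gates(1.2, 0.833, 0.2, "fdr")
  out <- classify_deg(rec, gates)
  # boundary cases: fc == 1.2 is not up; fdr == 0.2 is not significant
  expect_equal(out$status, c("up", "down", "ns", "ns", "ns"))
  expect_error(deg_gates(fc_up = 0.9), "fc_up")
  expect_error(deg_gates(fc_down = 1.2), "fc_down")
})

test_that("the Welch fallback serves log2 intensity matrices", {
  set.seed(12)
  m <- matrix(rnorm(80, 8), 8, 10,
              dimnames = list(sprintf("g%d", 1:8), sprintf("s%d", 1:10)))
  m[1, 6:10] <- m[1, 6:10] + 2
  ann <- sample_annotation(colnames(m), rep(c("ctl", "tnf"), each = 5))
  deg <- test_differential(expression_matrix(m, "log2"), ann)
  expect_lt(deg$p_value[1], 0.01)
  expect_equal(deg$log2_fc[1], mean(m[1, 6:10]) - mean(m[1, 1:5]),
               tolerance = 1e-9)
  expect_gt(min(deg$p_value[-1]), 0.001)
  expect_error(test_differential(expression_matrix(m, "log2"), ann,
                                 method = "nb_wald"), "counts")
})
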