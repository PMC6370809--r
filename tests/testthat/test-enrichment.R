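test_that("set intersection partitions exactly and commutes", {
  a <- gene_set("A", c("a", "b", "c"))
  b <- gene_set("B", c("b", "c", "d"))
  ov <- intersect_sets(a, b)
  expect_equal(sort(ov$both), c("b", "c"))
  expect_equal(ov$only_a, "a")
  expect_equal(ov$only_b, "d")
  expect_equal(unname(ov$counts), c(1L, 2L, 1L))

  vo <- intersect_sets(b, a)
  expect_equal(sort(vo$both), sort(ov$both))
  expect_equal(vo$only_a, ov$only_b)
  expect_equal(vo$only_b, ov$only_a)

  expect_length(intersect_sets(gene_set("X", "x"), gene_set("Y", "y"))$both, 0)
  same <- intersect_sets(a, gene_set("A2", c("c", "b", "a")))
  expect_length(same$only_a, 0)
  expect_length(same$only_b, 0)
  expect_setequal(same$both, a$members)
})

test_that("z-score composites standardize genes and detect planted shifts", {
  sim <- simulate_counts(100, 10, dispersion = 0.05, seed = 3L,
                         planted_degs = data.frame(gene = 1:20, log2fc = 0.6),
                         lib_size_range = NULL)
  logm <- log2(sim$matrix$values + 1)
  fs <- gene_set("FOCUS", sim$truth$gene_id)
  zc <- zscore_composite(logm, fs, sim$annotation)
  # per-gene standardization across samples: mean 0, population sd 1
  z <- (logm[fs$members, ] - rowMeans(logm[fs$members, ])) /
    sqrt(rowMeans((logm[fs$members, ] - rowMeans(logm[fs$members, ]))^2))
  expect_equal(rowMeans(z), rep(0, 20), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(sqrt(rowMeans(z^2)), rep(1, 20), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(zc$scores$score, unname(colMeans(z)), tolerance = 1e-12)
  med <- tapply(zc$scores$score, zc$scores$group, median)
  expect_gt(med[["B"]], med[["A"]])
  expect_lt(zc$p_value, 0.05)

  const <- logm
  const[1, ] <- 3
  expect_warning(zscore_composite(const, fs, sim$annotation),
                 "zero-variance")
  expect_error(zscore_composite(logm, gene_set("TINY", rownames(logm)[1]),
                                sim$annotation), "fewer than 2")
})

test_that("hypergeometric enrichment matches closed-form tail values", {
  uni <- gene_set("U", sprintf("u%02d", 1:10))
  term <- gene_set("T3", uni$members[1:3])
  # query = the whole term: p = 1 / C(10,3)
  enr <- fisher_enrich(gene_set("Q", uni$members[1:3]), list(term), uni)
  expect_equal(enr$p_value, 1 / choose(10, 3), tolerance = 1e-12)
  expect_equal(enr[, c("k", "K", "n", "N")],
               data.frame(k = 3L, K = 3L, n = 3L, N = 10L))

  # k = 0: the upper tail includes zero, so p = 1
  enr0 <- fisher_enrich(gene_set("Q", uni$members[4:6]), list(term), uni)
  expect_equal(enr0$p_value, 1)

  uni4 <- gene_set("U4", c("a", "b", "c", "d"))
  t2 <- gene_set("T2", c("a", "b"))
  enr1 <- fisher_enrich(gene_set("Q", c("a", "c")), list(t2), uni4)
  expect_equal(enr1$p_value, 1 - 1 / 6, tolerance = 1e-12)  # 1 - P(X = 0)

  expect_warning(fisher_enrich(gene_set("Q", c("a", "zzz")), list(t2), uni4),
                 "outside the universe")
  # one-sided tail and two-sided Fisher agree with fisher.test
  ft <- fisher.test(matrix(c(2, 0, 1, 1), 2), alternative = "greater")
  enr2 <- fisher_enrich(gene_set("Q", c("a", "b", "c")), list(t2), uni4)
  expect_equal(enr2$p_value, ft$p.value, tolerance = 1e-12)
})

test_that("ddCT relative expression follows the 2^(-ddCT) identities", {
  ann <- sample_annotation(c("c1", "c2", "t1"),
                           c("chow", "chow", "hfd"))
  ct <- rbind(
    data.frame(sample_id = c("c1", "c2", "t1"), gene_id = "36b4",
               ct = c(15, 15, 15)),
    data.frame(sample_id = c("c1", "c2", "t1"), gene_id = "Ctsb",
               ct = c(22, 22, 20))
  )
  out <- ddct_relative_expression(ct, "36b4", "chow", ann)
  # controls sit at ddCT = 0 -> rel_expr exactly 1
  expect_equal(out$rel_expr[out$group == "chow"], c(1, 1))
  # treatment: dCT 5 vs control mean 7 -> ddCT -2 -> 4-fold
  expect_equal(out$delta_delta_ct[out$sample_id == "t1"], -2)
  expect_equal(out$rel_expr[out$sample_id == "t1"], 4)

  # adding a constant to every CT of one sample cancels out
  ct2 <- ct
  ct2$ct[ct2$sample_id == "t1"] <- ct2$ct[ct2$sample_id == "t1"] + 3.7
  out2 <- ddct_relative_expression(ct2, "36b4", "chow", ann)
  expect_equal(out2$rel_expr, out$rel_expr, tolerance = 1e-12)

  # control-group geometric mean of rel_expr is 1 by construction
  expect_equal(mean(log2(out$rel_expr[out$group == "chow"])), 0,
               tolerance = 1e-12)

  expect_error(ddct_relative_expression(ct[ct$gene_id != "36b4", ],
                                        "36b4", "chow", ann), "c1")
})
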