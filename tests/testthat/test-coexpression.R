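test_that("network edges follow the correlation t-test with joint FDR", {
  x <- random_matrix(6, 12, seed = 5)
  x <- rbind(x, dup = x[1, ])            # perfect duplicate of gene 1
  net <- build_network(x, fdr_max = 0.05)
  edge <- net$edges[net$edges$gene_a == "dup" | net$edges$gene_b == "dup", ]
  pair <- edge[edge$gene_a == "dup" & edge$gene_b == "g001" |
                 edge$gene_a == "g001" & edge$gene_b == "dup", ]
  expect_equal(nrow(pair), 1L)
  expect_equal(pair$r, 1)
  expect_equal(pair$p_value, 0)

  # mirrored vectors: r and -r give the same two-sided p
  y <- rbind(a = 1:10 + rnorm(10, sd = 0.4),
             b = 1:10 + rnorm(10, sd = 0.4))
  y <- rbind(y, c = -y["b", ])
  colnames(y) <- paste0("s", 1:10)
  n0 <- build_network(y, fdr_max = 1 - 1e-12)
  eab <- n0$edges[n0$edges$gene_a == "a" & n0$edges$gene_b == "b", ]
  eac <- n0$edges[n0$edges$gene_a == "a" & n0$edges$gene_b == "c", ]
  expect_equal(eab$r, -eac$r, tolerance = 1e-12)
  expect_equal(eab$p_value, eac$p_value, tolerance = 1e-12)

  const <- rbind(x, flat = rep(2, 12))
  expect_warning(build_network(const, fdr_max = 0.5), "constant")
  expect_error(build_network(x[, 1:2]), "3 samples")
})

test_that("coreness equals brute-force peeling on known and random graphs", {
  # triangle plus a pendant vertex
  tri <- make_network(c("a", "b", "c", "d"),
                      rbind(c("a", "b"), c("b", "c"), c("a", "c"),
                            c("c", "d")))
  expect_equal(kcore_decomposition(tri),
               c(a = 2L, b = 2L, c = 2L, d = 1L))

  empty <- make_network(c("a", "b"), NULL)
  expect_equal(kcore_decomposition(empty), c(a = 0L, b = 0L))

  k5 <- make_network(letters[1:5], t(combn(letters[1:5], 2)))
  expect_equal(unname(kcore_decomposition(k5)), rep(4L, 5))

  set.seed(42)
  for (i in 1:200) {
    n <- sample(2:12, 1)
    nodes <- sprintf("v%02d", seq_len(n))
    all_pairs <- t(combn(nodes, 2))
    m <- sample.int(nrow(all_pairs), rbinom(1, nrow(all_pairs), 0.35))
    net <- make_network(nodes, all_pairs[m, , drop = FALSE])
    got <- kcore_decomposition(net)
    want <- oracle_coreness(net$nodes, net$edges)
    expect_equal(got, want[names(got)])
    # relabeling invariance
    relab <- net
    map <- setNames(sprintf("w%02d", sample.int(n)), nodes)
    relab$nodes <- sort(unname(map[net$nodes]))
    relab$edges$gene_a <- unname(map[net$edges$gene_a])
    relab$edges$gene_b <- unname(map[net$edges$gene_b])
    got2 <- kcore_decomposition(relab)
    expect_equal(unname(sort(got2)), unname(sort(got)))
    # removing an edge never increases coreness
    if (nrow(net$edges) > 0) {
      less <- net
      less$edges <- less$edges[-sample.int(nrow(less$edges), 1), ,
                               drop = FALSE]
      expect_true(all(kcore_decomposition(less) <= got))
    }
  }
})

test_that("hub ranking orders by coreness, then degree, then gene id", {
  # b-c-d triangle with b also holding two pendants: coreness ties at 2
  # for the triangle, b wins on degree
  net <- make_network(c("a", "b", "c", "d", "e"),
                      rbind(c("b", "c"), c("c", "d"), c("b", "d"),
                            c("a", "b"), c("b", "e")))
  h <- rank_hubs(net)
  expect_equal(h$gene_id[1], "b")
  expect_equal(h$rank, 1:5)
  # c and d tie completely: lexicographic id order decides
  expect_equal(h$gene_id[2:3], c("c", "d"))

  expect_equal(nrow(rank_hubs(make_network(character(0), NULL))), 0)
})

test_that("a planted hub in a realistic focus-list background is recovered", {
  hits <- sapply(1:10, function(s) {
    sim <- simulate_coexpression(322, 100, module_members = 1:12,
                                 hub_index = 1, loading_hub = 0.95,
                                 loading_member = 0.6, seed = s)
    h <- rank_hubs(build_network(sim$matrix, fdr_max = 0.05))
    h$gene_id[1] == sim$truth$hub
  })
  expect_gte(mean(hits), 0.9)
})

test_that("network files round-trip as edge list and parse as GraphML", {
  x <- random_matrix(8, 30, seed = 9)
  x[2, ] <- x[1, ] + rnorm(30, sd = 0.2)
  x[3, ] <- x[1, ] + rnorm(30, sd = 0.2)
  net <- build_network(x, fdr_max = 0.1)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  write_network_edgelist(net, p1)
  back <- read_results_table(p1)
  expect_equal(back$gene_a, net$edges$gene_a)
  expect_equal(back$r, net$edges$r, tolerance = 1e-5)
  p2 <- withr::local_tempfile(fileext = ".graphml")
  write_network_graphml(net, p2)
  g <- igraph::read_graph(p2, format = "graphml")
  expect_equal(igraph::gorder(g), length(net$nodes))
  expect_equal(igraph::gsize(g), nrow(net$edges))
  expect_true("coreness" %in% igraph::vertex_attr_names(g))
})
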