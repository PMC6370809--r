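test_that("profile enumeration matches the closed form and brute force", {
  u <- enumerate_profiles(4, 1)
  expect_equal(nrow(u$changes), 26)
  expect_equal(nrow(enumerate_profiles(4, 2)$changes), 124)

  u2 <- enumerate_profiles(2, 1)
  expect_equal(nrow(u2$changes), 2)
  expect_equal(unname(u2$changes[, 1]), c(-1, 1))  # down, up

  for (T in 2:5) {
    for (c in 1:2) {
      got <- enumerate_profiles(T, c)
      want <- oracle_profiles(T, c)
      expect_equal(nrow(got$changes), (2 * c + 1)^(T - 1) - 1)
      expect_equal(nrow(got$changes), length(want))
      # canonical lexicographic order, row by row
      for (i in seq_along(want)) {
        expect_equal(unname(got$changes[i, ]), want[[i]])
      }
    }
  }
  # templates are anchored cumulative sums
  expect_equal(unname(u$templates[1, ]), c(0, -1, -2, -3))
  expect_error(enumerate_profiles(1, 1), "T")
  expect_error(enumerate_profiles(4, 0), "c")
})

test_that("assignment is a brute-force arg-min with low-id tie break", {
  u <- enumerate_profiles(4, 1)
  # noiseless template -> its own profile at distance 0
  x <- rbind(1.0 * u$templates[7, ], 1.0 * u$templates[20, ])
  rownames(x) <- c("gA", "gB")
  colnames(x) <- c("t0", "t1", "t2", "t3")
  asg <- assign_profiles(x, u, step_size = 1)
  expect_equal(asg$profile_id, c(7L, 20L))
  expect_equal(asg$distance, c(0, 0))

  # exact midpoint between two templates: lower profile id wins
  mid <- (u$templates[3, ] + u$templates[5, ]) / 2
  m <- matrix(mid, 1, 4, dimnames = list("g", colnames(x)))
  expect_lte(assign_profiles(m, u)$profile_id, 5L)
  d3 <- sqrt(sum((mid - u$templates[3, ])^2))
  d5 <- sqrt(sum((mid - u$templates[5, ])^2))
  expect_equal(d3, d5)
  expect_equal(assign_profiles(m, u)$profile_id,
               min(which(abs(sqrt(colSums((t(u$templates) - mid)^2)) - d3)
                         < 1e-12)))

  # random anchored series against the brute-force arg-min
  set.seed(6)
  for (rep in 1:25) {
    s <- c(0, rnorm(3))
    mm <- matrix(s, 1, 4, dimnames = list("g", colnames(x)))
    d <- apply(u$templates, 1, function(tm) sqrt(sum((s - tm)^2)))
    expect_equal(assign_profiles(mm, u)$profile_id, unname(which.min(d)))
  }

  # anchoring: adding a constant to the whole series changes nothing
  y <- random_matrix(40, 4, seed = 3)
  colnames(y) <- colnames(x)
  expect_equal(assign_profiles(y + 5, u), assign_profiles(y, u))
  expect_error(assign_profiles(y[, 1:3], u), "time points")
})

test_that("profile significance is seeded, conserving and detects planting", {
  u <- enumerate_profiles(4, 1)
  empty <- data.frame(gene_id = character(0), profile_id = integer(0),
                      distance = numeric(0))
  expect_equal(nrow(profile_significance(empty, random_matrix(0, 4), u)), 0)

  sim <- simulate_timecourse(300, u,
                             data.frame(gene = 1:300, profile_id = 7L),
                             noise_sd = 0.1, seed = 5L)
  asg <- assign_profiles(sim$matrix, u, annotation = sim$annotation)
  sig <- profile_significance(asg, sim$matrix, u, n_permutations = 200,
                              seed = 5L, annotation = sim$annotation)
  expect_equal(sum(sig$observed_n), 300)        # conservation
  expect_lt(sig$fdr[sig$profile_id == 7L], 0.01)
  sig2 <- profile_significance(asg, sim$matrix, u, n_permutations = 200,
                               seed = 5L, annotation = sim$annotation)
  expect_identical(sig, sig2)                   # seeded determinism
  expect_error(profile_significance(asg, sim$matrix, u, n_permutations = 0),
               "n_permutations")

  # the 2x2 Fisher construction also flags the planted profile
  sigf <- profile_significance(asg, sim$matrix, u, n_permutations = 100,
                               seed = 5L, annotation = sim$annotation,
                               significance = "fisher2x2")
  expect_lt(sigf$p_value[sigf$profile_id == 7L], 0.01)
})

test_that("time-course DEG screen keeps responders and drops flat genes", {
  u <- enumerate_profiles(4, 1)
  sim <- simulate_timecourse(60, u,
                             data.frame(gene = 1:20, profile_id = 26L),
                             step_size = 1.5, noise_sd = 0.15,
                             replicates = 3, seed = 4L)
  kept <- timecourse_deg_filter(sim$matrix, sim$annotation)
  planted <- sim$truth$gene_id
  expect_gt(length(intersect(kept, planted)) / length(planted), 0.9)
  expect_lt(length(setdiff(kept, planted)), 10)
})
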