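# Independent brute-force oracles used to check the package's statistics.
# Each is written from the definition, not from the implementation path it
# verifies.

# Benjamini-Hochberg by the literal step-up definition:
# q_(i) = min_{j >= i} p_(j) * m / j, capped at 1, mapped to input order.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# coreness by peeling: for each candidate k remove vertices of degree < k
# until a fixed point; survivors have coreness >= k.
oracle_coreness <- function(nodes, edges) {
  core <- stats::setNames(integer(length(nodes)), nodes)
  k <- 1L
  repeat {
    present <- nodes
    repeat {
      e <- edges[edges$gene_a %in% present & edges$gene_b %in% present, ,
                 drop = FALSE]
      deg <- table(factor(c(e$gene_a, e$gene_b), levels = present))
      drop <- present[deg < k]
      if (!length(drop)) break
      present <- setdiff(present, drop)
    }
    if (!length(present)) break
    core[present] <- k
    k <- k + 1L
  }
  core
}

# wrap an arbitrary edge list as a network object for kcore/rank tests
make_network <- function(nodes, pairs) {
  edges <- if (length(pairs)) {
    ga <- pmin(pairs[, 1L], pairs[, 2L])
    gb <- pmax(pairs[, 1L], pairs[, 2L])
    data.frame(gene_a = ga, gene_b = gb, r = 0.9, p_value = 0, fdr = 0,
               stringsAsFactors = FALSE)
  } else {
    data.frame(gene_a = character(0), gene_b = character(0), r = numeric(0),
               p_value = numeric(0), fdr = numeric(0))
  }
  structure(list(nodes = sort(nodes), edges = edges, n_samples = 10L,
                 fdr_max = 0.05),
            class = "coexpression_network")
}

# brute-force weighted running sum for the enrichment score
oracle_running_sum <- function(metric, hit, weight_p) {
  N <- length(metric)
  nh <- sum(hit)
  w <- if (weight_p == 0) rep(1, N) else abs(metric)^weight_p
  tot <- sum(w[hit])
  rs <- numeric(N)
  cur <- 0
  for (i in seq_len(N)) {
    cur <- cur + if (hit[i]) w[i] / tot else -1 / (N - nh)
    rs[i] <- cur
  }
  rs
}

# two-sample KS statistic between hit and miss rank positions
oracle_ks <- function(hit) {
  N <- length(hit)
  f_hit <- cumsum(hit) / sum(hit)
  f_miss <- cumsum(!hit) / sum(!hit)
  max(abs(f_hit - f_miss))
}

# recursive enumeration of unit-change profiles in lexicographic order
oracle_profiles <- function(T, c) {
  steps <- seq.int(-c, c)
  vecs <- list(integer(0))
  for (i in seq_len(T - 1L)) {
    vecs <- unlist(lapply(vecs, function(v) {
      lapply(steps, function(s) c(v, s))
    }), recursive = FALSE)
  }
  vecs[vapply(vecs, function(v) any(v != 0L), logical(1L))]
}

# small random expression matrix with gene/sample names
random_matrix <- function(n_genes, n_samples, seed = 1L) {
  set.seed(seed)
  matrix(stats::rnorm(n_genes * n_samples), n_genes, n_samples,
         dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                         sprintf("s%03d", seq_len(n_samples))))
}
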