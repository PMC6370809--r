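# Short-time-series profile clustering: enumerate unit-change model
# profiles, assign each gene's anchored series to its nearest template,
# and test per-profile over-assignment against a per-gene time-permutation
# null. For a 4-point course with steps bounded by one unit there are
# 3^3 - 1 = 26 model profiles.

#' Enumerate model expression profiles
#'
#' A model profile is a vector of T - 1 integer changes between consecutive
#' time points, each in \[-c, c\], excluding the all-flat profile; its
#' template is the cumulative sum prefixed with 0. Exactly
#' (2c + 1)^(T - 1) - 1 profiles exist, ordered canonically (lexicographic
#' over change vectors, -c < ... < +c) with `profile_id` equal to the
#' 1-based rank in that order.
#'
#' @param T number of time points (>= 2).
#' @param c unit-change bound per step (>= 1).
#' @return object of class `profile_universe`: list with `T`, `c`,
#'   `changes` (matrix, one row per profile), `templates` (matrix, T
#'   columns), and `table` (data.frame `profile_id`, `change_vector`).
#' @export
#' @examples
#' length(enumerate_profiles(4, 1)$table$profile_id)  # 26
enumerate_profiles <- function(T, c = 1L) {
  assert_scalar_number(T, "T", lower = 2)
  assert_scalar_number(c, "c", lower = 1)
  T <- as.integer(T); c <- as.integer(c)
  steps <- seq.int(-c, c)
  grid <- as.matrix(expand.grid(rep(list(steps), T - 1L),
                                KEEP.OUT.ATTRS = FALSE))
  # expand.grid varies the first column fastest; flipping columns makes the
  # row order lexicographic in the change vector read left to right
  grid <- grid[, rev(seq_len(T - 1L)), drop = FALSE]
  flat <- rowSums(grid != 0L) == 0L
  changes <- unname(grid[!flat, , drop = FALSE])
  templates <- cbind(0L, t(apply(changes, 1L, cumsum)))
  if (T == 2L) templates <- cbind(0L, changes)  # apply() would drop dims
  ids <- seq_len(nrow(changes))
  rownames(changes) <- rownames(templates) <- ids
  structure(list(
    T = T, c = c, changes = changes, templates = templates,
    table = data.frame(
      profile_id = ids,
      change_vector = apply(changes, 1L, paste, collapse = ","),
      template = apply(templates, 1L, paste, collapse = ","),
      stringsAsFactors = FALSE)
  ), class = "profile_universe")
}

#' @export
print.profile_universe <- function(x, ...) {
  cat(sprintf("profile_universe: T = %d, c = %d, %d profiles\n",
              x$T, x$c, nrow(x$changes)))
  invisible(x)
}

# average (or median-summarise) replicate columns into one column per time
# point, in declared time order
summarise_timepoints <- function(values, annotation,
                                 summarise = c("mean", "median")) {
  summarise <- match.arg(summarise)
  if (is.null(annotation)) return(values)
  if (is.null(annotation$time_point)) {
    stop("annotation lacks a time_point column", call. = FALSE)
  }
  lev <- levels(annotation$time_point)
  fun <- if (summarise == "mean") rowMeans else
    function(m) apply(m, 1L, stats::median)
  out <- vapply(lev, function(tp) {
    ids <- annotation$sample_id[annotation$time_point == tp]
    fun(values[, ids, drop = FALSE])
  }, numeric(nrow(values)))
  colnames(out) <- lev
  out
}

#' Assign genes to their nearest model profile
#'
#' Each gene's series is anchored by subtracting its first-time-point
#' value, then compared with `step_size`-scaled templates by Euclidean
#' distance; the gene is assigned to the minimizing profile, ties going to
#' the lowest `profile_id`. Replicates, when an annotation with time
#' points is supplied, are averaged per time point first. Anchoring makes
#' the assignment invariant to adding a constant to a gene's whole series.
#'
#' @param series log2 [expression_matrix()] (or matrix) whose columns are
#'   time points in order, or replicate samples resolved via `annotation`.
#' @param profiles a [enumerate_profiles()] universe with matching T.
#' @param step_size log2 units per unit template change (> 0).
#' @param annotation optional [sample_annotation()] carrying `time_point`.
#' @param summarise replicate summary, `"mean"` or `"median"`.
#' @return data.frame `gene_id`, `profile_id`, `distance`.
#' @export
assign_profiles <- function(series, profiles, step_size = 1.0,
                            annotation = NULL,
                            summarise = c("mean", "median")) {
  assert_scalar_number(step_size, "step_size", lower = 0, strict_lower = TRUE)
  x <- as_em_values(series)
  x <- summarise_timepoints(x, annotation, match.arg(summarise))
  if (ncol(x) != profiles$T) {
    stop(sprintf("series has %d time points but the profile universe expects %d",
                 ncol(x), profiles$T), call. = FALSE)
  }
  anchored <- x - x[, 1L]
  tm <- step_size * profiles$templates
  # squared distances via ||a||^2 + ||t||^2 - 2 a.t
  d2 <- outer(rowSums(anchored^2), rowSums(tm^2), `+`) -
    2 * anchored %*% t(tm)
  d2[d2 < 0] <- 0
  best <- max.col(-d2, ties.method = "first")
  data.frame(gene_id = rownames(x), profile_id = best,
             distance = sqrt(d2[cbind(seq_len(nrow(d2)), best)]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Permutation significance of profile membership
#'
#' The null expected count per profile is the mean assigned count over
#' `n_permutations` in which each gene's time columns are permuted
#' independently (and the series re-anchored). The p-value is the
#' one-sided binomial tail P(X >= observed) with success probability
#' expected / n_genes; FDR across profiles by [bh_fdr()]. An alternative
#' 2x2 Fisher construction (assigned vs not x observed vs rounded
#' expected) is available via `significance = "fisher2x2"`.
#'
#' @inheritParams assign_profiles
#' @param assignments output of [assign_profiles()] for the same series.
#' @param n_permutations number of per-gene time permutations (>= 1).
#' @param seed integer seed for the permutation stream.
#' @param significance `"binomial"` (default) or `"fisher2x2"`.
#' @return data.frame `profile_id`, `observed_n`, `expected_n`, `p_value`,
#'   `fdr`.
#' @export
profile_significance <- function(assignments, series, profiles,
                                 step_size = 1.0, n_permutations = 200L,
                                 seed = 1L, annotation = NULL,
                                 summarise = c("mean", "median"),
                                 significance = c("binomial", "fisher2x2")) {
  significance <- match.arg(significance)
  assert_scalar_number(n_permutations, "n_permutations", lower = 1)
  ids <- profiles$table$profile_id
  if (nrow(assignments) == 0L) {
    return(data.frame(profile_id = integer(0), observed_n = integer(0),
                      expected_n = numeric(0), p_value = numeric(0),
                      fdr = numeric(0)))
  }
  x <- as_em_values(series)
  x <- summarise_timepoints(x, annotation, match.arg(summarise))
  G <- nrow(x); T_ <- ncol(x)
  observed <- tabulate(assignments$profile_id, nbins = length(ids))
  tm <- step_size * profiles$templates
  t2 <- rowSums(tm^2)
  counts <- matrix(0L, as.integer(n_permutations), length(ids))
  with_rng_seed(seed, {
    for (b in seq_len(as.integer(n_permutations))) {
      xp <- t(vapply(seq_len(G), function(i) x[i, sample.int(T_)],
                     numeric(T_)))
      anchored <- xp - xp[, 1L]
      d2 <- outer(rowSums(anchored^2), t2, `+`) - 2 * anchored %*% t(tm)
      best <- max.col(-d2, ties.method = "first")
      counts[b, ] <- tabulate(best, nbins = length(ids))
    }
  })
  expected <- colMeans(counts)
  p <- vapply(seq_along(ids), function(j) {
    pr <- min(expected[j] / G, 1)
    stats::pbinom(observed[j] - 1L, size = G, prob = pr, lower.tail = FALSE)
  }, numeric(1L))
  if (significance == "fisher2x2") {
    p <- vapply(seq_along(ids), function(j) {
      exp_n <- min(round(expected[j]), G)
      tab <- matrix(c(observed[j], G - observed[j],
                      exp_n, G - exp_n), nrow = 2L)
      stats::fisher.test(tab, alternative = "greater")$p.value
    }, numeric(1L))
  }
  data.frame(profile_id = ids, observed_n = observed, expected_n = expected,
             p_value = p, fdr = bh_fdr(p), stringsAsFactors = FALSE)
}

#' Per-time-point DEG filter for a replicated time course
#'
#' Screens genes for a differential response relative to the first
#' (baseline) time point: each later time point is contrasted with the
#' baseline by a Welch t test on the log2 values, and a gene is kept when
#' any time point passes the fold-change/p gates (defaults 2 / 0.5 at
#' p < 0.05, the microarray time-course criteria).
#'
#' @param series log2 [expression_matrix()].
#' @param annotation [sample_annotation()] with `time_point`; at least two
#'   replicates per time point are required.
#' @param gates a [deg_gates()]; defaults to the time-course gates.
#' @return character vector of gene ids passing at any time point.
#' @export
timecourse_deg_filter <- function(series, annotation,
                                  gates = deg_gates(2, 0.5, 0.05, "pvalue")) {
  lev <- levels(annotation$time_point)
  if (length(lev) < 2L) stop("need >= 2 time points", call. = FALSE)
  hits <- character(0)
  for (tp in lev[-1L]) {
    ann <- annotation[annotation$time_point %in% c(lev[1L], tp), , drop = FALSE]
    ann2 <- sample_annotation(ann$sample_id, as.character(ann$time_point))
    deg <- test_differential(series, ann2, group_a = lev[1L], group_b = tp,
                             method = "welch_log")
    deg <- classify_deg(deg, gates)
    hits <- union(hits, deg$gene_id[deg$status != "ns"])
  }
  hits
}
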