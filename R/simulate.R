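# Synthetic-data generators. Each emulates the statistical structure one
# downstream stage assumes — negative-binomial counts with planted
# fold-changes for the two-group DE stage, short log2 time courses planted
# into model profiles for the series-clustering stage, and a single-latent-
# factor module with a designated hub for the co-expression stage — and each
# returns a truth table sufficient to score recovery without re-deriving it.

#' Simulate a two-group negative-binomial count matrix with planted DEGs
#'
#' Counts are drawn per gene and sample as NB(mu, dispersion) with
#' variance = mu + dispersion * mu^2 (`dispersion = 0` gives the Poisson
#' limit). Group B means of planted genes are multiplied by
#' `2^log2fc`. Optional per-sample library-size factors (log-uniform)
#' exercise the median-of-ratios normalization downstream.
#'
#' @param n_genes number of genes.
#' @param samples_per_group samples in each of the two groups.
#' @param baseline_mean baseline expected count (> 0).
#' @param dispersion NB dispersion (>= 0).
#' @param planted_degs data.frame with columns `gene` (index in
#'   `1:n_genes`, unique) and `log2fc` (effect in group B); `NULL` for a
#'   global null.
#' @param lib_size_range range of per-sample library-size factors, drawn
#'   log-uniformly; `NULL` disables library-size variation.
#' @param group_labels length-2 character vector of group names.
#' @param seed integer seed; fixed seed gives a bitwise-identical matrix.
#' @return list with `matrix` (counts [expression_matrix()]),
#'   `annotation` ([sample_annotation()]), and `truth` (data.frame
#'   `gene_id`, `log2fc` of every planted gene).
#' @export
simulate_counts <- function(n_genes, samples_per_group, baseline_mean = 100,
                            dispersion = 0.1, planted_degs = NULL,
                            lib_size_range = c(0.7, 1.4),
                            group_labels = c("A", "B"), seed = 1L) {
  assert_scalar_number(n_genes, "n_genes", lower = 1)
  assert_scalar_number(samples_per_group, "samples_per_group", lower = 2)
  assert_scalar_number(baseline_mean, "baseline_mean", lower = 0,
                       strict_lower = TRUE)
  assert_scalar_number(dispersion, "dispersion", lower = 0)
  stopifnot(length(group_labels) == 2L)
  lfc <- rep(0, n_genes)
  if (!is.null(planted_degs) && nrow(planted_degs) > 0L) {
    idx <- planted_degs$gene
    if (anyDuplicated(idx) || any(idx < 1L | idx > n_genes)) {
      stop("planted gene indices must be unique and within 1:n_genes",
           call. = FALSE)
    }
    lfc[idx] <- planted_degs$log2fc
  }
  n <- as.integer(samples_per_group)
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  sample_ids <- c(sprintf("%s_%02d", group_labels[1L], seq_len(n)),
                  sprintf("%s_%02d", group_labels[2L], seq_len(n)))
  with_rng_seed(seed, {
    sf <- if (is.null(lib_size_range)) rep(1, 2L * n) else {
      exp(stats::runif(2L * n, log(lib_size_range[1L]), log(lib_size_range[2L])))
    }
    mu <- cbind(matrix(baseline_mean, n_genes, n),
                matrix(baseline_mean * 2^lfc, n_genes, n))
    mu <- sweep(mu, 2L, sf, `*`)
    counts <- if (dispersion == 0) {
      matrix(stats::rpois(length(mu), mu), n_genes, 2L * n)
    } else {
      matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
             n_genes, 2L * n)
    }
    dimnames(counts) <- list(gene_ids, sample_ids)
    planted <- which(lfc != 0)
    list(
      matrix = expression_matrix(counts, "counts"),
      annotation = sample_annotation(sample_ids,
                                     rep(group_labels, each = n)),
      truth = data.frame(gene_id = gene_ids[planted],
                         log2fc = lfc[planted],
                         stringsAsFactors = FALSE)
    )
  })
}

#' Simulate a short log2 time course with genes planted into model profiles
#'
#' Each planted gene's noiseless series equals `step_size` times the
#' cumulative-change template of its profile, anchored at 0 at the first
#' time point; unplanted genes are flat. Gaussian noise of sd `noise_sd` is
#' added per measurement; `replicates` measurements are generated per time
#' point.
#'
#' @param n_genes number of genes.
#' @param profiles profile universe from [enumerate_profiles()]; its
#'   template length fixes the number of time points.
#' @param planted_profiles data.frame with columns `gene` (index) and
#'   `profile_id` (a valid id of `profiles`); `NULL` plants nothing.
#' @param time_points ordered time labels (default the 4-point TNFa design
#'   0 h, 2 h, 24 h, 6 d).
#' @param step_size log2 units per unit template change.
#' @param noise_sd Gaussian noise sd on log2 values (>= 0).
#' @param replicates measurements per time point.
#' @param seed integer seed.
#' @return list with `matrix` (log2 [expression_matrix()]), `annotation`
#'   (group = time point), and `truth` (data.frame `gene_id`, `profile_id`).
#' @export
simulate_timecourse <- function(n_genes, profiles = enumerate_profiles(4L, 1L),
                                planted_profiles = NULL,
                                time_points = c("0h", "2h", "24h", "6d"),
                                step_size = 1.0, noise_sd = 0.25,
                                replicates = 3L, seed = 1L) {
  assert_scalar_number(n_genes, "n_genes", lower = 1)
  assert_scalar_number(noise_sd, "noise_sd", lower = 0)
  assert_scalar_number(step_size, "step_size", lower = 0, strict_lower = TRUE)
  tmpl <- profiles$templates
  T_ <- ncol(tmpl)
  if (length(time_points) != T_) {
    stop("length(time_points) must match the profile universe's template length",
         call. = FALSE)
  }
  base <- matrix(0, n_genes, T_)
  truth <- data.frame(gene_id = character(0), profile_id = integer(0),
                      stringsAsFactors = FALSE)
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  if (!is.null(planted_profiles) && nrow(planted_profiles) > 0L) {
    idx <- planted_profiles$gene
    pid <- planted_profiles$profile_id
    if (any(idx < 1L | idx > n_genes)) stop("planted gene index out of range",
                                            call. = FALSE)
    if (any(!pid %in% profiles$table$profile_id)) {
      stop("planted profile_id outside the enumerated universe", call. = FALSE)
    }
    base[idx, ] <- step_size * tmpl[pid, , drop = FALSE]
    truth <- data.frame(gene_id = gene_ids[idx], profile_id = pid,
                        stringsAsFactors = FALSE)
  }
  reps <- as.integer(replicates)
  sample_ids <- as.vector(t(outer(time_points, seq_len(reps),
                                  function(tp, r) sprintf("%s_r%d", tp, r))))
  tp_of_sample <- rep(time_points, each = reps)
  with_rng_seed(seed, {
    vals <- base[, rep(seq_len(T_), each = reps), drop = FALSE] +
      matrix(stats::rnorm(n_genes * T_ * reps, sd = noise_sd),
             n_genes, T_ * reps)
    dimnames(vals) <- list(gene_ids, sample_ids)
    list(
      matrix = expression_matrix(vals, "log2"),
      annotation = sample_annotation(sample_ids, group = tp_of_sample,
                                     time_point = tp_of_sample,
                                     replicate = rep(seq_len(reps), length(time_points)),
                                     time_levels = time_points),
      truth = truth
    )
  })
}

#' Simulate an expression matrix with one planted co-expression module
#'
#' Module members load on a single latent factor z ~ N(0,1):
#' x = loading * z + sqrt(1 - loading^2) * e with e ~ N(0, noise_sd^2),
#' so at the default `noise_sd = 1` every member has unit variance and two
#' members with loadings l1, l2 have expected Pearson correlation l1*l2.
#' The hub is distinguished purely by a larger loading
#' (`loading_hub > loading_member`), making it the member with maximal true
#' connectivity. Non-members are independent N(0,1) noise.
#'
#' @param n_genes total genes.
#' @param n_samples samples (columns).
#' @param module_members gene indices of the planted module.
#' @param hub_index one element of `module_members`.
#' @param loading_hub hub loading in (0, 1].
#' @param loading_member non-hub member loading in (0, 1], less than
#'   `loading_hub`.
#' @param noise_sd sd of the orthogonal noise component.
#' @param seed integer seed.
#' @return list with `matrix` (log2-kind [expression_matrix()]) and `truth`
#'   (list `module`, `hub` of gene ids).
#' @export
simulate_coexpression <- function(n_genes, n_samples, module_members,
                                  hub_index = module_members[1L],
                                  loading_hub = 0.95, loading_member = 0.6,
                                  noise_sd = 1.0, seed = 1L) {
  assert_scalar_number(loading_hub, "loading_hub", lower = 0, upper = 1,
                       strict_lower = TRUE)
  assert_scalar_number(loading_member, "loading_member", lower = 0, upper = 1,
                       strict_lower = TRUE)
  assert_scalar_number(noise_sd, "noise_sd", lower = 0)
  if (loading_member >= loading_hub) {
    stop("loading_member must be smaller than loading_hub", call. = FALSE)
  }
  if (!hub_index %in% module_members) {
    stop("hub_index must be one of module_members", call. = FALSE)
  }
  if (any(module_members < 1L | module_members > n_genes) ||
      anyDuplicated(module_members)) {
    stop("module_members must be unique indices within 1:n_genes",
         call. = FALSE)
  }
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  with_rng_seed(seed, {
    z <- stats::rnorm(n_samples)
    vals <- matrix(stats::rnorm(n_genes * n_samples), n_genes, n_samples)
    load <- rep(0, n_genes)
    load[module_members] <- loading_member
    load[hub_index] <- loading_hub
    mem <- module_members
    vals[mem, ] <- load[mem] %o% z +
      sqrt(1 - load[mem]^2) * noise_sd * vals[mem, , drop = FALSE]
    dimnames(vals) <- list(gene_ids, sprintf("s%03d", seq_len(n_samples)))
    list(
      matrix = expression_matrix(vals, "log2"),
      truth = list(module = gene_ids[module_members],
                   hub = gene_ids[hub_index])
    )
  })
}
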