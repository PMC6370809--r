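# Gene set enrichment analysis: rank genes by a two-group phenotype
# metric, walk the ranked list with a weighted running sum, and assess
# significance by phenotype (label) or gene-set permutation.

#' Rank genes by a two-group phenotype metric
#'
#' Metrics (group B vs group A): `signal_to_noise` = (mB - mA)/(sA + sB)
#' with each group sd floored at 0.2 * |group mean| (and at a small
#' absolute floor when the mean is 0, logged via message), the canonical
#' GSEA default; `log2fc` = mean difference for log2 matrices, log2 ratio
#' of means (pseudocount 0.5) for counts; `t_stat` = Welch t statistic.
#' Ordering is descending, ties broken by gene id for determinism.
#'
#' @param matrix an [expression_matrix()].
#' @param annotation two-group [sample_annotation()].
#' @param metric ranking metric.
#' @param group_a,group_b optional explicit group labels.
#' @return data.frame `gene_id`, `metric` in descending metric order.
#' @export
rank_genes <- function(matrix, annotation,
                       metric = c("signal_to_noise", "log2fc", "t_stat"),
                       group_a = NULL, group_b = NULL) {
  metric <- match.arg(metric)
  x <- as_em_values(matrix)
  grp <- match_two_groups(x, annotation, group_a, group_b)
  m <- rank_metric(x, grp$samples_a, grp$samples_b, metric,
                   counts = inherits(matrix, "expression_matrix") &&
                     matrix$value_kind == "counts", quiet = FALSE)
  ord <- order(-m, rownames(x), method = "radix")
  data.frame(gene_id = rownames(x)[ord], metric = m[ord],
             stringsAsFactors = FALSE, row.names = NULL)
}

# metric vector in gene order (not sorted); shared with the permutation loop
rank_metric <- function(x, samples_a, samples_b, metric, counts = FALSE,
                        quiet = TRUE) {
  A <- x[, samples_a, drop = FALSE]
  B <- x[, samples_b, drop = FALSE]
  nA <- ncol(A); nB <- ncol(B)
  mA <- rowMeans(A); mB <- rowMeans(B)
  if (metric == "log2fc") {
    return(if (counts) log2((mB + 0.5) / (mA + 0.5)) else mB - mA)
  }
  vA <- rowSums((A - mA)^2) / (nA - 1)
  vB <- rowSums((B - mB)^2) / (nB - 1)
  if (metric == "signal_to_noise") {
    floor_sd <- function(s, mu) pmax(s, 0.2 * abs(mu), 1e-8)
    sA <- floor_sd(sqrt(vA), mA)
    sB <- floor_sd(sqrt(vB), mB)
    if (!quiet && any(sqrt(vA) < sA | sqrt(vB) < sB)) {
      message("signal_to_noise: sd floored at 0.2*|mean| for some gene(s)")
    }
    return((mB - mA) / (sA + sB))
  }
  se <- sqrt(vA / nA + vB / nB)
  ifelse(se > 0, (mB - mA) / se, 0)
}

#' Weighted running-sum enrichment score
#'
#' Walking the ranked list, hits add |metric|^weight_p normalized by the
#' total over hits; misses subtract 1/(N - |S|). The enrichment score is
#' the running-sum value of maximal absolute deviation from zero (signed).
#' With `weight_p = 0` this is the classical Kolmogorov-Smirnov statistic
#' between the hit and miss positional distributions, and the running sum
#' ends at exactly 0.
#'
#' @param ranked output of [rank_genes()] (or any data.frame with
#'   `gene_id`, `metric`).
#' @param gene_set a [gene_set()]; must intersect the ranked list. If it
#'   covers the whole list the score degenerates to 1 (warning).
#' @param weight_p metric weighting exponent (>= 0), default 1.
#' @return list with `es` and `running_sum` (length N).
#' @export
enrichment_score <- function(ranked, gene_set, weight_p = 1) {
  assert_scalar_number(weight_p, "weight_p", lower = 0)
  hit <- ranked$gene_id %in% gene_set$members
  es_running(ranked$metric, hit, weight_p, warn = TRUE)
}

es_running <- function(metric, hit, weight_p, warn = FALSE) {
  N <- length(hit)
  nh <- sum(hit)
  if (nh == 0L) stop("gene set does not intersect the ranked list",
                     call. = FALSE)
  w <- if (weight_p == 0) rep(1, N) else abs(metric)^weight_p
  if (sum(w[hit]) == 0) w <- rep(1, N)  # all-zero metrics: fall back to KS
  if (nh == N) {
    if (warn) warning("gene set covers the entire ranked list", call. = FALSE)
    rs <- cumsum(w / sum(w))
    return(list(es = 1, running_sum = rs))
  }
  step <- numeric(N)
  step[hit] <- w[hit] / sum(w[hit])
  step[!hit] <- -1 / (N - nh)
  rs <- cumsum(step)
  list(es = rs[which.max(abs(rs))], running_sum = rs)
}

# es only, for permutation loops
es_value <- function(metric, hit, weight_p) {
  es_running(metric, hit, weight_p)$es
}

#' GSEA with permutation significance
#'
#' Observed enrichment scores come from [rank_genes()] +
#' [enrichment_score()]. The null distribution per set is built either by
#' permuting group labels and re-ranking (`"phenotype"`) or by sampling
#' random gene sets of the same size from the ranked list (`"gene_set"`).
#' `"auto"` picks phenotype permutation when both groups have >= 7
#' samples, else gene-set permutation (logged). NES = ES divided by the
#' mean |null ES| of matching sign; p = (1 + #null at least as extreme,
#' same sign)/(n_permutations + 1); FDR across sets by [bh_fdr()].
#'
#' @inheritParams rank_genes
#' @param gene_sets list of [gene_set()] objects.
#' @param n_permutations number of permutations (>= 100 recommended).
#' @param seed integer seed.
#' @param mode `"auto"`, `"phenotype"`, or `"gene_set"`.
#' @param weight_p metric weighting exponent.
#' @return data.frame `set_name`, `size`, `es`, `nes`, `p_value`, `fdr`,
#'   plus attribute `"running_sums"` (named list of observed traces).
#' @export
gsea_significance <- function(matrix, annotation, gene_sets,
                              n_permutations = 1000L, seed = 1L,
                              mode = c("auto", "phenotype", "gene_set"),
                              metric = c("signal_to_noise", "log2fc", "t_stat"),
                              weight_p = 1, group_a = NULL, group_b = NULL) {
  mode <- match.arg(mode)
  metric <- match.arg(metric)
  assert_scalar_number(n_permutations, "n_permutations", lower = 1)
  x <- as_em_values(matrix)
  counts_kind <- inherits(matrix, "expression_matrix") &&
    matrix$value_kind == "counts"
  grp <- match_two_groups(x, annotation, group_a, group_b)
  nA <- length(grp$samples_a); nB <- length(grp$samples_b)
  if (mode == "auto") {
    mode <- if (nA >= 7L && nB >= 7L) "phenotype" else "gene_set"
    message("gsea: permutation mode '", mode, "' selected")
  }
  obs_metric <- rank_metric(x, grp$samples_a, grp$samples_b, metric,
                            counts = counts_kind)
  ord <- order(-obs_metric, rownames(x), method = "radix")
  ranked_metric <- obs_metric[ord]
  ranked_genes <- rownames(x)[ord]
  masks <- lapply(gene_sets, function(s) rownames(x) %in% s$members)
  obs <- lapply(seq_along(gene_sets), function(j) {
    es_running(ranked_metric, masks[[j]][ord], weight_p)
  })
  obs_es <- vapply(obs, `[[`, numeric(1L), "es")

  nperm <- as.integer(n_permutations)
  null_es <- matrix(NA_real_, nperm, length(gene_sets))
  all_samples <- c(grp$samples_a, grp$samples_b)
  with_rng_seed(seed, {
    if (mode == "phenotype") {
      for (b in seq_len(nperm)) {
        perm <- sample(all_samples)
        pm <- rank_metric(x, perm[seq_len(nA)], perm[nA + seq_len(nB)],
                          metric, counts = counts_kind)
        pord <- order(-pm, rownames(x), method = "radix")
        pmetric <- pm[pord]
        for (j in seq_along(gene_sets)) {
          null_es[b, j] <- es_value(pmetric, masks[[j]][pord], weight_p)
        }
      }
    } else {
      N <- length(ranked_genes)
      for (j in seq_along(gene_sets)) {
        nh <- sum(masks[[j]])
        if (nh == 0L) next
        for (b in seq_len(nperm)) {
          hit <- logical(N)
          hit[sample.int(N, min(nh, N))] <- TRUE
          null_es[b, j] <- es_value(ranked_metric, hit, weight_p)
        }
      }
    }
  })
  res <- lapply(seq_along(gene_sets), function(j) {
    es <- obs_es[j]
    nulls <- null_es[, j]
    same <- nulls[sign(nulls) == sign(es) & sign(es) != 0]
    denom <- if (length(same)) mean(abs(same)) else mean(abs(nulls))
    nes <- if (denom > 0) es / denom else 0
    extreme <- if (es >= 0) sum(nulls >= es) else sum(nulls <= es)
    p <- (1 + extreme) / (nperm + 1)
    data.frame(set_name = gene_sets[[j]]$name, size = sum(masks[[j]]),
               es = es, nes = nes, p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(res, list(make.row.names = FALSE)))
  out$fdr <- bh_fdr(out$p_value)
  attr(out, "running_sums") <- stats::setNames(
    lapply(obs, `[[`, "running_sum"),
    vapply(gene_sets, `[[`, character(1L), "name"))
  out
}
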