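# Gene-set operations around the DE results: Venn-style intersection,
# z-score composite scoring with a Mann-Whitney group comparison,
# hypergeometric (Fisher-exact) term over-representation, and ddCT
# relative quantification for qPCR validation data.

#' Intersect two gene sets (Venn partition)
#'
#' @param a,b [gene_set()] objects.
#' @return list of class `overlap_result` with `set_a_name`, `set_b_name`,
#'   `only_a`, `both`, `only_b` and a `counts` vector.
#' @export
intersect_sets <- function(a, b) {
  stopifnot(inherits(a, "gene_set"), inherits(b, "gene_set"))
  both <- intersect(a$members, b$members)
  only_a <- setdiff(a$members, b$members)
  only_b <- setdiff(b$members, a$members)
  structure(list(set_a_name = a$name, set_b_name = b$name,
                 only_a = only_a, both = both, only_b = only_b,
                 counts = c(only_a = length(only_a), both = length(both),
                            only_b = length(only_b))),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("overlap %s vs %s: only_a %d | both %d | only_b %d\n",
              x$set_a_name, x$set_b_name,
              x$counts[["only_a"]], x$counts[["both"]], x$counts[["only_b"]]))
  invisible(x)
}

#' Composite z-score of a gene set per sample, compared between groups
#'
#' Each set gene is standardized across all samples (population sd,
#' divisor n); a sample's composite score is the mean z over the set
#' genes. Groups are compared with a two-sided Mann-Whitney U test using
#' the normal approximation with tie correction. Zero-variance genes are
#' excluded with a warning; at least two usable set genes are required.
#'
#' @param matrix an [expression_matrix()] (any value kind; counts are
#'   typically normalized and log-transformed first).
#' @param gene_set a [gene_set()].
#' @param annotation a two-group [sample_annotation()].
#' @return list with `scores` (data.frame `sample_id`, `group`, `score`),
#'   `p_value`, and `statistic` (the U statistic).
#' @export
zscore_composite <- function(matrix, gene_set, annotation) {
  x <- as_em_values(matrix)
  grp <- match_two_groups(x, annotation)
  genes <- intersect(gene_set$members, rownames(x))
  if (length(genes) < 2L) stop("fewer than 2 set genes present in the matrix",
                               call. = FALSE)
  sub <- x[genes, , drop = FALSE]
  mu <- rowMeans(sub)
  sd_pop <- sqrt(rowMeans((sub - mu)^2))
  usable <- sd_pop > 0
  if (any(!usable)) {
    warning("excluding zero-variance gene(s): ",
            paste(genes[!usable], collapse = ", "), call. = FALSE)
  }
  if (sum(usable) < 2L) stop("fewer than 2 usable (non-constant) set genes",
                             call. = FALSE)
  z <- (sub[usable, , drop = FALSE] - mu[usable]) / sd_pop[usable]
  score <- colMeans(z)
  ann <- annotation[match(colnames(x), annotation$sample_id), , drop = FALSE]
  scores <- data.frame(sample_id = colnames(x), group = ann$group,
                       score = score, stringsAsFactors = FALSE,
                       row.names = NULL)
  wa <- score[grp$samples_a]
  wb <- score[grp$samples_b]
  wt <- stats::wilcox.test(wb, wa, alternative = "two.sided", exact = FALSE,
                           correct = FALSE)
  list(scores = scores, p_value = wt$p.value,
       statistic = unname(wt$statistic))
}

#' Hypergeometric (Fisher-exact) term over-representation
#'
#' For each term: k = |query ∩ term|, K = |term ∩ universe|, n = |query|,
#' N = |universe|; the one-sided over-representation p-value is the
#' hypergeometric upper tail P(X >= k) (equivalently a one-sided Fisher
#' exact test on the 2x2 membership table). Query genes outside the
#' universe are dropped with a warning. A two-sided Fisher variant is
#' available via `alternative = "two.sided"`. FDR across terms by
#' [bh_fdr()].
#'
#' @param query a [gene_set()] of interesting genes (e.g. upregulated
#'   DEGs).
#' @param terms a list of [gene_set()] annotation terms.
#' @param universe a [gene_set()] defining the background (typically all
#'   genes in the expression matrix).
#' @param alternative `"greater"` (over-representation, default) or
#'   `"two.sided"`.
#' @return data.frame `term_name`, `k`, `K`, `n`, `N`, `p_value`, `fdr`.
#' @export
fisher_enrich <- function(query, terms, universe,
                          alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(inherits(query, "gene_set"), inherits(universe, "gene_set"))
  uni <- universe$members
  if (!length(uni)) stop("empty universe", call. = FALSE)
  q <- query$members
  outside <- setdiff(q, uni)
  if (length(outside)) {
    warning(sprintf("%d query gene(s) outside the universe dropped",
                    length(outside)), call. = FALSE)
    q <- intersect(q, uni)
  }
  N <- length(uni); n <- length(q)
  rows <- lapply(terms, function(tm) {
    members <- intersect(tm$members, uni)
    K <- length(members)
    k <- length(intersect(q, members))
    p <- if (alternative == "greater") {
      stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    } else {
      stats::fisher.test(matrix(c(k, K - k, n - k, N - K - n + k), 2L),
                         alternative = "two.sided")$p.value
    }
    data.frame(term_name = tm$name, k = k, K = K, n = n, N = N,
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(term_name = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p_value = numeric(0))
  }
  out$fdr <- bh_fdr(out$p_value)
  out
}

#' Relative expression by the ddCT method
#'
#' Per sample and target gene: delta_ct = CT_target - CT_reference;
#' delta_delta_ct = delta_ct - mean delta_ct of the control group for that
#' target; rel_expr = 2^(-delta_delta_ct). By construction the
#' control-group mean of log2(rel_expr) is 0 per target. Adding a constant
#' to every CT of a sample cancels in the reference subtraction.
#'
#' @param ct_table data.frame with columns `sample_id`, `gene_id`, `ct`.
#' @param reference_gene the internal-control gene (e.g. 36b4) whose CT is
#'   subtracted per sample.
#' @param control_group label of the baseline group in `annotation`.
#' @param annotation a [sample_annotation()] covering every sample in
#'   `ct_table`.
#' @return data.frame `sample_id`, `group`, `target_gene`, `delta_ct`,
#'   `delta_delta_ct`, `rel_expr`.
#' @export
ddct_relative_expression <- function(ct_table, reference_gene, control_group,
                                     annotation) {
  stopifnot(all(c("sample_id", "gene_id", "ct") %in% names(ct_table)))
  samples <- unique(ct_table$sample_id)
  grp <- annotation$group[match(samples, annotation$sample_id)]
  if (anyNA(grp)) {
    stop("sample(s) missing from annotation: ",
         paste(samples[is.na(grp)], collapse = ", "), call. = FALSE)
  }
  if (!control_group %in% grp) stop("control group is empty", call. = FALSE)
  ref <- ct_table[ct_table$gene_id == reference_gene, , drop = FALSE]
  ref_ct <- ref$ct[match(samples, ref$sample_id)]
  if (anyNA(ref_ct)) {
    stop("missing reference-gene CT for sample(s): ",
         paste(samples[is.na(ref_ct)], collapse = ", "), call. = FALSE)
  }
  targets <- setdiff(unique(ct_table$gene_id), reference_gene)
  rows <- lapply(targets, function(g) {
    tg <- ct_table[ct_table$gene_id == g, , drop = FALSE]
    ct <- tg$ct[match(samples, tg$sample_id)]
    if (anyNA(ct)) {
      stop(sprintf("missing CT of target '%s' for sample(s): %s", g,
                   paste(samples[is.na(ct)], collapse = ", ")), call. = FALSE)
    }
    dct <- ct - ref_ct
    ddct <- dct - mean(dct[grp == control_group])
    data.frame(sample_id = samples, group = grp, target_gene = g,
               delta_ct = dct, delta_delta_ct = ddct,
               rel_expr = 2^(-ddct), stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
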