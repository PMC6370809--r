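# Two-group differential expression on counts, with the fold-change and
# FDR gates used for the lean/obese contrast (1.2 / 0.833 at FDR 0.2) and
# the TNFa time course (2 / 0.5 at P 0.05).

#' Median-of-ratios size factors and normalized counts
#'
#' The size factor of sample j is the median, over genes whose counts are
#' positive in every sample, of count_gj divided by that gene's geometric
#' mean across samples. Normalized value = count / size factor. Doubling
#' every count of one sample is absorbed exactly by its size factor.
#'
#' @param counts counts-mode [expression_matrix()] or integer matrix.
#' @param positive_subset if no gene is positive in every sample, setting
#'   this to `TRUE` computes each gene's geometric mean over its positive
#'   entries only (and ratios where the count is positive) instead of
#'   erroring.
#' @return list with `size_factors` (named numeric) and `normalized`
#'   (numeric matrix).
#' @export
normalize_median_of_ratios <- function(counts, positive_subset = FALSE) {
  x <- as_em_values(counts)
  if (any(x < 0)) stop("counts must be non-negative", call. = FALSE)
  logx <- log(x)
  loggeo <- rowMeans(logx)                      # -Inf if any zero in row
  usable <- is.finite(loggeo)
  if (!any(usable)) {
    if (!positive_subset) {
      stop(paste("no gene has positive counts in every sample;",
                 "set positive_subset = TRUE to use per-gene positive entries"),
           call. = FALSE)
    }
    logx[!is.finite(logx)] <- NA
    loggeo <- rowMeans(logx, na.rm = TRUE)
    usable <- is.finite(loggeo)
  }
  sf <- apply(logx[usable, , drop = FALSE], 2L, function(col) {
    r <- col - loggeo[usable]
    exp(stats::median(r[is.finite(r)]))
  })
  list(size_factors = sf, normalized = sweep(x, 2L, sf, `/`))
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up adjustment q_(i) = min_{j >= i} p_(j) * m / j, capped at 1 and
#' mapped back to input order.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return q-values in the same order.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Fold-change / significance gates for DEG calling
#'
#' @param fc_up linear fold-change above which a gene can be called up
#'   (> 1); strict inequality.
#' @param fc_down fold change below which a gene can be called down
#'   (in (0,1)); strict inequality.
#' @param alpha significance ceiling (strict `<`, matching the printed
#'   "FDR < 0.2" convention).
#' @param alpha_kind whether `alpha` gates the FDR or the raw p-value.
#' @return a list of class `deg_gates`.
#' @export
deg_gates <- function(fc_up = 1.2, fc_down = 0.833, alpha = 0.2,
                      alpha_kind = c("fdr", "pvalue")) {
  alpha_kind <- match.arg(alpha_kind)
  assert_scalar_number(fc_up, "fc_up", lower = 1, strict_lower = TRUE)
  assert_scalar_number(fc_down, "fc_down", lower = 0, upper = 1,
                       strict_lower = TRUE)
  if (fc_down >= 1) stop("fc_down must be < 1", call. = FALSE)
  assert_scalar_number(alpha, "alpha", lower = 0, upper = 1,
                       strict_lower = TRUE)
  structure(list(fc_up = fc_up, fc_down = fc_down, alpha = alpha,
                 alpha_kind = alpha_kind), class = "deg_gates")
}

#' Two-group differential expression test
#'
#' For counts (`method = "nb_wald"`): counts are normalized by
#' [normalize_median_of_ratios()], genes below `min_mean` normalized mean
#' are dropped, and each remaining gene gets a negative-binomial Wald test
#' on its log fold change. The per-gene dispersion is estimated by method
#' of moments from the pooled within-group variance of normalized counts,
#' floored at 1e-8, then shrunk (weight `trend_weight`) toward a log-linear
#' mean-dispersion trend fitted across all genes. The Wald statistic is
#' referred to a t distribution on nA + nB - 2 degrees of freedom.
#'
#' For log2-scale matrices (`method = "welch_log"`, the default for
#' `value_kind == "log2"`): a Welch t test per gene on the log2 values,
#' with the fold change taken as 2^(mean difference). For counts under
#' `"welch_log"` the test runs on log2(normalized + 1).
#'
#' Fold change is group B over group A, computed on group means with a
#' pseudocount of 0.5 added to both means.
#'
#' @param counts an [expression_matrix()].
#' @param annotation a [sample_annotation()] with exactly two groups (or
#'   explicit `group_a`/`group_b`), each with >= 2 samples.
#' @param group_a,group_b optional explicit group labels; defaults to the
#'   order of first appearance in `annotation`.
#' @param method `"nb_wald"` or `"welch_log"`; `NULL` picks by value kind.
#' @param min_mean low-count filter on mean normalized count (counts only).
#' @param pseudocount added to both group means for the fold change.
#' @param trend_weight weight of the trend component in dispersion
#'   shrinkage (0 = raw moments, 1 = pure trend).
#' @param positive_subset passed to [normalize_median_of_ratios()].
#' @return data.frame of DEG records: `gene_id`, `base_mean`,
#'   `fold_change`, `log2_fc`, `p_value`, `fdr`, `status` (unset, `NA`;
#'   see [classify_deg()]).
#' @export
test_differential <- function(counts, annotation, group_a = NULL,
                              group_b = NULL, method = NULL,
                              min_mean = 1, pseudocount = 0.5,
                              trend_weight = 0.5, positive_subset = FALSE) {
  kind <- if (inherits(counts, "expression_matrix")) counts$value_kind else "counts"
  if (is.null(method)) method <- if (kind == "counts") "nb_wald" else "welch_log"
  method <- match.arg(method, c("nb_wald", "welch_log"))
  if (method == "nb_wald" && kind != "counts") {
    stop("nb_wald requires a counts-mode matrix", call. = FALSE)
  }
  x <- as_em_values(counts)
  grp <- match_two_groups(x, annotation, group_a, group_b)

  if (kind == "counts") {
    nrm <- normalize_median_of_ratios(x, positive_subset = positive_subset)
    y <- nrm$normalized
    keep <- rowMeans(y) >= min_mean
    if (!any(keep)) stop("no gene passes the low-count filter", call. = FALSE)
    y <- y[keep, , drop = FALSE]
  } else {
    y <- x
  }
  A <- y[, grp$samples_a, drop = FALSE]
  B <- y[, grp$samples_b, drop = FALSE]
  nA <- ncol(A); nB <- ncol(B)
  mA <- rowMeans(A); mB <- rowMeans(B)
  vA <- rowSums((A - mA)^2) / (nA - 1)
  vB <- rowSums((B - mB)^2) / (nB - 1)
  base_mean <- rowMeans(y)

  if (method == "nb_wald") {
    fc <- (mB + pseudocount) / (mA + pseudocount)
    s2 <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
    m <- (mA + mB) / 2
    raw <- (s2 - m) / m^2
    disp_raw <- pmax(raw, 1e-8)
    pos <- raw > 0 & m > 0
    disp_trend <- if (sum(pos) >= 10L) {
      cf <- stats::coef(stats::lm(log(raw[pos]) ~ log(m[pos])))
      pmax(exp(cf[[1L]] + cf[[2L]] * log(m)), 1e-8)
    } else {
      rep(max(stats::median(disp_raw), 1e-8), length(m))
    }
    disp <- trend_weight * disp_trend + (1 - trend_weight) * disp_raw
    vlA <- (1 / (mA + pseudocount) + disp) / nA
    vlB <- (1 / (mB + pseudocount) + disp) / nB
    se <- sqrt(vlA + vlB)
    z <- log(fc) / se
    p <- 2 * stats::pt(-abs(z), df = nA + nB - 2)
  } else {
    if (kind == "counts") {
      A <- log2(A + 1); B <- log2(B + 1)
      mA2 <- rowMeans(A); mB2 <- rowMeans(B)
      vA <- rowSums((A - mA2)^2) / (nA - 1)
      vB <- rowSums((B - mB2)^2) / (nB - 1)
      fc <- (mB + pseudocount) / (mA + pseudocount)
      d <- mB2 - mA2
    } else {
      fc <- 2^(mB - mA)
      d <- mB - mA
    }
    seA <- vA / nA; seB <- vB / nB
    se <- sqrt(seA + seB)
    df <- ifelse(se > 0,
                 (seA + seB)^2 / (seA^2 / (nA - 1) + seB^2 / (nB - 1)), 1)
    t <- ifelse(se > 0, d / se, 0)
    p <- ifelse(d == 0, 1, 2 * stats::pt(-abs(t), df = df))
    p[se == 0 & d != 0] <- 0
  }

  res <- data.frame(gene_id = rownames(y), base_mean = base_mean,
                    fold_change = fc, log2_fc = log2(fc), p_value = p,
                    fdr = bh_fdr(p), status = NA_character_,
                    stringsAsFactors = FALSE, row.names = NULL)
  res
}

#' Apply fold-change and significance gates to DEG records
#'
#' up: fold_change > fc_up and significance < alpha;
#' down: fold_change < fc_down and significance < alpha; else ns.
#' All inequalities strict, following the printed criteria.
#'
#' @param records output of [test_differential()].
#' @param gates a [deg_gates()].
#' @return `records` with `status` set to `"up"`, `"down"` or `"ns"`.
#' @export
classify_deg <- function(records, gates = deg_gates()) {
  stopifnot(inherits(gates, "deg_gates"))
  sig <- if (gates$alpha_kind == "fdr") records$fdr else records$p_value
  st <- rep("ns", nrow(records))
  st[records$fold_change > gates$fc_up & sig < gates$alpha] <- "up"
  st[records$fold_change < gates$fc_down & sig < gates$alpha] <- "down"
  records$status <- st
  records
}
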