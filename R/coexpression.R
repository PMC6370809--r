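# Pearson co-expression network with FDR-gated edges, and hub nomination
# by k-core decomposition with degree as tie break.

#' Build an FDR-thresholded Pearson co-expression network
#'
#' All unordered gene pairs are tested: two-sided p from
#' t = r * sqrt((n - 2)/(1 - r^2)) on n - 2 degrees of freedom, BH-FDR
#' across all tested pairs jointly, and an edge kept when fdr < `fdr_max`
#' (and |r| >= `r_min` when set). Constant genes are excluded with a
#' warning since r is undefined for them.
#'
#' @param matrix an [expression_matrix()] with >= 3 samples.
#' @param genes optional [gene_set()] restricting the network to a focus
#'   list (e.g. lysosomal/autophagic genes).
#' @param fdr_max edge FDR ceiling (default 0.05, the printed criterion).
#' @param r_min optional absolute-correlation floor; `NULL` (default)
#'   applies the FDR rule alone.
#' @return object of class `coexpression_network`: list with `nodes`
#'   (all tested gene ids), `edges` (data.frame `gene_a`, `gene_b`, `r`,
#'   `p_value`, `fdr` with `gene_a` < `gene_b`), `n_samples`, `fdr_max`.
#' @export
build_network <- function(matrix, genes = NULL, fdr_max = 0.05,
                          r_min = NULL) {
  assert_scalar_number(fdr_max, "fdr_max", lower = 0, upper = 1,
                       strict_lower = TRUE)
  x <- as_em_values(matrix)
  if (!is.null(genes)) {
    keep <- intersect(rownames(x), genes$members)
    x <- x[keep, , drop = FALSE]
  }
  n <- ncol(x)
  if (n < 3L) stop("need >= 3 samples to test correlations", call. = FALSE)
  sds <- apply(x, 1L, stats::sd)
  if (any(sds == 0)) {
    warning("excluding constant gene(s): ",
            paste(rownames(x)[sds == 0], collapse = ", "), call. = FALSE)
    x <- x[sds > 0, , drop = FALSE]
  }
  if (nrow(x) < 2L) stop("need >= 2 non-constant genes", call. = FALSE)
  R <- stats::cor(t(x))
  ut <- which(upper.tri(R), arr.ind = TRUE)
  r <- R[ut]
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1] <- 0
  fdr <- bh_fdr(p)
  keep <- fdr < fdr_max
  if (!is.null(r_min)) keep <- keep & abs(r) >= r_min
  ga <- rownames(x)[ut[, 1L]]
  gb <- rownames(x)[ut[, 2L]]
  swap <- ga > gb
  tmp <- ga[swap]; ga[swap] <- gb[swap]; gb[swap] <- tmp
  edges <- data.frame(gene_a = ga[keep], gene_b = gb[keep], r = r[keep],
                      p_value = p[keep], fdr = fdr[keep],
                      stringsAsFactors = FALSE, row.names = NULL)
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = sort(rownames(x)), edges = edges, n_samples = n,
                 fdr_max = fdr_max),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf("coexpression_network: %d nodes, %d edges (fdr < %g)\n",
              length(x$nodes), nrow(x$edges), x$fdr_max))
  invisible(x)
}

as_igraph <- function(network) {
  igraph::graph_from_data_frame(
    network$edges[, c("gene_a", "gene_b"), drop = FALSE],
    directed = FALSE,
    vertices = data.frame(name = network$nodes, stringsAsFactors = FALSE))
}

#' k-core decomposition of a co-expression network
#'
#' The coreness of a gene is the largest k such that it survives iterative
#' removal of all vertices of degree < k; genes with high coreness sit in
#' densely interconnected cores and are nominated as key regulatory genes.
#'
#' @param network a [build_network()] result.
#' @return named integer vector mapping gene id to coreness (0 for
#'   isolated genes; empty networks allowed).
#' @export
kcore_decomposition <- function(network) {
  stopifnot(inherits(network, "coexpression_network"))
  if (!length(network$nodes)) return(stats::setNames(integer(0), character(0)))
  g <- as_igraph(network)
  cr <- igraph::coreness(g)
  stats::setNames(as.integer(cr), igraph::V(g)$name)[network$nodes]
}

#' Rank genes as network hubs by coreness, then degree
#'
#' Descending coreness, ties by descending degree, remaining ties by gene
#' id; rank 1 is the nominated key regulatory gene (CTSB in the obese
#' adipose analysis this pipeline emulates).
#'
#' @param network a [build_network()] result.
#' @return data.frame `gene_id`, `degree`, `coreness`, `rank`.
#' @export
rank_hubs <- function(network) {
  core <- kcore_decomposition(network)
  if (!length(core)) {
    return(data.frame(gene_id = character(0), degree = integer(0),
                      coreness = integer(0), rank = integer(0)))
  }
  g <- as_igraph(network)
  deg <- stats::setNames(as.integer(igraph::degree(g)),
                         igraph::V(g)$name)[network$nodes]
  ord <- order(-core, -deg, network$nodes, method = "radix")
  data.frame(gene_id = network$nodes[ord], degree = unname(deg[ord]),
             coreness = unname(core[ord]), rank = seq_along(ord),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a network as an edge-list TSV
#'
#' Columns `gene_a`, `gene_b`, `r`, `p_value`, `fdr`.
#'
#' @param network a [build_network()] result.
#' @param path output path.
#' @param digits significant digits for numeric columns.
#' @export
write_network_edgelist <- function(network, path, digits = 6L) {
  write_results_table(network$edges, path, digits = digits)
}

#' Write a network as GraphML with degree/coreness node attributes
#'
#' @param network a [build_network()] result.
#' @param path output path (.graphml).
#' @export
write_network_graphml <- function(network, path) {
  g <- as_igraph(network)
  core <- kcore_decomposition(network)
  igraph::V(g)$degree <- as.integer(igraph::degree(g))
  igraph::V(g)$coreness <- unname(core[igraph::V(g)$name])
  if (nrow(network$edges)) igraph::E(g)$r <- network$edges$r
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
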