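#' Construct a validated expression matrix
#'
#' The central container of the pipeline: a genes x samples numeric matrix
#' with unique row (gene) and column (sample) identifiers. `value_kind`
#' records whether entries are raw counts (non-negative integers, as produced
#' by read counting of bulk RNA-seq) or log2-scale intensities/abundances
#' (reals, as in a normalized microarray series).
#'
#' @param values numeric matrix with rownames (gene ids) and colnames
#'   (sample ids).
#' @param value_kind `"counts"` or `"log2"`.
#' @return an object of class `expression_matrix`: a list with elements
#'   `values`, `value_kind`.
#' @export
expression_matrix <- function(values, value_kind = c("counts", "log2")) {
  value_kind <- match.arg(value_kind)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix", call. = FALSE)
  }
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("'values' must carry gene ids as rownames and sample ids as colnames",
         call. = FALSE)
  }
  dup_g <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup_g)) {
    stop("duplicate gene id(s): ", paste(dup_g, collapse = ", "),
         call. = FALSE)
  }
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup_s)) {
    stop("duplicate sample id(s): ", paste(dup_s, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing value at gene '%s', sample '%s'; imputation is not supported",
                 gene_ids[bad[1L]], sample_ids[bad[2L]]), call. = FALSE)
  }
  if (value_kind == "counts") {
    if (any(values < 0)) {
      bad <- which(values < 0, arr.ind = TRUE)[1L, ]
      stop(sprintf("negative count %s at gene '%s', sample '%s'",
                   format(values[bad[1L], bad[2L]]),
                   gene_ids[bad[1L]], sample_ids[bad[2L]]), call. = FALSE)
    }
    if (any(values != round(values))) {
      bad <- which(values != round(values), arr.ind = TRUE)[1L, ]
      stop(sprintf("non-integer count %s at gene '%s', sample '%s'",
                   format(values[bad[1L], bad[2L]]),
                   gene_ids[bad[1L]], sample_ids[bad[2L]]), call. = FALSE)
    }
  }
  structure(list(values = values, value_kind = value_kind),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix [%s]: %d genes x %d samples\n",
              x$value_kind, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

# accept either an expression_matrix or a bare named numeric matrix
as_em_values <- function(x) {
  if (inherits(x, "expression_matrix")) return(x$values)
  if (is.matrix(x) && is.numeric(x)) return(x)
  stop("expected an expression_matrix or a numeric matrix", call. = FALSE)
}

#' Construct a sample annotation table
#'
#' Maps samples to a two-group contrast (e.g. lean/obese, control/TNFa) and
#' optionally to ordered time points for time-course data.
#'
#' @param sample_id character vector of sample ids.
#' @param group group label per sample.
#' @param time_point optional time label per sample; its total order is taken
#'   from `time_levels` (or order of first appearance).
#' @param replicate optional replicate index.
#' @param time_levels optional character vector declaring the time order.
#' @return a `data.frame` of class `sample_annotation`.
#' @export
sample_annotation <- function(sample_id, group, time_point = NULL,
                              replicate = NULL, time_levels = NULL) {
  stopifnot(length(group) == length(sample_id))
  if (anyDuplicated(sample_id)) {
    stop("duplicate sample id(s) in annotation", call. = FALSE)
  }
  ann <- data.frame(sample_id = as.character(sample_id),
                    group = as.character(group),
                    stringsAsFactors = FALSE)
  if (!is.null(time_point)) {
    stopifnot(length(time_point) == length(sample_id))
    lev <- if (is.null(time_levels)) unique(as.character(time_point)) else time_levels
    ann$time_point <- factor(as.character(time_point), levels = lev, ordered = TRUE)
    if (anyNA(ann$time_point)) {
      stop("time_point value outside the declared time_levels", call. = FALSE)
    }
  }
  if (!is.null(replicate)) ann$replicate <- as.integer(replicate)
  class(ann) <- c("sample_annotation", "data.frame")
  ann
}

# check annotation against a matrix and return the two group index lists
match_two_groups <- function(values, annotation, group_a = NULL, group_b = NULL) {
  missing_s <- setdiff(annotation$sample_id, colnames(values))
  if (length(missing_s)) {
    stop("annotated sample(s) absent from matrix: ",
         paste(missing_s, collapse = ", "), call. = FALSE)
  }
  groups <- unique(annotation$group)
  if (is.null(group_a) || is.null(group_b)) {
    if (length(groups) != 2L) {
      stop("annotation must define exactly two groups (found: ",
           paste(groups, collapse = ", "), ")", call. = FALSE)
    }
    group_a <- groups[1L]
    group_b <- groups[2L]
  }
  ia <- annotation$sample_id[annotation$group == group_a]
  ib <- annotation$sample_id[annotation$group == group_b]
  if (length(ia) < 2L || length(ib) < 2L) {
    stop("each group in a two-group contrast needs at least 2 samples",
         call. = FALSE)
  }
  list(group_a = group_a, group_b = group_b, samples_a = ia, samples_b = ib)
}

#' Read a tab-separated expression matrix
#'
#' First column gene ids, header row sample ids. Validation (duplicate ids,
#' negative or fractional counts, non-numeric cells) happens at the boundary
#' so downstream stages can assume a clean matrix.
#'
#' @inheritParams expression_matrix
#' @param path file path to a TSV table.
#' @return an [expression_matrix()].
#' @export
read_expression_matrix <- function(path, value_kind = c("counts", "log2")) {
  value_kind <- match.arg(value_kind)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (ncol(tab) < 2L) stop("matrix file needs a gene-id column plus >= 1 sample",
                           call. = FALSE)
  gene_ids <- tab[[1L]]
  sample_ids <- colnames(tab)[-1L]
  vals <- suppressWarnings(
    vapply(tab[-1L], as.numeric, numeric(nrow(tab)))
  )
  vals <- matrix(vals, nrow = nrow(tab),
                 dimnames = list(gene_ids, sample_ids))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell at row %d (gene '%s'), column '%s' in %s",
                 bad[1L], gene_ids[bad[1L]], sample_ids[bad[2L]], path),
         call. = FALSE)
  }
  expression_matrix(vals, value_kind)
}

#' Write an expression matrix as TSV
#'
#' @param em an [expression_matrix()] or named numeric matrix.
#' @param path output path.
#' @param digits significant digits for real-valued matrices; counts are
#'   written exactly.
#' @export
write_expression_matrix <- function(em, path, digits = 6L) {
  vals <- as_em_values(em)
  kind <- if (inherits(em, "expression_matrix")) em$value_kind else "log2"
  out <- if (kind == "counts") {
    format(vals, scientific = FALSE, trim = TRUE)
  } else {
    formatC(vals, digits = digits, format = "g")
  }
  df <- data.frame(gene_id = rownames(vals), out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a gene set
#'
#' @param name non-empty set name.
#' @param members gene identifiers; deduplicated, must be non-empty.
#' @param description free-text description.
#' @return an object of class `gene_set`.
#' @export
gene_set <- function(name, members, description = "") {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("gene set name must be a non-empty string", call. = FALSE)
  }
  members <- as.character(members)
  if (anyDuplicated(members)) {
    warning(sprintf("gene set '%s': duplicate members removed", name),
            call. = FALSE)
    members <- unique(members)
  }
  if (!length(members)) {
    stop(sprintf("gene set '%s' has no members", name), call. = FALSE)
  }
  structure(list(name = name, description = description, members = members),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set '%s' (%d genes)\n", x$name, length(x$members)))
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' name, description, member genes. Member order is preserved; duplicate
#' members within a line are dropped with a warning.
#'
#' @param path GMT file path.
#' @return a named list of [gene_set()] objects.
#' @export
read_gene_sets_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  sets <- vector("list", length(keep))
  nms <- character(length(keep))
  for (i in seq_along(keep)) {
    ln <- keep[i]
    fields <- strsplit(lines[ln], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop(sprintf("GMT line %d: expected >= 3 tab-separated fields, got %d",
                   ln, length(fields)), call. = FALSE)
    }
    sets[[i]] <- gene_set(fields[1L], fields[-(1:2)], description = fields[2L])
    nms[i] <- fields[1L]
  }
  dup <- unique(nms[duplicated(nms)])
  if (length(dup)) {
    stop("duplicate gene set name(s) in GMT: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  names(sets) <- nms
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets a list of [gene_set()] objects.
#' @param path output path.
#' @export
write_gene_sets_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    paste(c(s$name, if (nzchar(s$description)) s$description else ".",
            s$members), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Write a result table as TSV with fixed precision
#'
#' All result tables of the pipeline (DEG calls, profile assignments,
#' enrichment records, hub ranks, ...) go through this writer so that
#' re-running a seeded pipeline reproduces byte-identical files.
#'
#' @param records a data.frame.
#' @param path output path.
#' @param digits significant digits used for numeric (non-integer) columns.
#' @export
write_results_table <- function(records, path, digits = 6L) {
  stopifnot(is.data.frame(records))
  out <- records
  for (j in seq_along(out)) {
    v <- out[[j]]
    if (is.double(v)) out[[j]] <- formatC(v, digits = digits, format = "g")
    if (is.factor(v)) out[[j]] <- as.character(v)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a result table written by [write_results_table()]
#'
#' @param path TSV path.
#' @return a data.frame.
#' @export
read_results_table <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
}
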