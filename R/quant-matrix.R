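# The quantification container: a numeric matrix of log2 LFQ intensities
# (rows = protein groups, columns = samples) with a group label per column
# and NA marking missing values.

#' Construct a quantification matrix
#'
#' Bundles a log2 intensity matrix with per-sample group labels.  Missing
#' values are `NA`; present values must be finite.
#'
#' @param values Numeric matrix, rows named by protein-group id, columns by
#'   sample id.
#' @param groups Character vector of group labels, one per column (optionally
#'   named by sample id).
#' @return A `quant_matrix` object (a numeric matrix with a `groups`
#'   attribute).
#' @export
quant_matrix <- function(values, groups) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values))) {
    if (nrow(values) > 0L) {
      stop("quant_matrix rows must be named by protein-group id", call. = FALSE)
    }
    rownames(values) <- character(0)
  }
  if (is.null(colnames(values))) {
    stop("quant_matrix columns must be named by sample id", call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate protein-group ids in quant matrix", call. = FALSE)
  }
  if (!is.null(names(groups))) {
    missing <- setdiff(names(groups), colnames(values))
    if (length(missing)) {
      stop("sample(s) in group map absent from matrix: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    groups <- groups[colnames(values)]
  }
  if (length(groups) != ncol(values)) {
    stop("need exactly one group label per sample column", call. = FALSE)
  }
  if (any(!is.finite(values) & !is.na(values))) {
    stop("non-finite intensities present (use NA for missing values)", call. = FALSE)
  }
  structure(values, groups = as.character(groups), class = c("quant_matrix", "matrix", "array"))
}

#' @export
print.quant_matrix <- function(x, ...) {
  g <- attr(x, "groups")
  cat("quant_matrix: ", nrow(x), " protein groups x ", ncol(x), " samples\n", sep = "")
  cat("groups: ", paste(sprintf("%s(%d)", names(table(g)), table(g)), collapse = ", "), "\n", sep = "")
  cat("missing values: ", sum(is.na(x)), "\n", sep = "")
  invisible(x)
}

#' Group labels of a quant matrix
#' @param qm A [quant_matrix()].
#' @return Character vector of per-column group labels.
#' @export
sample_groups <- function(qm) attr(qm, "groups")

# Subset rows and/or columns, keeping the groups attribute aligned.
subset_quant <- function(qm, rows = NULL, cols = NULL) {
  g <- attr(qm, "groups")
  v <- unclass(qm)
  attr(v, "groups") <- NULL
  if (!is.null(rows)) v <- v[rows, , drop = FALSE]
  if (!is.null(cols)) {
    idx <- if (is.character(cols)) match(cols, colnames(v)) else cols
    v <- v[, idx, drop = FALSE]
    g <- g[idx]
  }
  quant_matrix(v, g)
}

# Column indices per group, in first-appearance order.
group_index <- function(qm) {
  g <- attr(qm, "groups")
  split(seq_along(g), factor(g, levels = unique(g)))
}

#' Read a tab-separated quantification table
#'
#' Parses a TSV whose first column holds protein-group ids and whose
#' remaining columns are per-sample log2 intensities.  Empty cells, `NA`
#' and `NaN` denote missing values; any other non-numeric cell is an error.
#' Only the samples named in `group_map` are retained, in file order.
#'
#' @param path Path to the TSV file.
#' @param group_map Named character vector mapping sample (column) names to
#'   group labels, e.g. `c(WT_1 = "WT", ..., R40A_3 = "R40A")`.
#' @return A [quant_matrix()].
#' @export
read_quant_table <- function(path, group_map) {
  stopifnot(is.character(group_map), !is.null(names(group_map)))
  raw <- read.delim(path, check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 2L) {
    stop("quant table needs an id column plus at least one sample column", call. = FALSE)
  }
  ids <- raw[[1L]]
  absent <- setdiff(names(group_map), colnames(raw)[-1L])
  if (length(absent)) {
    stop("sample(s) in group map absent from table header: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  keep <- intersect(colnames(raw)[-1L], names(group_map))
  vals <- sapply(keep, function(cn) {
    cell <- trimws(raw[[cn]])
    miss <- cell == "" | toupper(cell) %in% c("NA", "NAN")
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!miss & is.na(num))
    if (length(bad)) {
      stop("non-numeric value '", cell[bad[1L]], "' in column '", cn,
           "', row ", bad[1L], call. = FALSE)
    }
    num[miss] <- NA_real_
    num
  })
  vals <- matrix(vals, nrow = nrow(raw), dimnames = list(ids, keep))
  quant_matrix(vals, group_map[keep])
}

#' Write a quant matrix to TSV
#'
#' @param qm A [quant_matrix()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_quant_table <- function(qm, path) {
  df <- data.frame(protein_id = rownames(qm), unclass(qm)[, , drop = FALSE],
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
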