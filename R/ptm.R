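# Co-location of known post-translational modification (PTM) sites with
# K/R-motif-containing IDRs, summarized per dataset as the share of
# qualifying IDRs that contain at least one site of each modification type.

PTM_TYPES <- c("acetylation", "methylation", "phosphorylation",
               "sumoylation", "ubiquitination")

#' Load a PTM site table
#'
#' Reads a TSV with columns `protein_id`, `position` (1-based residue
#' index) and `ptm_type`.  Types outside the closed set (acetylation,
#' methylation, phosphorylation, sumoylation, ubiquitination) are skipped
#' with a warning; duplicate `(protein, position, type)` rows are collapsed.
#'
#' @param path Path to the TSV file.
#' @param proteome Optional named character vector; positions beyond the
#'   protein length are then an error.
#' @return Data frame `protein_id`, `position`, `ptm_type`.
#' @export
load_ptm_table <- function(path, proteome = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  required <- c("protein_id", "position", "ptm_type")
  if (!all(required %in% colnames(df))) {
    stop("PTM table must have columns: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  df <- df[, required]
  if (nrow(df) == 0L) {
    return(df)
  }
  df$position <- as.integer(df$position)
  df$ptm_type <- tolower(df$ptm_type)
  if (any(df$position < 1L, na.rm = TRUE) || anyNA(df$position)) {
    stop("PTM positions must be positive integers", call. = FALSE)
  }
  unknown <- !df$ptm_type %in% PTM_TYPES
  if (any(unknown)) {
    warning("skipping ", sum(unknown), " PTM row(s) with unknown type(s): ",
            paste(unique(df$ptm_type[unknown]), collapse = ", "), call. = FALSE)
    df <- df[!unknown, , drop = FALSE]
  }
  if (!is.null(proteome) && nrow(df)) {
    absent <- setdiff(unique(df$protein_id), names(proteome))
    if (length(absent)) {
      stop("PTM protein(s) absent from proteome: ",
           paste(head(absent, 3L), collapse = ", "), call. = FALSE)
    }
    bad <- which(df$position > nchar(proteome[df$protein_id]))
    if (length(bad)) {
      stop("PTM position exceeds protein length at row ", bad[1L], call. = FALSE)
    }
  }
  df <- unique(df)
  rownames(df) <- NULL
  df
}

#' Restrict consensus IDRs to those containing a motif hit
#'
#' Keeps the IDRs that fully contain at least one hit of the chosen
#' pattern.
#'
#' @param regions Consensus IDR data frame (`protein_id`, `start`, `end`).
#' @param hits Annotated motif hit data frame.
#' @param pattern_id Pattern to require (default `"long"`).
#' @return Subset of `regions`.
#' @export
motif_containing_idrs <- function(regions, hits, pattern_id = "long") {
  hits <- hits[hits$pattern_id == pattern_id, , drop = FALSE]
  if (nrow(regions) == 0L || nrow(hits) == 0L) {
    return(regions[integer(), , drop = FALSE])
  }
  keep <- vapply(seq_len(nrow(regions)), function(i) {
    h <- hits[hits$protein_id == regions$protein_id[i], , drop = FALSE]
    any(h$start >= regions$start[i] & h$end <= regions$end[i])
  }, logical(1L))
  out <- regions[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-IDR PTM presence flags
#'
#' Flags each IDR, per modification type, when at least one site of that
#' type falls within the IDR's span (presence, not count).
#'
#' @param sites PTM site data frame (see [load_ptm_table()]).
#' @param motif_idrs IDR data frame (`protein_id`, `start`, `end`),
#'   typically from [motif_containing_idrs()].
#' @return Logical matrix, one row per IDR, one column per PTM type.
#' @export
ptm_in_motif_idrs <- function(sites, motif_idrs) {
  flags <- matrix(FALSE, nrow = nrow(motif_idrs), ncol = length(PTM_TYPES),
                  dimnames = list(NULL, PTM_TYPES))
  if (nrow(motif_idrs) == 0L || nrow(sites) == 0L) {
    return(flags)
  }
  by_protein <- split(sites, sites$protein_id)
  for (i in seq_len(nrow(motif_idrs))) {
    s <- by_protein[[motif_idrs$protein_id[i]]]
    if (is.null(s)) next
    inside <- s[s$position >= motif_idrs$start[i] & s$position <= motif_idrs$end[i], ,
                drop = FALSE]
    flags[i, unique(inside$ptm_type)] <- TRUE
  }
  flags
}

#' PTM frequency table over motif-containing IDRs
#'
#' For each dataset, counts the consensus IDRs (of that dataset's
#' proteins) that contain at least one hit of the chosen K/R pattern, and
#' the percentage of those IDRs carrying at least one site of each PTM
#' type.  The unit is the IDR, not the protein: one protein may contribute
#' several qualifying IDRs.
#'
#' @param datasets Named list of protein-id vectors.
#' @param regions Consensus IDR data frame.
#' @param hits Annotated motif hit data frame.
#' @param sites PTM site data frame.
#' @param pattern_id K/R pattern to require (default `"long"`).
#' @return Data frame: `dataset`, `n_idrs`, then one percentage column per
#'   PTM type (`NA` percentages when a dataset has no qualifying IDR).
#' @export
ptm_frequency_table <- function(datasets, regions, hits, sites,
                                pattern_id = "long") {
  stopifnot(is.list(datasets), !is.null(names(datasets)))
  motif_idrs <- motif_containing_idrs(regions, hits, pattern_id)
  rows <- lapply(names(datasets), function(ds) {
    idrs <- motif_idrs[motif_idrs$protein_id %in% datasets[[ds]], , drop = FALSE]
    n <- nrow(idrs)
    pct <- if (n == 0L) {
      setNames(rep(NA_real_, length(PTM_TYPES)), PTM_TYPES)
    } else {
      100 * colMeans(ptm_in_motif_idrs(sites, idrs))
    }
    cbind(data.frame(dataset = ds, n_idrs = n, stringsAsFactors = FALSE),
          as.data.frame(as.list(pct)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
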