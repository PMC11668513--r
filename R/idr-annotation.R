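# Intrinsically disordered region (IDR) annotation from per-predictor
# interval tables (D2P2-style: several independent disorder predictors per
# protein).  Coordinates are 1-based inclusive throughout, the
# PROSITE/UniProt convention.

# Normalize a disorder table: per (protein, predictor), sort and merge
# overlapping or touching intervals.
normalize_disorder <- function(df) {
  if (nrow(df) == 0L) {
    return(df[, c("protein_id", "predictor", "start", "end")])
  }
  key <- paste(df$protein_id, df$predictor, sep = "\r")
  rng <- IRanges::IRanges(start = df$start, end = df$end)
  merged <- IRanges::reduce(S4Vectors::split(rng, factor(key, levels = unique(key))))
  n <- S4Vectors::elementNROWS(merged)
  flat <- unlist(merged, use.names = FALSE)
  keys <- rep(names(merged), n)
  parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  out <- data.frame(
    protein_id = parts[, 1L],
    predictor = parts[, 2L],
    start = IRanges::start(flat),
    end = IRanges::end(flat),
    stringsAsFactors = FALSE
  )
  out[order(out$protein_id, out$predictor, out$start), , drop = FALSE]
}

#' Load a per-predictor disorder interval table
#'
#' Reads a TSV with columns `protein_id`, `predictor`, `start`, `end`
#' (1-based inclusive residue positions) and normalizes it: intervals of
#' one predictor on one protein are sorted and merged when overlapping or
#' touching.
#'
#' @param path Path to the TSV file.
#' @param proteome Optional named character vector of sequences; when
#'   supplied, positions exceeding the protein length are an error.
#' @return Normalized data frame `protein_id`, `predictor`, `start`, `end`.
#' @export
load_disorder_table <- function(path, proteome = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  required <- c("protein_id", "predictor", "start", "end")
  if (!all(required %in% colnames(df))) {
    stop("disorder table must have columns: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  df <- df[, required]
  if (nrow(df) == 0L) {
    return(df)
  }
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  bad <- which(df$end < df$start | df$start < 1L)
  if (length(bad)) {
    stop("invalid interval at row ", bad[1L], ": start=", df$start[bad[1L]],
         ", end=", df$end[bad[1L]], call. = FALSE)
  }
  if (!is.null(proteome)) {
    absent <- setdiff(unique(df$protein_id), names(proteome))
    if (length(absent)) {
      stop("protein(s) absent from proteome: ", paste(head(absent, 3L), collapse = ", "),
           call. = FALSE)
    }
    too_long <- which(df$end > nchar(proteome[df$protein_id]))
    if (length(too_long)) {
      stop("interval exceeds sequence length at row ", too_long[1L],
           " (protein ", df$protein_id[too_long[1L]], ")", call. = FALSE)
    }
  }
  normalize_disorder(df)
}

#' Does a protein carry an IDR of minimum length?
#'
#' `TRUE` iff any single-predictor interval has length >= `min_len`
#' residues (default 20, the usual threshold for counting a protein as
#' IDR-containing; 30 is used for stricter analyses).
#'
#' @param intervals Normalized disorder data frame for one protein (any
#'   predictors).
#' @param min_len Minimum IDR length in residues.
#' @return Logical scalar.
#' @export
protein_has_idr <- function(intervals, min_len = 20L) {
  if (nrow(intervals) == 0L) {
    return(FALSE)
  }
  any(intervals$end - intervals$start + 1L >= min_len)
}

#' Consensus disordered regions across predictors
#'
#' Maximal runs of residues covered by at least `k` distinct predictors,
#' filtered to length >= `min_len`.  With `k = 1` this is the union of all
#' predictor intervals.
#'
#' @param disorder Normalized disorder data frame (any number of proteins).
#' @param k Minimum predictor support (default 3).
#' @param min_len Minimum region length in residues (default 20).
#' @return Data frame `protein_id`, `start`, `end`, `support` (the minimum
#'   number of predictors covering any residue of the region), sorted and
#'   non-overlapping within each protein.
#' @export
consensus_regions <- function(disorder, k = 3L, min_len = 20L) {
  if (k < 1L) {
    stop("k must be at least 1", call. = FALSE)
  }
  empty <- data.frame(protein_id = character(), start = integer(),
                      end = integer(), support = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(disorder) == 0L) {
    return(empty)
  }
  disorder <- normalize_disorder(disorder)
  res <- lapply(split(disorder, disorder$protein_id), function(d) {
    # per-predictor intervals are disjoint, so interval coverage counts
    # distinct predictors per residue
    cov <- IRanges::coverage(IRanges::IRanges(d$start, d$end))
    runs <- IRanges::slice(cov, lower = k, rangesOnly = TRUE)
    runs <- runs[IRanges::width(runs) >= min_len]
    if (length(runs) == 0L) {
      return(NULL)
    }
    support <- vapply(seq_along(runs), function(i) {
      min(S4Vectors::runValue(IRanges::Views(cov, runs[i])[[1L]]))
    }, numeric(1L))
    data.frame(
      protein_id = d$protein_id[1L],
      start = IRanges::start(runs),
      end = IRanges::end(runs),
      support = as.integer(support),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, res)
  if (is.null(res)) {
    return(empty)
  }
  rownames(res) <- NULL
  res
}

#' Percentage of disordered residues in a protein
#'
#' @param protein_length Protein length in residues (> 0).
#' @param intervals Normalized intervals of one predictor on that protein.
#' @return `100 * covered residues / protein_length`.
#' @export
disorder_fraction <- function(protein_length, intervals) {
  if (protein_length <= 0L) {
    stop("protein_length must be positive", call. = FALSE)
  }
  if (nrow(intervals) == 0L) {
    return(0)
  }
  rng <- IRanges::reduce(IRanges::IRanges(intervals$start, intervals$end))
  covered <- sum(IRanges::width(IRanges::restrict(rng, start = 1L, end = as.integer(protein_length))))
  100 * covered / protein_length
}
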