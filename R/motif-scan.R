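# ScanProsite-style scanning of polybasic K/R motifs.  Matching is greedy
# with no overlaps: the scan walks left to right; at each feasible start the
# longest x(3,7) spacer wins, and after accepting a hit scanning resumes
# immediately after the hit's end.

# The wildcard x matches the 20 canonical residues plus X.
X_CLASS <- "[ACDEFGHIKLMNPQRSTVWYX]"

#' The three polybasic K/R motif patterns
#'
#' PROSITE notation: `long` = `[KR]-x(3,7)-K-x-[KR]-[KR]`,
#' `mid` = `[KR]-x(3,7)-K-x-[KR]`, `short` = `[KR]-x(3,7)-K-x-K`.
#' Match lengths are 8-12 residues for `long` and 7-11 for `mid`/`short`.
#'
#' @return Named character vector of PROSITE pattern strings.
#' @export
kr_patterns <- function() {
  c(
    long = "[KR]-x(3,7)-K-x-[KR]-[KR]",
    mid = "[KR]-x(3,7)-K-x-[KR]",
    short = "[KR]-x(3,7)-K-x-K"
  )
}

#' Convert a PROSITE pattern to a regular expression
#'
#' Supports the PROSITE subset used for short linear motifs: single
#' residues, `x`, `[...]` (alternatives), `{...}` (exclusions), and the
#' repetition forms `(n)` and `(n,m)`; elements separated by `-`.
#'
#' @param pattern PROSITE pattern string, e.g. `"[KR]-x(3,7)-K-x-[KR]"`.
#' @return A regular expression string.
#' @export
prosite_to_regex <- function(pattern) {
  elements <- strsplit(pattern, "-", fixed = TRUE)[[1L]]
  out <- vapply(elements, function(el) {
    m <- regmatches(el, regexec("^(x|[A-Z]|\\[[A-Z]+\\]|\\{[A-Z]+\\})(\\((\\d+)(,(\\d+))?\\))?$", el))[[1L]]
    if (length(m) == 0L) {
      stop("unsupported PROSITE element: '", el, "'", call. = FALSE)
    }
    base <- m[2L]
    core <- switch(substr(base, 1L, 1L),
      "x" = X_CLASS,
      "[" = base,
      "{" = paste0("[^", substr(base, 2L, nchar(base) - 1L), "]"),
      base
    )
    if (nzchar(m[3L])) {
      rep <- if (nzchar(m[6L])) paste0("{", m[4L], ",", m[6L], "}") else paste0("{", m[4L], "}")
      core <- paste0(core, rep)
    }
    core
  }, character(1L), USE.NAMES = FALSE)
  paste0(out, collapse = "")
}

resolve_pattern <- function(pattern) {
  if (pattern %in% names(kr_patterns())) {
    pattern_id <- pattern
    pattern <- kr_patterns()[[pattern]]
  } else {
    pattern_id <- pattern
  }
  list(id = pattern_id, regex = prosite_to_regex(pattern))
}

#' Greedy non-overlapping motif scan of one sequence
#'
#' Scans left to right.  At each position the greedy match (longest
#' feasible spacer run) is taken; after accepting a hit, scanning resumes
#' at the position immediately after the hit's end, so hits of one pattern
#' never overlap.  Deterministic.
#'
#' @param sequence Uppercase amino-acid string (empty gives no hits).
#' @param pattern One of `"long"`, `"mid"`, `"short"`, or a PROSITE
#'   pattern string.
#' @param protein_id Optional id recorded in the output.
#' @return Data frame of hits: `protein_id`, `pattern_id`, `start`, `end`
#'   (1-based inclusive), `matched` (the matched subsequence), `in_idr`
#'   (`NA` until assigned), sorted by `start`.
#' @export
scan_sequence <- function(sequence, pattern, protein_id = NA_character_) {
  p <- resolve_pattern(pattern)
  empty <- data.frame(protein_id = character(), pattern_id = character(),
                      start = integer(), end = integer(), matched = character(),
                      in_idr = logical(), stringsAsFactors = FALSE)
  if (!nzchar(sequence)) {
    return(empty)
  }
  sequence <- toupper(sequence)
  starts <- integer()
  ends <- integer()
  pos <- 1L
  n <- nchar(sequence)
  while (pos <= n) {
    m <- regexpr(p$regex, substr(sequence, pos, n), perl = TRUE)
    if (m == -1L) break
    s <- pos + as.integer(m) - 1L
    e <- s + attr(m, "match.length") - 1L
    starts <- c(starts, s)
    ends <- c(ends, e)
    pos <- e + 1L
  }
  if (length(starts) == 0L) {
    return(empty)
  }
  data.frame(
    protein_id = protein_id,
    pattern_id = p$id,
    start = starts,
    end = ends,
    matched = substring(sequence, starts, ends),
    in_idr = NA,
    stringsAsFactors = FALSE
  )
}

#' Scan a whole proteome for K/R motifs
#'
#' @param proteome Named character vector of sequences.
#' @param patterns Pattern names or PROSITE strings (default all three K/R
#'   motifs); each pattern is scanned independently.
#' @return Row-bound hit data frame (see [scan_sequence()]).
#' @export
scan_proteome <- function(proteome, patterns = names(kr_patterns())) {
  res <- lapply(patterns, function(p) {
    hits <- lapply(names(proteome), function(id) {
      scan_sequence(proteome[[id]], p, protein_id = id)
    })
    do.call(rbind, hits)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Assign motif hits to consensus-supported IDRs
#'
#' A hit is counted as inside an IDR only if at least `k` distinct
#' predictors each report an interval of length >= `min_len` that fully
#' contains the hit's span ("at the site of" the motif).
#'
#' @param hits Hit data frame from [scan_sequence()]/[scan_proteome()].
#' @param disorder Normalized disorder data frame (see
#'   [load_disorder_table()]); a protein may have zero intervals.
#' @param k Minimum number of supporting predictors (default 3).
#' @param min_len Minimum qualifying interval length (default 20).
#' @param proteome Optional named character vector; when supplied, a hit on
#'   a protein absent from it is an error.
#' @return `hits` with the `in_idr` column set.
#' @export
assign_hits_to_idrs <- function(hits, disorder, k = 3L, min_len = 20L,
                                proteome = NULL) {
  if (!is.null(proteome)) {
    absent <- setdiff(unique(hits$protein_id), names(proteome))
    if (length(absent)) {
      stop("hit protein(s) absent from proteome: ",
           paste(head(absent, 3L), collapse = ", "), call. = FALSE)
    }
  }
  if (nrow(hits) == 0L) {
    return(hits)
  }
  disorder <- disorder[disorder$end - disorder$start + 1L >= min_len, , drop = FALSE]
  by_protein <- split(disorder, disorder$protein_id)
  hits$in_idr <- vapply(seq_len(nrow(hits)), function(i) {
    d <- by_protein[[hits$protein_id[i]]]
    if (is.null(d) || nrow(d) == 0L) {
      return(FALSE)
    }
    containing <- d$start <= hits$start[i] & d$end >= hits$end[i]
    length(unique(d$predictor[containing])) >= k
  }, logical(1L))
  hits
}

#' Per-dataset, per-pattern motif-in-IDR statistics
#'
#' @param hits Annotated hit data frame (after [assign_hits_to_idrs()]).
#' @param datasets Named list of protein-id vectors.
#' @return Data frame: `dataset`, `pattern_id`, `n_sites`, `n_in_idr`,
#'   `percent_in_idr` (`NA`, not 0, when a dataset has no sites).
#' @export
motif_site_stats <- function(hits, datasets) {
  stopifnot(is.list(datasets), !is.null(names(datasets)))
  patterns <- unique(hits$pattern_id)
  rows <- lapply(names(datasets), function(ds) {
    in_ds <- hits[hits$protein_id %in% datasets[[ds]], , drop = FALSE]
    do.call(rbind, lapply(patterns, function(p) {
      h <- in_ds[in_ds$pattern_id == p, , drop = FALSE]
      n <- nrow(h)
      n_in <- sum(h$in_idr)
      data.frame(
        dataset = ds, pattern_id = p, n_sites = n, n_in_idr = n_in,
        percent_in_idr = if (n == 0L) NA_real_ else 100 * n_in / n,
        stringsAsFactors = FALSE
      )
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
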