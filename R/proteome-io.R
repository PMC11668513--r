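# Sequence and ID-list I/O.  A proteome is represented as a named character
# vector (one uppercase amino-acid string per protein id), the lightest
# container that keeps downstream interval arithmetic simple; conversion to
# Biostrings::AAStringSet happens at the file boundary.

#' Read protein sequences from a FASTA file
#'
#' Reads a FASTA file into a named character vector of uppercase amino-acid
#' sequences.  The protein id is the header token before the first
#' whitespace.  Sequences may contain the 20 canonical residues plus `X`;
#' anything else is an error reporting the offending position.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector: `names()` are protein ids, values are
#'   uppercase sequences.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">P1 demo", "MKKR", ">P2", "ACDE"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  aas <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) stop("not a readable FASTA file: ", path, " (", conditionMessage(e), ")", call. = FALSE)
  )
  if (length(aas) == 0L) {
    stop("FASTA file contains no sequences: ", path, call. = FALSE)
  }
  ids <- sub("\\s.*$", "", names(aas))
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate protein id in FASTA: '", dup[1L], "'", call. = FALSE)
  }
  seqs <- toupper(as.character(aas))
  names(seqs) <- ids
  for (i in seq_along(seqs)) {
    if (!nzchar(seqs[[i]])) {
      stop("protein '", ids[i], "': empty sequence", call. = FALSE)
    }
    check_sequence(seqs[[i]], ids[i])
  }
  seqs
}

#' Write protein sequences to a FASTA file
#'
#' @param proteome Named character vector of sequences (as from
#'   [read_fasta()]).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(proteome, path) {
  stopifnot(is.character(proteome), !is.null(names(proteome)))
  aas <- Biostrings::AAStringSet(toupper(proteome))
  names(aas) <- names(proteome)
  Biostrings::writeXStringSet(aas, filepath = path)
  invisible(path)
}

#' Read a plain-text protein id list
#'
#' One accession per line; blank lines and `#` comments are skipped.  Such
#' lists stand in for external annotation queries (RNA-binding, phase
#' separation, PIP2-binding-domain membership).
#'
#' @param path Path to a text file.
#' @return Character vector of unique ids, in file order.
#' @export
read_id_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  unique(x)
}
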