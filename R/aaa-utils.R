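# Internal helpers shared across modules.

AA_CANONICAL <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)
AA_ALLOWED <- c(AA_CANONICAL, "X")

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream.  A NULL seed leaves the global stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Validate an amino-acid sequence (20 canonical letters plus X), reporting
# the first offending position.  `id` is used in error messages.
check_sequence <- function(seq, id = "<sequence>") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || !nzchar(seq)) {
    stop("protein '", id, "': sequence must be a non-empty string", call. = FALSE)
  }
  letters <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bad <- which(!letters %in% AA_ALLOWED)
  if (length(bad)) {
    stop(
      "protein '", id, "': illegal residue '", letters[bad[1L]],
      "' at position ", bad[1L],
      call. = FALSE
    )
  }
  invisible(seq)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
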