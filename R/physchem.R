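# Per-subsequence physicochemistry: isoelectric point via
# Henderson-Hasselbalch charge bisection, GRAVY hydropathy, charged-residue
# composition and the acidic/basic classification of IDRs.

#' EMBOSS pKa constants
#'
#' The default acid-dissociation constants for the terminal groups and the
#' ionizable side chains (D, E, C, Y acidic; H, K, R basic), as used by the
#' EMBOSS suite.  All values must lie in (0, 14).
#'
#' @return Named numeric vector with elements `Nterm`, `Cterm`, `C`, `D`,
#'   `E`, `H`, `K`, `R`, `Y`.
#' @export
emboss_pka <- function() {
  c(Nterm = 8.6, Cterm = 3.6, C = 8.5, D = 3.9, E = 4.1,
    H = 6.5, K = 10.8, R = 12.5, Y = 10.1)
}

# Kyte-Doolittle hydropathy index (Kyte & Doolittle 1982, J Mol Biol 157).
KD_HYDROPATHY <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
  L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

# Net Henderson-Hasselbalch charge of a residue-composition at a given pH.
# `counts` is a named integer vector of residue counts.
net_charge <- function(pH, counts, pka) {
  pos <- 1 / (1 + 10^(pH - pka["Nterm"]))
  for (aa in c("H", "K", "R")) {
    n <- counts[aa]
    if (!is.na(n) && n > 0) pos <- pos + n / (1 + 10^(pH - pka[aa]))
  }
  neg <- 1 / (1 + 10^(pka["Cterm"] - pH))
  for (aa in c("D", "E", "C", "Y")) {
    n <- counts[aa]
    if (!is.na(n) && n > 0) neg <- neg + n / (1 + 10^(pka[aa] - pH))
  }
  unname(pos - neg)
}

#' Isoelectric point of a sequence
#'
#' Finds the pH at which the net Henderson-Hasselbalch charge — positive
#' terms from the N-terminus, H, K and R; negative terms from the
#' C-terminus, D, E, C and Y — crosses zero, by bisection on `[0, 14]`.
#' Bisection is iterated well past `tol` so that the residual charge at the
#' returned pH is below 1e-3 even for long, highly charged sequences.
#'
#' @param sequence Non-empty amino-acid string (X is tolerated and ignored:
#'   it carries no ionizable group).
#' @param pka Named pKa set, see [emboss_pka()].
#' @param tol Required pH accuracy (default 1e-4).
#' @return The isoelectric point in pH units.
#' @export
isoelectric_point <- function(sequence, pka = emboss_pka(), tol = 1e-4) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence)) {
    stop("sequence must be a non-empty string", call. = FALSE)
  }
  stopifnot(all(pka > 0 & pka < 14))
  counts <- table(strsplit(toupper(sequence), "", fixed = TRUE)[[1L]])
  counts <- setNames(as.integer(counts), names(counts))
  lo <- 0
  hi <- 14
  # Q is strictly decreasing in pH; Q(0) > 0 > Q(14) always holds because
  # the termini ionize.  Iterate to an interval far below tol so |Q| < 1e-3.
  iters <- max(60L, ceiling(log2(14 / max(tol * 1e-3, 1e-12))))
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (net_charge(mid, counts, pka) > 0) lo <- mid else hi <- mid
    if (hi - lo < tol * 1e-3) break
  }
  (lo + hi) / 2
}

#' Grand average of hydropathy (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy of a sequence: the sum of per-residue
#' hydropathy values divided by the number of residues.  `X` and other
#' non-canonical letters are excluded from both the sum and the length.
#' Lower values indicate a more hydrophilic sequence.
#'
#' @param sequence Non-empty amino-acid string.
#' @return GRAVY value in `[-4.5, 4.5]`.
#' @export
gravy <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence)) {
    stop("sequence must be a non-empty string", call. = FALSE)
  }
  h <- KD_HYDROPATHY[strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]]
  h <- h[!is.na(h)]
  if (length(h) == 0L) {
    stop("sequence contains no canonical residues", call. = FALSE)
  }
  mean(h)
}

#' Counts of acidic (D/E) and basic (K/R) residues
#'
#' @param sequence Non-empty amino-acid string.
#' @return Named integer vector `c(n_DE = ..., n_KR = ...)`.
#' @export
charged_residue_counts <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence)) {
    stop("sequence must be a non-empty string", call. = FALSE)
  }
  letters <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  c(n_DE = sum(letters %in% c("D", "E")), n_KR = sum(letters %in% c("K", "R")))
}

#' Classify an IDR as acidic or basic by its isoelectric point
#'
#' The pI distribution of IDRs is bimodal: an acidic population (pI < 7,
#' D/E-enriched) and a basic one (pI > 7, K/R-enriched).  The boundary
#' value 7.0 is assigned to the basic class.
#'
#' @param pI Isoelectric point(s) in (0, 14).
#' @return Character vector, `"acidic"` or `"basic"`.
#' @export
classify_idr_charge <- function(pI) {
  stopifnot(all(pI > 0 & pI < 14))
  ifelse(pI < 7, "acidic", "basic")
}

#' Per-IDR physicochemical profile
#'
#' Extracts each region's subsequence and computes length, pI, GRAVY,
#' charged-residue counts and the acidic/basic class.
#'
#' @param proteome Named character vector of sequences.
#' @param regions Data frame with `protein_id`, `start`, `end` (e.g. from
#'   [consensus_regions()]).
#' @param pka pKa set for the pI computation.
#' @return Data frame: `protein_id`, `start`, `end`, `length`, `pI`,
#'   `gravy`, `n_DE`, `n_KR`, `charge_class`.
#' @export
idr_physchem <- function(proteome, regions, pka = emboss_pka()) {
  absent <- setdiff(unique(regions$protein_id), names(proteome))
  if (length(absent)) {
    stop("protein(s) absent from proteome: ", paste(head(absent, 3L), collapse = ", "),
         call. = FALSE)
  }
  if (nrow(regions) == 0L) {
    return(data.frame(protein_id = character(), start = integer(), end = integer(),
                      length = integer(), pI = numeric(), gravy = numeric(),
                      n_DE = integer(), n_KR = integer(), charge_class = character(),
                      stringsAsFactors = FALSE))
  }
  sub <- substring(proteome[regions$protein_id], regions$start, regions$end)
  pI <- vapply(sub, isoelectric_point, numeric(1L), pka = pka, USE.NAMES = FALSE)
  grv <- vapply(sub, function(s) tryCatch(gravy(s), error = function(e) NA_real_),
                numeric(1L), USE.NAMES = FALSE)
  cnt <- t(vapply(sub, charged_residue_counts, c(n_DE = 0L, n_KR = 0L)))
  data.frame(
    protein_id = regions$protein_id,
    start = regions$start,
    end = regions$end,
    length = regions$end - regions$start + 1L,
    pI = pI,
    gravy = grv,
    n_DE = cnt[, "n_DE"],
    n_KR = cnt[, "n_KR"],
    charge_class = classify_idr_charge(pI),
    stringsAsFactors = FALSE
  )
}
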