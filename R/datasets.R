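# Construction of the named protein datasets used throughout the
# characterization analyses.  Membership is driven by quantification
# evidence in subcellular fractions: a protein counts as quantifiable in a
# fraction when it carries at least `min_reps` valid (non-missing) values
# across that fraction's replicates.

#' Build fraction-based protein datasets
#'
#' Derives the rule-based dataset collection from nuclear and cytosolic
#' fraction quantification evidence:
#'
#' * `RDPA` — the supplied RDPA members, verbatim;
#' * `Nucleo-specific` — quantifiable in the nuclear fraction but not in the
#'   cytosolic fraction, with RDPA proteins added;
#' * `Nuclear-fraction` — quantifiable in the nuclear fraction, with RDPA
#'   proteins added;
#' * `Cytosol-specific` — quantifiable in the cytosolic fraction but not in
#'   the nuclear fraction;
#' * `Cytosolic-fraction` — quantifiable in the cytosolic fraction;
#' * `Total-cell` — quantifiable in either fraction, with RDPA proteins
#'   added.
#'
#' "Not in a fraction" defaults to the mirror of the quantifiability rule
#' (fewer than `min_reps` valid values); `strict_absence = TRUE` instead
#' requires zero observations in that fraction.
#'
#' @param nuclear,cytosolic [quant_matrix()] objects for the two fractions
#'   (their columns are replicates of one fraction each).
#' @param rdpa_members Character vector of RDPA protein ids (may be empty).
#' @param min_reps Minimum number of valid replicate values for a protein to
#'   count as quantifiable (default 2).
#' @param strict_absence If `TRUE`, "not in the other fraction" means zero
#'   observed values there rather than sub-threshold quantifiability.
#' @return Named list of character vectors (the datasets).
#' @export
build_fraction_datasets <- function(nuclear, cytosolic, rdpa_members = character(),
                                    min_reps = 2L, strict_absence = FALSE) {
  stopifnot(inherits(nuclear, "quant_matrix"), inherits(cytosolic, "quant_matrix"))
  if (min_reps > ncol(nuclear) || min_reps > ncol(cytosolic)) {
    stop("min_reps (", min_reps, ") exceeds the replicate count", call. = FALSE)
  }
  rdpa_members <- unique(as.character(rdpa_members))

  quantifiable <- function(qm) rownames(qm)[rowSums(!is.na(qm)) >= min_reps]
  observed <- function(qm) rownames(qm)[rowSums(!is.na(qm)) > 0L]

  nuc_q <- quantifiable(nuclear)
  cyt_q <- quantifiable(cytosolic)
  not_in_cyt <- if (strict_absence) {
    setdiff(rownames(nuclear), observed(cytosolic))
  } else {
    setdiff(union(rownames(nuclear), rownames(cytosolic)), cyt_q)
  }
  not_in_nuc <- if (strict_absence) {
    setdiff(rownames(cytosolic), observed(nuclear))
  } else {
    setdiff(union(rownames(nuclear), rownames(cytosolic)), nuc_q)
  }

  sets <- list(
    "RDPA" = rdpa_members,
    "Nucleo-specific" = union(intersect(nuc_q, not_in_cyt), rdpa_members),
    "Nuclear-fraction" = union(nuc_q, rdpa_members),
    "Cytosol-specific" = intersect(cyt_q, not_in_nuc),
    "Cytosolic-fraction" = cyt_q,
    "Total-cell" = Reduce(union, list(nuc_q, cyt_q, rdpa_members))
  )
  sets <- lapply(sets, function(x) sort(unique(x)))

  # Nesting invariants of the rule system; violated only by a coding error.
  stopifnot(
    all(sets[["Nucleo-specific"]] %in% sets[["Nuclear-fraction"]]),
    all(sets[["Nuclear-fraction"]] %in% sets[["Total-cell"]]),
    all(sets[["Cytosol-specific"]] %in% sets[["Cytosolic-fraction"]]),
    all(sets[["Cytosolic-fraction"]] %in% sets[["Total-cell"]]),
    all(sets[["RDPA"]] %in% sets[["Nucleo-specific"]])
  )
  sets
}
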