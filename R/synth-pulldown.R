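# Synthetic three-condition pull-down experiment (WT PH domain, R40A
# binding-deficient control, WT after RNase III digestion; three replicates
# each) with planted effects and intensity-dependent (MNAR) missingness.

#' Generate a synthetic pull-down LFQ experiment with planted truth
#'
#' Background proteins share a per-protein baseline log2 intensity across
#' all conditions.  PIP2-associated proteins are shifted up in WT relative
#' to R40A by `effect_pip2`.  Within the PIP2-associated set, the planted
#' dsRNA+ proteins are additionally shifted down by `effect_rnase` after
#' RNase III treatment and the planted dsRNA- proteins shifted up.
#' Missingness is missing-not-at-random: the probability a cell is missing
#' is logistic in its true intensity (lower abundance, more missing) —
#' the structure the downshifted-normal imputation presumes — plus an
#' optional uniform missing-completely-at-random rate.
#'
#' @param n_proteins Total protein groups (default 2000; fewer than 100
#'   background proteins warns: permutation FDR estimates become unstable).
#' @param n_pip2 Planted PIP2-associated proteins (default 195).
#' @param n_dsrna_plus,n_dsrna_minus Planted dsRNA+ / dsRNA- subsets of the
#'   PIP2-associated set (defaults 150 / 15, disjoint).
#' @param effect_pip2 Log2 enrichment of PIP2-associated proteins in WT over
#'   R40A (default 2).
#' @param effect_rnase Log2 shift after RNase III (default 2; applied
#'   negatively to dsRNA+ and positively to dsRNA-).
#' @param sigma Replicate noise SD in log2 units (default 0.3).
#' @param baseline_mean,baseline_sd Distribution of per-protein baseline
#'   log2 intensities (defaults 25 and 2).
#' @param n_reps Replicates per condition (default 3).
#' @param missingness Apply the MNAR model (default `TRUE`).
#' @param mnar_midpoint Intensity at which the MNAR missingness probability
#'   is 0.5 (default `baseline_mean - 7`).
#' @param mnar_scale Logistic scale of the MNAR model (default 1).
#' @param mcar_rate Additional uniform missingness rate (default 0).
#' @param seed RNG seed.
#' @return List: `wt_vs_r40a` and `wt_vs_rnase` ([quant_matrix()] objects
#'   sharing the WT samples), `matrices` (per-condition matrices) and
#'   `truth` (`pip2`, `dsrna_plus`, `dsrna_minus` id vectors).
#' @export
generate_pulldown_experiment <- function(n_proteins = 2000L, n_pip2 = 195L,
                                         n_dsrna_plus = 150L, n_dsrna_minus = 15L,
                                         effect_pip2 = 2, effect_rnase = 2,
                                         sigma = 0.3, baseline_mean = 25,
                                         baseline_sd = 2, n_reps = 3L,
                                         missingness = TRUE,
                                         mnar_midpoint = baseline_mean - 7,
                                         mnar_scale = 1, mcar_rate = 0,
                                         seed = 1L) {
  stopifnot(n_dsrna_plus + n_dsrna_minus <= n_pip2, n_pip2 <= n_proteins)
  if (n_proteins - n_pip2 < 100L) {
    warning("fewer than 100 background proteins; FDR estimates will be unstable",
            call. = FALSE)
  }
  with_seed(seed, {
    ids <- sprintf("PG%04d", seq_len(n_proteins))
    pip2 <- sample(ids, n_pip2)
    dsrna_plus <- pip2[seq_len(n_dsrna_plus)]
    dsrna_minus <- pip2[n_dsrna_plus + seq_len(n_dsrna_minus)]

    mu <- rnorm(n_proteins, baseline_mean, baseline_sd)
    names(mu) <- ids
    shift_pip2 <- effect_pip2 * (ids %in% pip2)
    shift_rnase <- -effect_rnase * (ids %in% dsrna_plus) +
      effect_rnase * (ids %in% dsrna_minus)

    draw <- function(means, label) {
      m <- matrix(rnorm(n_proteins * n_reps, mean = means, sd = sigma),
                  nrow = n_proteins,
                  dimnames = list(ids, paste0(label, "_", seq_len(n_reps))))
      if (missingness) {
        p_miss <- plogis((mnar_midpoint - m) / mnar_scale) + mcar_rate
        m[runif(length(m)) < p_miss] <- NA_real_
      }
      m
    }
    wt <- draw(mu + shift_pip2, "WT")
    r40a <- draw(mu, "R40A")
    rnase <- draw(mu + shift_pip2 + shift_rnase, "RNaseIII")

    list(
      wt_vs_r40a = quant_matrix(cbind(wt, r40a),
                                rep(c("WT", "R40A"), each = n_reps)),
      wt_vs_rnase = quant_matrix(cbind(wt, rnase),
                                 rep(c("WT", "RNaseIII"), each = n_reps)),
      matrices = list(WT = wt, R40A = r40a, WT_RNaseIII = rnase),
      truth = list(pip2 = sort(pip2), dsrna_plus = sort(dsrna_plus),
                   dsrna_minus = sort(dsrna_minus))
    )
  })
}
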