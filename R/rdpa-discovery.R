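# Two-step statistical identification of RDPA proteins from a
# three-condition pull-down experiment (WT PH domain, R40A mutant control,
# WT after RNase III digestion; three replicates each).
#
# Step 1 contrasts WT vs R40A with a one-sided S0-moderated t-test under
# permutation-based FDR control, yielding the PIP2-associated proteome.
# Step 2 restricts to those proteins and contrasts WT vs WT+RNaseIII
# two-sided: proteins significantly LOWER after RNase III are the dsRNA+
# set (association positively regulated by higher-order RNA), proteins
# significantly HIGHER are the dsRNA- set.

#' Filter a quant matrix on valid values
#'
#' Retains exactly the rows that have 100% valid (non-missing) values in at
#' least one sample group — the standard completeness filter applied before
#' imputation of label-free data.
#'
#' @param qm A [quant_matrix()] with at least two groups.
#' @return The filtered [quant_matrix()].  Warns (does not error) when no
#'   row survives.
#' @export
filter_valid_values <- function(qm) {
  stopifnot(inherits(qm, "quant_matrix"))
  idx <- group_index(qm)
  if (length(idx) < 2L) {
    stop("valid-value filtering needs at least two sample groups", call. = FALSE)
  }
  complete_in_some_group <- Reduce(`|`, lapply(idx, function(j) {
    rowSums(is.na(qm[, j, drop = FALSE])) == 0L
  }))
  if (!any(complete_in_some_group)) {
    warning("no row has a fully observed group; result is empty", call. = FALSE)
  }
  subset_quant(qm, rows = which(complete_in_some_group))
}

#' Impute missing values from a downshifted normal distribution
#'
#' Replaces each missing cell by a draw from
#' `Normal(m_c - shift * s_c, (width * s_c)^2)` where `m_c`, `s_c` are the
#' observed mean and standard deviation of the cell's column — the
#' conventional treatment of left-censored (low-abundance) missingness in
#' label-free proteomics.  Defaults `width = 0.3`, `shift = 1.8` (in units
#' of the observed SD).
#'
#' @param qm A log2-transformed [quant_matrix()]; every column must have at
#'   least 3 observed values.
#' @param width Spread of the imputation distribution, as a fraction of the
#'   observed column SD (> 0).
#' @param shift Downshift of the imputation mean, in observed column SDs
#'   (>= 0).
#' @param seed Optional RNG seed; identical seeds give identical output.
#' @param global If `TRUE`, use the mean/SD of all observed values in the
#'   matrix instead of per-column statistics.
#' @return A [quant_matrix()] with no missing values; observed cells are
#'   untouched.
#' @export
impute_downshifted <- function(qm, width = 0.3, shift = 1.8, seed = NULL,
                               global = FALSE) {
  stopifnot(inherits(qm, "quant_matrix"), width > 0, shift >= 0)
  n_obs <- colSums(!is.na(qm))
  if (any(n_obs < 3L)) {
    stop("column '", colnames(qm)[which(n_obs < 3L)[1L]],
         "' has fewer than 3 observed values; cannot estimate its distribution",
         call. = FALSE)
  }
  if (!anyNA(qm)) {
    return(qm)
  }
  out <- unclass(qm)
  g <- attr(out, "groups")
  attr(out, "groups") <- NULL
  with_seed(seed, {
    if (global) {
      m <- mean(out, na.rm = TRUE)
      s <- sd(as.vector(out), na.rm = TRUE)
    }
    for (j in seq_len(ncol(out))) {
      miss <- is.na(out[, j])
      if (!any(miss)) next
      if (!global) {
        m <- mean(out[, j], na.rm = TRUE)
        s <- sd(out[, j], na.rm = TRUE)
      }
      out[miss, j] <- rnorm(sum(miss), mean = m - shift * s, sd = width * s)
    }
  })
  quant_matrix(out, g)
}

#' S0-moderated two-sample t statistic
#'
#' The SAM-style moderated statistic
#' `d = (mean(x_a) - mean(x_b)) / (SE + s0)`, where `SE` is the pooled
#' equal-variance two-sample standard error.  The fudge factor `s0`
#' penalizes small fold-changes attained with small variance; with
#' `s0 = 0` the statistic reduces to the classical equal-variance t.
#'
#' @param x_a,x_b Numeric vectors, each with at least 2 values.
#' @param s0 Non-negative moderation constant (default 0.2).
#' @return The moderated statistic (dimensionless scalar).
#' @export
s0_statistic <- function(x_a, x_b, s0 = 0.2) {
  stopifnot(is.numeric(x_a), is.numeric(x_b), s0 >= 0)
  if (length(x_a) < 2L || length(x_b) < 2L) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  na <- length(x_a)
  nb <- length(x_b)
  sp2 <- ((na - 1) * var(x_a) + (nb - 1) * var(x_b)) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  (mean(x_a) - mean(x_b)) / (se + s0)
}

# Row-wise moderated statistics for a value matrix and two column index
# sets.  Returns list(d, diff).
row_s0_stats <- function(X, ia, ib, s0) {
  na <- length(ia)
  nb <- length(ib)
  ma <- rowMeans(X[, ia, drop = FALSE])
  mb <- rowMeans(X[, ib, drop = FALSE])
  ssa <- rowSums((X[, ia, drop = FALSE] - ma)^2)
  ssb <- rowSums((X[, ib, drop = FALSE] - mb)^2)
  sp2 <- (ssa + ssb) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  list(d = (ma - mb) / (se + s0), diff = ma - mb)
}

# All distinct assignments of `n` columns to a group-A of size `na`,
# excluding the observed partition: the observed assignment `obs` (sorted
# index vector within 1..n) and, for balanced designs, its complement
# (the same grouping with labels swapped, which would replicate the
# observed statistics exactly).  Returns a matrix with one assignment per
# column, or NULL when nothing remains.
label_permutations <- function(n, na, obs, n_perm, seed) {
  all_comb <- combn(n, na)
  is_obs <- colSums(all_comb == obs) == na
  if (n - na == na) {
    comp <- setdiff(seq_len(n), obs)
    is_obs <- is_obs | colSums(all_comb == comp) == na
  }
  all_comb <- all_comb[, !is_obs, drop = FALSE]
  if (ncol(all_comb) == 0L) {
    return(NULL)
  }
  if (ncol(all_comb) > n_perm) {
    keep <- with_seed(seed, sample.int(ncol(all_comb), n_perm))
    all_comb <- all_comb[, keep, drop = FALSE]
  }
  all_comb
}

#' Permutation-FDR moderated t-test over a two-group quant matrix
#'
#' Computes the S0-moderated statistic for every row, then estimates, for
#' each candidate threshold `t*` on the statistic (signed for one-sided
#' tests, absolute for two-sided), the false discovery rate as the mean
#' number of permuted statistics beyond `t*` across label permutations
#' divided by the number of observed statistics beyond `t*` (pi0 fixed at
#' 1, conservative).  Each row's q-value is the minimum estimated FDR over
#' the thresholds at which that row is called.  The observed labeling is
#' excluded from the permutation set; when `n_perm` exceeds the number of
#' distinct relabelings, all of them are enumerated exactly.
#'
#' @param qm A filtered, imputed (complete) [quant_matrix()] with exactly
#'   two groups.
#' @param groups Optional length-2 character vector fixing the contrast
#'   order: the statistic is `mean(groups[1]) - mean(groups[2])`, and a
#'   one-sided test calls `groups[1] > groups[2]`.  Defaults to
#'   first-appearance order.
#' @param s0 Moderation constant (default 0.2).
#' @param alternative `"two_sided"` or `"one_sided"`.
#' @param n_perm Maximum number of label permutations (default 250, >= 10).
#' @param alpha Significance level on the q-value (default 0.05).
#' @param seed RNG seed used when permutations must be sampled.
#' @return A data frame with one row per protein: `protein_id`,
#'   `mean_diff` (log2 units), `d_stat`, `q_value`, `significant`
#'   (`q_value < alpha`) and `direction` (`"up"`/`"down"` by the sign of
#'   `mean_diff`).
#' @export
permutation_fdr <- function(qm, groups = NULL, s0 = 0.2,
                            alternative = c("two_sided", "one_sided"),
                            n_perm = 250L, alpha = 0.05, seed = NULL) {
  stopifnot(inherits(qm, "quant_matrix"))
  alternative <- match.arg(alternative)
  if (n_perm < 10L) {
    stop("n_perm must be at least 10", call. = FALSE)
  }
  if (anyNA(qm)) {
    stop("matrix contains missing values; filter and impute first", call. = FALSE)
  }
  g <- attr(qm, "groups")
  lev <- groups %||% unique(g)
  if (length(lev) != 2L || !all(lev %in% g) || !all(g %in% lev)) {
    stop("permutation_fdr needs exactly two sample groups", call. = FALSE)
  }
  ia <- which(g == lev[1L])
  ib <- which(g == lev[2L])
  if (length(ia) < 2L || length(ib) < 2L) {
    stop("each group needs at least 2 replicates", call. = FALSE)
  }
  X <- unclass(qm)

  obs <- row_s0_stats(X, ia, ib, s0)
  score <- function(d) if (alternative == "one_sided") d else abs(d)
  s_obs <- score(obs$d)

  cols <- c(ia, ib)
  # positions are relative to `cols`; the observed assignment is 1..na
  perms <- label_permutations(length(cols), length(ia), seq_along(ia), n_perm, seed)
  if (is.null(perms)) {
    stop("no non-trivial label permutation exists", call. = FALSE)
  }
  s_perm <- unlist(lapply(seq_len(ncol(perms)), function(p) {
    pa <- cols[perms[, p]]
    pb <- setdiff(cols, pa)
    score(row_s0_stats(X, pa, pb, s0)$d)
  }), use.names = FALSE)
  n_used <- ncol(perms)

  # FDR at each observed threshold; q = min FDR over attainable thresholds.
  ord <- order(s_obs, decreasing = TRUE)
  thr <- s_obs[ord]
  n_obs_beyond <- vapply(thr, function(t) sum(s_obs >= t), integer(1L))
  sp_sorted <- sort(s_perm)
  n_perm_beyond <- length(sp_sorted) -
    findInterval(thr, sp_sorted, left.open = TRUE)
  fdr <- pmin(1, (n_perm_beyond / n_used) / pmax(1L, n_obs_beyond))
  q_sorted <- rev(cummin(rev(fdr)))
  q <- numeric(length(thr))
  q[ord] <- q_sorted
  # equal statistics must receive equal q-values
  for (t in unique(thr[duplicated(thr)])) {
    sel <- s_obs == t
    q[sel] <- min(q[sel])
  }

  data.frame(
    protein_id = rownames(X),
    mean_diff = obs$diff,
    d_stat = obs$d,
    q_value = q,
    significant = q < alpha,
    direction = ifelse(obs$diff >= 0, "up", "down"),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Two-step RDPA protein identification
#'
#' Step 1: one-sided moderated test (enrichment in WT over the
#' binding-deficient R40A control) at FDR < `alpha` identifies the
#' PIP2-associated proteome.  Step 2: the WT vs WT+RNaseIII matrix is
#' restricted to the step-1 significant proteins and tested two-sided;
#' proteins significantly lower after RNase III form the dsRNA+ set,
#' significantly higher the dsRNA- set.  Both matrices are valid-value
#' filtered and imputed internally.
#'
#' @param wt_vs_r40a [quant_matrix()] with groups `groups1` (WT first).
#' @param wt_vs_rnase [quant_matrix()] with groups `groups2` (WT first).
#' @param groups1,groups2 Length-2 group-order vectors; defaults take each
#'   matrix's first-appearance order with the enriched (WT) group first.
#' @param s0 Moderation constant (default 0.2).
#' @param alpha FDR threshold (default 0.05).
#' @param n_perm Permutations per test (default 250).
#' @param seed RNG seed (imputation and permutation sampling).
#' @param width,shift Imputation parameters, see [impute_downshifted()].
#' @return An object of class `rdpa_call`: list with `pip2_associated`,
#'   `dsrna_plus`, `dsrna_minus` (character vectors) and the per-step test
#'   tables `step1`, `step2`.
#' @export
call_rdpa <- function(wt_vs_r40a, wt_vs_rnase, groups1 = NULL, groups2 = NULL,
                      s0 = 0.2, alpha = 0.05, n_perm = 250L, seed = 1L,
                      width = 0.3, shift = 1.8) {
  f1 <- suppressWarnings(filter_valid_values(wt_vs_r40a))
  step1 <- NULL
  pip2 <- character()
  if (nrow(f1) > 0L) {
    i1 <- impute_downshifted(f1, width = width, shift = shift, seed = seed)
    step1 <- permutation_fdr(i1, groups = groups1, s0 = s0,
                             alternative = "one_sided", n_perm = n_perm,
                             alpha = alpha, seed = seed)
    pip2 <- step1$protein_id[step1$significant]
  }

  dsrna_plus <- character()
  dsrna_minus <- character()
  step2 <- NULL
  if (length(pip2) == 0L) {
    warning("step 1 found no PIP2-associated proteins; returning empty call",
            call. = FALSE)
  } else {
    rows2 <- intersect(pip2, rownames(wt_vs_rnase))
    if (length(rows2)) {
      f2 <- suppressWarnings(filter_valid_values(subset_quant(wt_vs_rnase, rows = rows2)))
      if (nrow(f2) > 0L) {
        i2 <- impute_downshifted(f2, width = width, shift = shift, seed = seed + 1L)
        step2 <- permutation_fdr(i2, groups = groups2, s0 = s0,
                                 alternative = "two_sided", n_perm = n_perm,
                                 alpha = alpha, seed = seed + 1L)
        dsrna_plus <- step2$protein_id[step2$significant & step2$direction == "up"]
        dsrna_minus <- step2$protein_id[step2$significant & step2$direction == "down"]
      }
    }
  }

  out <- list(
    pip2_associated = pip2,
    dsrna_plus = dsrna_plus,
    dsrna_minus = dsrna_minus,
    step1 = step1,
    step2 = step2
  )
  stopifnot(
    all(out$dsrna_plus %in% out$pip2_associated),
    all(out$dsrna_minus %in% out$pip2_associated),
    length(intersect(out$dsrna_plus, out$dsrna_minus)) == 0L
  )
  class(out) <- "rdpa_call"
  out
}

#' @export
print.rdpa_call <- function(x, ...) {
  cat("RDPA call:\n")
  cat("  PIP2-associated (step 1): ", length(x$pip2_associated), "\n", sep = "")
  cat("  dsRNA+ (lost after RNase III): ", length(x$dsrna_plus), "\n", sep = "")
  cat("  dsRNA- (gained after RNase III): ", length(x$dsrna_minus), "\n", sep = "")
  invisible(x)
}

#' Replicate quality-control report
#'
#' Per-sample median intensity and inter-sample Pearson correlations on
#' complete rows — the evidence used to flag an outlier replicate.
#' Flagging never removes a sample automatically; removal is a manual
#' choice.
#'
#' @param qm A [quant_matrix()].
#' @return List with `medians` (named numeric) and `correlation` (matrix).
#' @export
qc_replicates <- function(qm) {
  stopifnot(inherits(qm, "quant_matrix"))
  list(
    medians = apply(qm, 2L, median, na.rm = TRUE),
    correlation = suppressWarnings(cor(unclass(qm), use = "pairwise.complete.obs"))
  )
}
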