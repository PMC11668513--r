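# Filtering, imputation, moderated statistics and the two-step call.

qm_from <- function(values, groups) {
  m <- matrix(values, nrow = length(values) / length(groups), byrow = TRUE)
  dimnames(m) <- list(paste0("P", seq_len(nrow(m))), paste0("S", seq_len(ncol(m))))
  quant_matrix(m, groups)
}

test_that("valid-value filter keeps rows complete in at least one group", {
  m <- matrix(c(
    1, 2, 3, NA, NA, NA,   # complete in group A -> retained
    1, NA, 3, 4, NA, 6,    # 2/3 in both groups -> removed
    1, 2, 3, 4, 5, 6       # fully observed -> retained
  ), nrow = 3, byrow = TRUE,
  dimnames = list(c("A", "B", "C"), paste0("S", 1:6)))
  qm <- quant_matrix(m, rep(c("G1", "G2"), each = 3))
  kept <- filter_valid_values(qm)
  expect_identical(rownames(kept), c("A", "C"))

  all_gappy <- quant_matrix(m[2, , drop = FALSE], rep(c("G1", "G2"), each = 3))
  expect_warning(res <- filter_valid_values(all_gappy), "empty")
  expect_equal(nrow(res), 0L)
})

test_that("imputation draws from the downshifted column distribution", {
  # column with observed mean exactly 25 and SD exactly 2; half missing
  withr::local_seed(1)
  n <- 20000
  obs <- rnorm(n / 2)
  obs <- (obs - mean(obs)) / sd(obs) * 2 + 25
  vals <- c(obs, rep(NA_real_, n / 2))
  m <- cbind(vals, rep(25, n), rep(26, n))
  dimnames(m) <- list(paste0("P", 1:n), c("S1", "S2", "S3"))
  m[1:3, 2] <- c(24, 25, 26) # give constant columns some spread
  m[1:3, 3] <- c(25, 26, 27)
  qm <- quant_matrix(m, c("A", "A", "A"))

  imp <- impute_downshifted(qm, seed = 7)
  drawn <- imp[is.na(qm[, 1]), 1]
  expect_equal(mean(drawn), 25 - 1.8 * 2, tolerance = 0.05 / 21.4)
  expect_equal(sd(drawn), 0.3 * 2, tolerance = 0.05 / 0.6)
  # observed cells untouched
  expect_identical(imp[!is.na(qm[, 1]), 1], qm[!is.na(qm[, 1]), 1])
  # imputed empirical distribution passes a KS test against the target
  expect_gt(ks.test(drawn, "pnorm", 21.4, 0.6)$p.value, 0.01)
})

test_that("imputation is deterministic, identity without missingness, and guarded", {
  m <- matrix(rnorm(30, 25), nrow = 5,
              dimnames = list(paste0("P", 1:5), paste0("S", 1:6)))
  qm <- quant_matrix(m, rep(c("A", "B"), each = 3))
  expect_identical(impute_downshifted(qm, seed = 1), qm)

  m[2, 3] <- NA
  qm <- quant_matrix(m, rep(c("A", "B"), each = 3))
  expect_identical(impute_downshifted(qm, seed = 5), impute_downshifted(qm, seed = 5))
  expect_false(identical(impute_downshifted(qm, seed = 5), impute_downshifted(qm, seed = 6)))

  m[, 4] <- NA
  m[1:2, 4] <- c(25, 26)
  qm <- quant_matrix(m, rep(c("A", "B"), each = 3))
  expect_error(impute_downshifted(qm), "S4")
})

test_that("s0 statistic matches its closed forms and the classical t", {
  expect_equal(s0_statistic(c(1, 2, 3), c(1, 2, 3), s0 = 0.2), 0)
  # zero variance: d = diff / s0
  expect_equal(s0_statistic(c(2, 2, 2), c(1, 1, 1), s0 = 0.2), 5)
  expect_error(s0_statistic(1, c(1, 2)), "at least 2")

  withr::local_seed(3)
  for (i in 1:20) {
    a <- rnorm(4 + i %% 3)
    b <- rnorm(5)
    d <- s0_statistic(a, b, s0 = 0)
    tt <- t.test(a, b, var.equal = TRUE)$statistic
    expect_equal(d, unname(tt), tolerance = 1e-12)
    # antisymmetry and monotone shrinkage
    expect_equal(s0_statistic(b, a, 0.2), -s0_statistic(a, b, 0.2))
    expect_lte(abs(s0_statistic(a, b, 0.5)), abs(s0_statistic(a, b, 0.2)))
  }
})

test_that("permutation test enumerates exactly and controls the null", {
  withr::local_seed(9)
  m <- matrix(rnorm(200 * 6, 25), nrow = 200,
              dimnames = list(sprintf("P%03d", 1:200), paste0("S", 1:6)))
  qm <- quant_matrix(m, rep(c("A", "B"), each = 3))
  res <- permutation_fdr(qm, n_perm = 1000, seed = 1)
  # n_perm beyond the 18 non-trivial assignments -> exact enumeration,
  # hence seed-independent results
  res2 <- permutation_fdr(qm, n_perm = 250, seed = 99)
  expect_identical(res$q_value, res2$q_value)
  expect_true(all(res$q_value >= 0 & res$q_value <= 1))
  expect_lte(sum(res$significant), 4) # ~2% of a null matrix

  expect_error(permutation_fdr(qm, n_perm = 5), "at least 10")
  qm_na <- qm
  qm_na[1, 1] <- NA
  expect_error(permutation_fdr(qm_na), "impute")
})

test_that("two-step call logic gates step 2 on step 1", {
  withr::local_seed(5)
  n <- 300
  ids <- sprintf("P%03d", 1:n)
  mu <- rnorm(n, 25, 0.5)
  base <- function(shift, label) {
    matrix(rnorm(n * 3, mu + shift, 0.2), nrow = n,
           dimnames = list(ids, paste0(label, 1:3)))
  }
  # first 30 proteins PIP2-associated; of those, 1..10 lost after RNase III
  shift1 <- c(rep(2, 30), rep(0, n - 30))
  shift2 <- c(rep(-2, 10), rep(0, n - 10))
  # P031 has a huge RNase response but no step-1 enrichment
  shift2[31] <- -4
  wt <- base(shift1, "WT")
  qm1 <- quant_matrix(cbind(wt, base(0, "R40A")), rep(c("WT", "R40A"), each = 3))
  qm2 <- quant_matrix(cbind(wt + 0.01 * matrix(rnorm(n * 3), ncol = 3),
                            wt + matrix(rep(shift2, 3), ncol = 3)),
                      rep(c("WT", "RNaseIII"), each = 3))
  colnames(qm2) <- c(paste0("WTb", 1:3), paste0("RN", 1:3))
  call <- call_rdpa(qm1, qm2, seed = 2)

  expect_setequal(call$pip2_associated, ids[1:30])
  # dsRNA sets obey the two-step gate
  expect_true(all(call$dsrna_plus %in% ids[1:10]))
  expect_false("P031" %in% c(call$dsrna_plus, call$dsrna_minus))
  # significant in step 1 with no step-2 change: in neither dsRNA set
  expect_true("P020" %in% call$pip2_associated)
  expect_false("P020" %in% c(call$dsrna_plus, call$dsrna_minus))
})

test_that("an empty step 1 yields an empty call with a warning", {
  withr::local_seed(8)
  m <- matrix(rnorm(100 * 6, 25, 0.3), nrow = 100,
              dimnames = list(sprintf("P%03d", 1:100), paste0("S", 1:6)))
  qm1 <- quant_matrix(m, rep(c("WT", "R40A"), each = 3))
  qm2 <- quant_matrix(m, rep(c("WT", "RNaseIII"), each = 3))
  expect_warning(call <- call_rdpa(qm1, qm2, seed = 1), "no PIP2-associated")
  expect_length(call$pip2_associated, 0)
  expect_length(call$dsrna_plus, 0)
})

test_that("replicate QC reports medians and correlations", {
  withr::local_seed(2)
  m <- matrix(rnorm(50 * 4, 25), nrow = 50,
              dimnames = list(sprintf("P%02d", 1:50), paste0("S", 1:4)))
  m[, 4] <- m[, 4] - 5 # outlier-like low-intensity replicate
  qc <- qc_replicates(quant_matrix(m, c("A", "A", "B", "B")))
  expect_equal(which.min(qc$medians), c(S4 = 4L))
  expect_equal(dim(qc$correlation), c(4L, 4L))
})
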