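# Generators: determinism, planted-truth verification, downstream recovery.

test_that("generators are pure functions of configuration and seed", {
  a <- generate_proteome(n_proteins = 30, seed = 61,
                         n_motif_in = c(long = 5L), n_motif_out = c(long = 3L))
  b <- generate_proteome(n_proteins = 30, seed = 61,
                         n_motif_in = c(long = 5L), n_motif_out = c(long = 3L))
  expect_identical(a, b)
  c <- generate_proteome(n_proteins = 30, seed = 62,
                         n_motif_in = c(long = 5L), n_motif_out = c(long = 3L))
  expect_false(identical(a$proteome, c$proteome))

  e1 <- generate_pulldown_experiment(n_proteins = 200, n_pip2 = 20,
                                     n_dsrna_plus = 10, n_dsrna_minus = 2, seed = 63)
  e2 <- generate_pulldown_experiment(n_proteins = 200, n_pip2 = 20,
                                     n_dsrna_plus = 10, n_dsrna_minus = 2, seed = 63)
  expect_identical(e1, e2)

  s1 <- generate_image_stack(dims = c(48L, 48L, 16L), n_foci = 2, seed = 64)
  s2 <- generate_image_stack(dims = c(48L, 48L, 16L), n_foci = 2, seed = 64)
  expect_identical(s1, s2)
})

test_that("planted motifs are recovered by the scanner with correct IDR flags", {
  pt <- generate_proteome(n_proteins = 80, seed = 65,
                          n_motif_in = c(long = 25L), n_motif_out = c(long = 10L))
  hits <- scan_proteome(pt$proteome, "long")
  hits <- assign_hits_to_idrs(hits, pt$disorder, k = pt$params$n_predictors)
  truth <- pt$motif_truth
  expect_gte(nrow(hits), nrow(truth))
  # every planted span appears verbatim among the scanned hits
  key_hit <- paste(hits$protein_id, hits$start, hits$end)
  key_truth <- paste(truth$protein_id, truth$start, truth$end)
  expect_true(all(key_truth %in% key_hit))
  # planted in-IDR motifs are flagged even at full-panel support
  planted <- hits[key_hit %in% key_truth[truth$in_idr], ]
  expect_gte(nrow(planted), 25L)
  expect_true(all(planted$in_idr))
  # planted structured-region motifs never reach the support threshold
  planted_out <- hits[key_hit %in% key_truth[!truth$in_idr], ]
  expect_false(any(planted_out$in_idr))
})

test_that("truth tables round-trip through the I/O layer losslessly", {
  pt <- generate_proteome(n_proteins = 25, seed = 66,
                          n_motif_in = c(long = 4L, mid = 3L), n_motif_out = c(short = 3L))
  fa <- withr::local_tempfile(fileext = ".fa")
  write_fasta(pt$proteome, fa)
  expect_identical(read_fasta(fa), pt$proteome)

  dtab <- withr::local_tempfile(fileext = ".tsv")
  write.table(pt$disorder, dtab, sep = "\t", quote = FALSE, row.names = FALSE)
  reloaded <- load_disorder_table(dtab, proteome = pt$proteome)
  expect_equal(reloaded[order(reloaded$protein_id, reloaded$predictor, reloaded$start), ],
               pt$disorder[order(pt$disorder$protein_id, pt$disorder$predictor,
                                 pt$disorder$start), ],
               ignore_attr = TRUE)
})

test_that("infeasible generator configurations error out", {
  expect_error(generate_proteome(idr_length_range = c(10L, 15L)), "infeasible")
  expect_error(generate_proteome(n_proteins = 5L), "infeasible")
  expect_error(generate_image_stack(dims = c(16L, 16L, 8L), n_nuclei = 4),
               "cannot pack")
})

test_that("null pull-down produces no calls; effects restore recovery", {
  exp0 <- generate_pulldown_experiment(n_proteins = 400, n_pip2 = 40,
                                       n_dsrna_plus = 20, n_dsrna_minus = 5,
                                       effect_pip2 = 0, effect_rnase = 0,
                                       missingness = FALSE, seed = 67)
  call0 <- suppressWarnings(call_rdpa(exp0$wt_vs_r40a, exp0$wt_vs_rnase, seed = 67))
  expect_lte(length(call0$pip2_associated), 8) # ~2% of 400 under the null

  exp1 <- generate_pulldown_experiment(n_proteins = 400, n_pip2 = 40,
                                       n_dsrna_plus = 20, n_dsrna_minus = 5, seed = 68)
  call1 <- call_rdpa(exp1$wt_vs_r40a, exp1$wt_vs_rnase, seed = 68)
  expect_gte(length(intersect(call1$dsrna_plus, exp1$truth$dsrna_plus)) / 20, 0.9)
})

test_that("disabling missingness keeps every planted row through the filter", {
  exp <- generate_pulldown_experiment(n_proteins = 300, n_pip2 = 30,
                                      n_dsrna_plus = 15, n_dsrna_minus = 3,
                                      missingness = FALSE, seed = 69)
  expect_false(anyNA(exp$wt_vs_r40a))
  kept <- filter_valid_values(exp$wt_vs_r40a)
  expect_equal(nrow(kept), 300L)
})

test_that("MNAR missingness concentrates in low-abundance proteins", {
  exp <- generate_pulldown_experiment(n_proteins = 3000, baseline_mean = 20,
                                      mnar_midpoint = 18, seed = 70)
  m <- exp$wt_vs_r40a
  miss_rate <- rowMeans(is.na(m))
  mu <- rowMeans(m, na.rm = TRUE)
  lo <- miss_rate[!is.nan(mu) & mu < 19]
  hi <- miss_rate[!is.nan(mu) & mu > 22]
  expect_gt(mean(lo), mean(hi))
})
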