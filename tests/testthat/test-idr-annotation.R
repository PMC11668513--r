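# Disorder interval normalization, consensus regions, disorder fractions.

disorder_df <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(protein_id = r[[1]], predictor = r[[2]],
               start = as.integer(r[[3]]), end = as.integer(r[[4]]),
               stringsAsFactors = FALSE)
  }))
}

test_that("loading normalizes, merges and validates intervals", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(disorder_df(list("P1", "X-Ray", 5, 30), list("P1", "X-Ray", 25, 40)),
              f, sep = "\t", quote = FALSE, row.names = FALSE)
  d <- load_disorder_table(f)
  expect_equal(nrow(d), 1L)
  expect_equal(c(d$start, d$end), c(5L, 40L))

  bad <- withr::local_tempfile(fileext = ".tsv")
  write.table(disorder_df(list("P1", "NMR", 10, 9)), bad,
              sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_disorder_table(bad), "row 1")

  emp <- withr::local_tempfile(fileext = ".tsv")
  writeLines("protein_id\tpredictor\tstart\tend", emp)
  expect_equal(nrow(load_disorder_table(emp)), 0L)

  toolong <- withr::local_tempfile(fileext = ".tsv")
  write.table(disorder_df(list("P1", "NMR", 10, 99)), toolong,
              sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_disorder_table(toolong, proteome = c(P1 = strrep("A", 50))),
               "exceeds sequence length")
})

test_that("protein_has_idr applies the minimum-length boundary", {
  d20 <- disorder_df(list("P1", "A", 11, 30))
  expect_true(protein_has_idr(d20, min_len = 20))
  d19 <- disorder_df(list("P1", "A", 11, 29))
  expect_false(protein_has_idr(d19, min_len = 20))
  expect_false(protein_has_idr(d19[0, ], min_len = 20))
  expect_true(protein_has_idr(d20, min_len = 10))
})

test_that("consensus regions follow the k-of-predictors coverage rule", {
  three <- disorder_df(list("P1", "A", 10, 60), list("P1", "B", 10, 60),
                       list("P1", "C", 10, 60))
  cr <- consensus_regions(three, k = 3, min_len = 20)
  expect_equal(cr[, c("start", "end", "support")],
               data.frame(start = 10L, end = 60L, support = 3L))

  # staggered intervals: coverage >= 3 only on (30, 40), too short to keep
  stag <- disorder_df(list("P1", "A", 1, 40), list("P1", "B", 20, 80),
                      list("P1", "C", 30, 90))
  expect_equal(nrow(consensus_regions(stag, k = 3, min_len = 20)), 0L)
  eleven <- consensus_regions(stag, k = 3, min_len = 11)
  expect_equal(c(eleven$start, eleven$end), c(30L, 40L))

  # k = 1 equals the union of predictor intervals
  uni <- consensus_regions(stag, k = 1, min_len = 20)
  expect_equal(c(uni$start, uni$end), c(1L, 90L))

  expect_error(consensus_regions(three, k = 0), "at least 1")
})

test_that("consensus matches per-residue coverage counting on random configs", {
  withr::local_seed(11)
  for (i in 1:250) {
    cfg <- random_interval_config()
    k <- sample(1:4, 1)
    min_len <- sample(c(5L, 20L), 1)
    got <- consensus_regions(cfg, k = k, min_len = min_len)
    want <- oracle_consensus(cfg, k = k, min_len = min_len, protein_length = 200L)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
  }
})

test_that("consensus support is monotone in k and order-invariant", {
  withr::local_seed(12)
  for (i in 1:25) {
    cfg <- random_interval_config()
    if (nrow(cfg) == 0) next
    a <- consensus_regions(cfg, k = 2, min_len = 5)
    b <- consensus_regions(cfg, k = 3, min_len = 5)
    res_a <- unlist(mapply(seq, a$start, a$end, SIMPLIFY = FALSE))
    res_b <- unlist(mapply(seq, b$start, b$end, SIMPLIFY = FALSE))
    expect_true(all(res_b %in% res_a))
    shuffled <- cfg[sample(nrow(cfg)), , drop = FALSE]
    expect_equal(consensus_regions(shuffled, k = 2, min_len = 5), a)
  }
})

test_that("disorder fraction is exact arithmetic within [0, 100]", {
  expect_equal(disorder_fraction(100, disorder_df(list("P1", "A", 1, 100))), 100)
  expect_equal(disorder_fraction(200, disorder_df(list("P1", "A", 51, 100))), 25)
  expect_equal(disorder_fraction(50, disorder_df(list("P1", "A", 1, 10))[0, ]), 0)
  expect_error(disorder_fraction(0, disorder_df(list("P1", "A", 1, 10))), "positive")
})
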