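# Independent brute-force oracles used to cross-check the implementation.
# These deliberately re-derive each rule from its definition and share no
# code with the package internals.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Random sequence enriched for K/R so that motif candidates are frequent.
random_kr_sequence <- function(len, p_kr = 0.15) {
  p <- rep((1 - 2 * p_kr) / 18, 20)
  p[AA20 %in% c("K", "R")] <- p_kr
  paste(sample(AA20, len, replace = TRUE, prob = p), collapse = "")
}

# Greedy no-overlap motif scan by candidate enumeration: list every
# (start, spacer-length) candidate, sort by (start, -length), accept
# non-overlapping candidates in order.
oracle_scan <- function(sequence, pattern_id) {
  tails <- list(
    long = list("K", "x", c("K", "R"), c("K", "R")),
    mid = list("K", "x", c("K", "R")),
    short = list("K", "x", "K")
  )
  tail <- tails[[pattern_id]]
  letters <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(letters)
  cand <- list()
  for (s in seq_len(n)) {
    if (!letters[s] %in% c("K", "R")) next
    for (L in 3:7) {
      len <- 1L + L + length(tail)
      e <- s + len - 1L
      if (e > n) next
      pos <- s + 1L + L
      ok <- TRUE
      for (t in tail) {
        if (!identical(t, "x") && !letters[pos] %in% t) {
          ok <- FALSE
          break
        }
        pos <- pos + 1L
      }
      if (ok) cand[[length(cand) + 1L]] <- c(s, e)
    }
  }
  if (!length(cand)) {
    return(data.frame(start = integer(), end = integer()))
  }
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand[, 1L], -(cand[, 2L] - cand[, 1L])), , drop = FALSE]
  acc <- matrix(integer(), ncol = 2L)
  last_end <- 0L
  for (i in seq_len(nrow(cand))) {
    if (cand[i, 1L] > last_end) {
      acc <- rbind(acc, cand[i, ])
      last_end <- cand[i, 2L]
    }
  }
  data.frame(start = acc[, 1L], end = acc[, 2L])
}

# Net Henderson-Hasselbalch charge, written out independently.
charge_at_acceptance <- function(pH, seq, pka = rdpatools::emboss_pka()) {
  aa <- strsplit(seq, "")[[1]]
  pos <- 1 / (1 + 10^(pH - pka["Nterm"])) +
    sum(aa == "H") / (1 + 10^(pH - pka["H"])) +
    sum(aa == "K") / (1 + 10^(pH - pka["K"])) +
    sum(aa == "R") / (1 + 10^(pH - pka["R"]))
  neg <- 1 / (1 + 10^(pka["Cterm"] - pH)) +
    sum(aa == "D") / (1 + 10^(pka["D"] - pH)) +
    sum(aa == "E") / (1 + 10^(pka["E"] - pH)) +
    sum(aa == "C") / (1 + 10^(pka["C"] - pH)) +
    sum(aa == "Y") / (1 + 10^(pka["Y"] - pH))
  unname(pos - neg)
}

# Per-residue coverage counting for the consensus-IDR rule.
oracle_consensus <- function(intervals, k, min_len, protein_length) {
  cov <- integer(protein_length)
  for (p in unique(intervals$predictor)) {
    covered <- rep(FALSE, protein_length)
    sub <- intervals[intervals$predictor == p, , drop = FALSE]
    for (r in seq_len(nrow(sub))) {
      covered[sub$start[r]:sub$end[r]] <- TRUE
    }
    cov <- cov + covered
  }
  above <- cov >= k
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values & runs$lengths >= min_len
  data.frame(start = starts[keep], end = ends[keep])
}

# Exact hypergeometric upper tail by enumerating every draw (N <= 12).
oracle_hyper_upper <- function(k, K, n, N) {
  draws <- combn(N, n)
  feature <- seq_len(K)
  hits <- colSums(matrix(draws %in% feature, nrow = n))
  mean(hits >= k)
}

# Table-2-shaped PTM frequency table by nested loops over IDRs and sites.
oracle_ptm_table <- function(datasets, regions, hits, sites, pattern_id,
                             ptm_types) {
  out <- list()
  for (ds in names(datasets)) {
    qual <- list()
    for (i in seq_len(nrow(regions))) {
      if (!regions$protein_id[i] %in% datasets[[ds]]) next
      has_motif <- FALSE
      for (j in seq_len(nrow(hits))) {
        if (hits$pattern_id[j] == pattern_id &&
            hits$protein_id[j] == regions$protein_id[i] &&
            hits$start[j] >= regions$start[i] &&
            hits$end[j] <= regions$end[i]) {
          has_motif <- TRUE
          break
        }
      }
      if (has_motif) qual[[length(qual) + 1L]] <- regions[i, ]
    }
    n_idrs <- length(qual)
    pct <- setNames(rep(NA_real_, length(ptm_types)), ptm_types)
    if (n_idrs > 0L) {
      for (tp in ptm_types) {
        n_with <- 0L
        for (idr in qual) {
          found <- FALSE
          for (j in seq_len(nrow(sites))) {
            if (sites$ptm_type[j] == tp &&
                sites$protein_id[j] == idr$protein_id &&
                sites$position[j] >= idr$start &&
                sites$position[j] <= idr$end) {
              found <- TRUE
              break
            }
          }
          if (found) n_with <- n_with + 1L
        }
        pct[tp] <- 100 * n_with / n_idrs
      }
    }
    out[[ds]] <- c(n_idrs = n_idrs, pct)
  }
  out
}

# Random disorder-interval configuration for consensus oracle checks.
random_interval_config <- function(protein_length = 120L, n_predictors = 5L,
                                   max_per_pred = 3L) {
  rows <- list()
  for (p in seq_len(n_predictors)) {
    for (i in seq_len(sample.int(max_per_pred + 1L, 1L) - 1L)) {
      st <- sample.int(protein_length - 5L, 1L)
      en <- min(protein_length, st + sample.int(60L, 1L))
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = "P1", predictor = paste0("pred", p),
        start = st, end = en, stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(protein_id = character(), predictor = character(),
                      start = integer(), end = integer()))
  }
  do.call(rbind, rows)
}
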