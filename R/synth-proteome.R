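# Synthetic proteome generator with planted ground truth: IDRs of
# controlled charge composition, K/R motifs planted inside or outside truth
# IDRs, a multi-predictor disorder panel with boundary jitter and drop-out,
# and planted PTM sites.  Every output is a pure function of the
# configuration and the seed.

# Sample n residues with a given D/E and K/R mass; the remaining mass is
# spread uniformly over the other 16 canonical letters.
sample_composition <- function(n, de = 0.1, kr = 0.1) {
  others <- setdiff(AA_CANONICAL, c("D", "E", "K", "R"))
  p <- c(rep(de / 2, 2L), rep(kr / 2, 2L), rep((1 - de - kr) / length(others), length(others)))
  sample(c("D", "E", "K", "R", others), n, replace = TRUE, prob = p)
}

NON_KR <- setdiff(AA_CANONICAL, c("K", "R"))

# Build one concrete instance of a K/R pattern.  Spacer residues are drawn
# from the non-K/R alphabet so the greedy scanner recovers exactly the
# planted span (see plant_motif for the flanking clear zone).
motif_instance <- function(pattern_id) {
  spacer_len <- sample(3:7, 1L)
  head <- sample(c("K", "R"), 1L)
  spacer <- sample(NON_KR, spacer_len, replace = TRUE)
  tail <- switch(pattern_id,
    long = c("K", sample(NON_KR, 1L), sample(c("K", "R"), 1L), sample(c("K", "R"), 1L)),
    mid = c("K", sample(NON_KR, 1L), sample(c("K", "R"), 1L)),
    short = c("K", sample(NON_KR, 1L), "K"),
    stop("unknown pattern id: ", pattern_id, call. = FALSE)
  )
  c(head, spacer, tail)
}

# Longest possible match of each named pattern (clear-zone sizing).
MAX_MOTIF_LEN <- c(long = 12L, mid = 11L, short = 11L)

# Write a motif into `letters` at `start`, clearing K/R from a window
# before and after it so no overlapping alternative match can arise.
plant_motif <- function(letters, motif, start) {
  len <- length(motif)
  letters[start:(start + len - 1L)] <- motif
  pre <- max(1L, start - 12L):(start - 1L)
  post <- (start + len):min(length(letters), start + len + 1L)
  for (zone in list(pre, post)) {
    kr <- zone[letters[zone] %in% c("K", "R")]
    if (length(kr)) {
      letters[kr] <- sample(NON_KR, length(kr), replace = TRUE)
    }
  }
  letters
}

#' Generate a synthetic proteome with planted ground truth
#'
#' Produces protein sequences with: truth IDRs of acidic (D/E-rich) or
#' basic (K/R-rich) composition; K/R motifs planted inside truth IDRs or in
#' structured (non-IDR) regions; a panel of synthetic disorder predictors,
#' each perturbing truth IDR boundaries by up to `jitter` residues and
#' dropping intervals with probability `drop_prob` (motif-hosting IDRs are
#' exempt from drop-out so their in-IDR truth is deterministic); and
#' planted PTM sites inside motif-hosting IDRs.  Planted motifs are
#' verified against the greedy scanner before the proteome is returned.
#'
#' @param n_proteins Number of proteins (must accommodate all hosts).
#' @param seed RNG seed; identical seeds give identical output.
#' @param length_range Protein length range (residues).
#' @param idr_length_range Truth IDR length range (residues).
#' @param n_predictors Size of the synthetic disorder-predictor panel.
#' @param jitter Maximum per-boundary perturbation (residues).
#' @param drop_prob Per-interval predictor drop-out probability.
#' @param n_motif_in,n_motif_out Named integer vectors (names among
#'   `"long"`, `"mid"`, `"short"`): number of proteins hosting one planted
#'   motif of that pattern inside / outside a truth IDR.
#' @param acidic_composition,basic_composition Length-2 numeric vectors
#'   `c(DE = ..., KR = ...)`: residue mass given to D+E and K+R in the two
#'   IDR classes.
#' @param ptm_rates Named per-type probability that a motif-hosting IDR
#'   receives a planted site of that PTM type.
#' @param p_idr Probability that a non-host protein carries an IDR.
#' @return List with `proteome` (named character vector), `disorder`
#'   (predictor interval table), `idr_truth`, `motif_truth`, `ptm_truth`
#'   (data frames) and `params`.
#' @export
generate_proteome <- function(n_proteins = 120L, seed = 1L,
                              length_range = c(300L, 600L),
                              idr_length_range = c(40L, 120L),
                              n_predictors = 9L, jitter = 3L, drop_prob = 0.1,
                              n_motif_in = c(long = 15L, mid = 10L, short = 10L),
                              n_motif_out = c(long = 8L, mid = 6L, short = 6L),
                              acidic_composition = c(DE = 0.30, KR = 0.05),
                              basic_composition = c(DE = 0.05, KR = 0.30),
                              ptm_rates = c(acetylation = 0.45, methylation = 0.25,
                                            phosphorylation = 0.9, sumoylation = 0.1,
                                            ubiquitination = 0.45),
                              p_idr = 0.7) {
  host_margin <- jitter + 2L
  if (idr_length_range[1L] < max(MAX_MOTIF_LEN) + 2L * host_margin ||
      idr_length_range[1L] < 20L + 2L * jitter) {
    stop("infeasible config: IDRs too short to host a motif with jitter margin",
         call. = FALSE)
  }
  n_hosts <- sum(n_motif_in) + sum(n_motif_out)
  if (n_hosts > n_proteins) {
    stop("infeasible config: more planted motifs than proteins", call. = FALSE)
  }

  with_seed(seed, {
    roles <- c(
      rep(paste0("in_", names(n_motif_in)), n_motif_in),
      rep(paste0("out_", names(n_motif_out)), n_motif_out),
      rep("none", n_proteins - n_hosts)
    )
    roles <- sample(roles)
    ids <- sprintf("SP%04d", seq_len(n_proteins))
    predictors <- sprintf("pred%02d", seq_len(n_predictors))

    proteome <- character(n_proteins)
    idr_rows <- list()
    motif_rows <- list()
    ptm_rows <- list()
    pred_rows <- list()

    for (i in seq_len(n_proteins)) {
      L <- sample(length_range[1L]:length_range[2L], 1L)
      letters <- sample(AA_CANONICAL, L, replace = TRUE)
      role <- roles[i]
      hosting <- role != "none"
      pattern_id <- if (hosting) sub("^(in|out)_", "", role) else NA_character_
      motif_in_idr <- hosting && startsWith(role, "in_")

      # --- truth IDRs ---------------------------------------------------
      n_idr <- if (motif_in_idr) {
        1L + stats::rbinom(1L, 1L, p_idr)
      } else {
        stats::rbinom(1L, 2L, p_idr / 2)
      }
      idrs <- NULL
      if (n_idr > 0L) {
        # one slot per IDR keeps truth IDRs separated by > 2 * jitter
        margin <- 15L
        slot <- (L - 2L * margin) %/% n_idr
        starts <- integer()
        ends <- integer()
        classes <- character()
        for (s in seq_len(n_idr)) {
          slot_lo <- margin + (s - 1L) * slot
          len <- sample(idr_length_range[1L]:min(idr_length_range[2L], slot - 10L), 1L)
          st <- slot_lo + sample.int(slot - len - 9L, 1L)
          en <- st + len - 1L
          cls <- if (runif(1L) < 0.5) "acidic" else "basic"
          host_this <- motif_in_idr && s == 1L
          comp <- if (cls == "acidic") acidic_composition else basic_composition
          if (host_this) {
            # K/R kept out of the host composition so the planted motif is
            # the only polybasic signal in this IDR
            letters[st:en] <- sample_composition(len, de = comp["DE"], kr = 0)
          } else {
            letters[st:en] <- sample_composition(len, de = comp["DE"], kr = comp["KR"])
          }
          starts <- c(starts, st)
          ends <- c(ends, en)
          classes <- c(classes, cls)
        }
        idrs <- data.frame(protein_id = ids[i], start = starts, end = ends,
                           class = classes,
                           host = motif_in_idr & seq_len(n_idr) == 1L,
                           stringsAsFactors = FALSE)
      }

      # --- planted motif ------------------------------------------------
      if (hosting) {
        motif <- motif_instance(pattern_id)
        if (motif_in_idr) {
          st_idr <- idrs$start[1L]
          en_idr <- idrs$end[1L]
          m_start <- st_idr + host_margin +
            sample.int(en_idr - st_idr + 1L - 2L * host_margin - length(motif) + 1L, 1L) - 1L
        } else {
          # structured region, kept clear of every truth IDR by > jitter
          ok <- FALSE
          for (try in 1:200) {
            m_start <- sample.int(L - length(motif) - 14L, 1L) + 13L
            m_end <- m_start + length(motif) - 1L
            clash <- FALSE
            if (!is.null(idrs)) {
              clash <- any(m_start <= idrs$end + jitter + 1L &
                             m_end >= idrs$start - jitter - 1L)
            }
            if (!clash) {
              ok <- TRUE
              break
            }
          }
          if (!ok) {
            stop("infeasible config: no room for an out-of-IDR motif", call. = FALSE)
          }
        }
        letters <- plant_motif(letters, motif, m_start)
        motif_rows[[length(motif_rows) + 1L]] <- data.frame(
          protein_id = ids[i], pattern_id = pattern_id,
          start = m_start, end = m_start + length(motif) - 1L,
          in_idr = motif_in_idr, stringsAsFactors = FALSE
        )
      }

      # --- predictor panel ---------------------------------------------
      if (!is.null(idrs)) {
        for (r in seq_len(nrow(idrs))) {
          for (p in predictors) {
            if (!idrs$host[r] && runif(1L) < drop_prob) next
            st <- max(1L, idrs$start[r] + sample((-jitter):jitter, 1L))
            en <- min(L, idrs$end[r] + sample((-jitter):jitter, 1L))
            pred_rows[[length(pred_rows) + 1L]] <- data.frame(
              protein_id = ids[i], predictor = p, start = st, end = en,
              stringsAsFactors = FALSE
            )
          }
        }
        idr_rows[[length(idr_rows) + 1L]] <- idrs
      }

      # --- PTM sites in motif-hosting IDRs -----------------------------
      if (motif_in_idr) {
        for (ptm in names(ptm_rates)) {
          if (runif(1L) < ptm_rates[[ptm]]) {
            pos <- sample(idrs$start[1L]:idrs$end[1L], 1L)
            ptm_rows[[length(ptm_rows) + 1L]] <- data.frame(
              protein_id = ids[i], position = pos, ptm_type = ptm,
              stringsAsFactors = FALSE
            )
          }
        }
      }

      proteome[i] <- paste(letters, collapse = "")
    }
    names(proteome) <- ids

    bind <- function(rows, proto) {
      if (length(rows)) do.call(rbind, rows) else proto
    }
    motif_truth <- bind(motif_rows, data.frame(
      protein_id = character(), pattern_id = character(), start = integer(),
      end = integer(), in_idr = logical(), stringsAsFactors = FALSE
    ))
    disorder <- normalize_disorder(bind(pred_rows, data.frame(
      protein_id = character(), predictor = character(), start = integer(),
      end = integer(), stringsAsFactors = FALSE
    )))

    # planted motifs must be recovered exactly by the greedy scanner
    for (r in seq_len(nrow(motif_truth))) {
      hits <- scan_sequence(proteome[[motif_truth$protein_id[r]]],
                            motif_truth$pattern_id[r])
      if (!any(hits$start == motif_truth$start[r] & hits$end == motif_truth$end[r])) {
        stop("internal error: planted motif not recovered by the scanner (",
             motif_truth$protein_id[r], ")", call. = FALSE)
      }
    }

    list(
      proteome = proteome,
      disorder = disorder,
      idr_truth = bind(idr_rows, data.frame(
        protein_id = character(), start = integer(), end = integer(),
        class = character(), host = logical(), stringsAsFactors = FALSE
      )),
      motif_truth = motif_truth,
      ptm_truth = bind(ptm_rows, data.frame(
        protein_id = character(), position = integer(), ptm_type = character(),
        stringsAsFactors = FALSE
      )),
      params = list(n_proteins = n_proteins, seed = seed,
                    n_predictors = n_predictors, jitter = jitter,
                    drop_prob = drop_prob)
    )
  })
}
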