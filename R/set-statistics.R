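# Enrichment and group-comparison statistics: exact hypergeometric
# over-representation of annotations across datasets, pairwise Wilcoxon
# rank-sum comparisons with Benjamini-Hochberg correction, and
# boxplot-convention summaries of per-IDR metrics.

#' Exact hypergeometric tail probability
#'
#' For `X ~ Hypergeometric(N, K, n)` (a draw of `n` from a background of
#' `N` containing `K` feature members), returns the inclusive upper tail
#' `P(X >= k)` or lower tail `P(X <= k)` via [stats::phyper()].
#'
#' @param k Observed feature members in the draw.
#' @param K Feature members in the background.
#' @param n Draw (dataset) size.
#' @param N Background size.
#' @param tail `"upper"` (enrichment) or `"lower"` (depletion).
#' @return The exact tail probability.
#' @export
hypergeometric_enrichment <- function(k, K, n, N, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  if (k < 0 || K < 0 || n < 0 || N < 0 || k > n || k > K || n > N || K > N) {
    stop("inconsistent counts: need 0 <= k <= min(n, K) and n, K <= N", call. = FALSE)
  }
  if (tail == "upper") {
    phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  } else {
    phyper(k, K, N - K, n)
  }
}

#' Feature over-representation in a dataset against a background
#'
#' Counts the overlap between a dataset and a feature list within a
#' background and tests it with the exact hypergeometric tail.  Proteins
#' of the dataset missing from the background are reported with a warning
#' and dropped from the counts.
#'
#' @param dataset Character vector of protein ids.
#' @param feature_list Character vector of feature-positive protein ids.
#' @param background Character vector of background protein ids.
#' @param tail `"upper"` for enrichment claims, `"lower"` for depletion.
#' @return One-row data frame: `k`, `n`, `K`, `N`, `p_value`, `direction`
#'   (`"enriched"` when the dataset rate exceeds the background rate).
#' @export
annotate_membership <- function(dataset, feature_list, background,
                                tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  dataset <- unique(dataset)
  background <- unique(background)
  if (length(dataset) == 0L || length(background) == 0L) {
    stop("dataset and background must be non-empty", call. = FALSE)
  }
  outside <- setdiff(dataset, background)
  if (length(outside)) {
    warning(length(outside), " dataset member(s) outside the background were dropped",
            call. = FALSE)
    dataset <- intersect(dataset, background)
  }
  feature <- intersect(unique(feature_list), background)
  k <- length(intersect(dataset, feature))
  n <- length(dataset)
  K <- length(feature)
  N <- length(background)
  p <- hypergeometric_enrichment(k, K, n, N, tail = tail)
  data.frame(
    k = k, n = n, K = K, N = N, p_value = p,
    direction = if (n > 0 && k / n >= K / N) "enriched" else "depleted",
    stringsAsFactors = FALSE
  )
}

#' Pairwise Wilcoxon rank-sum tests with BH correction
#'
#' Two-sided rank-sum test for every unordered pair of datasets, with
#' Benjamini-Hochberg adjustment over the family of pairs.  Groups with
#' fewer than 3 values are skipped with a warning.
#'
#' @param values Numeric vector of per-IDR metric values.
#' @param groups Dataset label per value.
#' @return Lower-triangular matrix of BH-adjusted p-values (as returned by
#'   [stats::pairwise.wilcox.test()]).
#' @export
pairwise_wilcoxon_bh <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  groups <- as.character(groups)
  sizes <- table(groups)
  small <- names(sizes)[sizes < 3L]
  if (length(small)) {
    warning("skipping group(s) with fewer than 3 values: ",
            paste(small, collapse = ", "), call. = FALSE)
    keep <- !groups %in% small
    values <- values[keep]
    groups <- groups[keep]
  }
  if (length(unique(groups)) < 2L) {
    stop("need at least two groups with 3 or more values", call. = FALSE)
  }
  res <- suppressWarnings(
    pairwise.wilcox.test(values, factor(groups), p.adjust.method = "BH")
  )
  res$p.value
}

#' Boxplot-convention summary of metric values by dataset
#'
#' Median, 25th/75th percentiles (type-7 linear-interpolation quantiles),
#' whiskers at the most extreme values within 1.5 times the interquartile
#' range of the box, and the values beyond the whiskers as outliers.
#'
#' @param values Numeric vector.
#' @param groups Dataset label per value.
#' @return List with `summary` (data frame: `dataset`, `n`, `median`,
#'   `q25`, `q75`, `whisker_low`, `whisker_high`, `n_outliers`) and
#'   `outliers` (named list of outlying values per dataset).
#' @export
summarize_idr_metrics <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  by_group <- split(values, as.character(groups))
  rows <- lapply(names(by_group), function(g) {
    v <- by_group[[g]]
    q <- quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3L] - q[1L]
    lo_fence <- q[1L] - 1.5 * iqr
    hi_fence <- q[3L] + 1.5 * iqr
    inside <- v[v >= lo_fence & v <= hi_fence]
    out <- v[v < lo_fence | v > hi_fence]
    list(
      row = data.frame(
        dataset = g, n = length(v), median = q[2L], q25 = q[1L], q75 = q[3L],
        whisker_low = min(inside), whisker_high = max(inside),
        n_outliers = length(out), stringsAsFactors = FALSE
      ),
      outliers = out
    )
  })
  list(
    summary = do.call(rbind, lapply(rows, `[[`, "row")),
    outliers = setNames(lapply(rows, `[[`, "outliers"), names(by_group))
  )
}
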