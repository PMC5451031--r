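# Two-group statistical machinery: Kolmogorov-Smirnov normality gate,
# Welch t / Mann-Whitney U selection, Pearson chi-squared with Fisher
# fallback, Bonferroni family thresholds and hypergeometric term
# enrichment.

#' Bonferroni family threshold
#'
#' The per-test significance threshold alpha / m for a family of m tests;
#' a raw p-value at or below the threshold is called significant.
#'
#' @param m Family size (>= 1).
#' @param alpha Family-wise level (default 0.05).
#' @return The threshold alpha / m.
#' @examples
#' bonferroniThreshold(6)   # 0.008333...
#' bonferroniThreshold(16)  # 0.003125
#' @export
bonferroniThreshold <- function(m, alpha = 0.05) {
  if (!is.numeric(m) || length(m) != 1L || m < 1)
    stop("family size m must be a single number >= 1")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  alpha / m
}

#' Normality gate
#'
#' Decides whether a sample looks normal: a Kolmogorov-Smirnov test against
#' a normal with sample-estimated mean and SD, by default with the
#' Lilliefors correction for the estimated parameters
#' ([nortest::lillie.test()]); `method = "ks"` runs the plain K-S test.
#' Returns `TRUE` (treat as normal) when the test p-value exceeds 0.05.
#' Degenerate samples (zero SD) are not normal.
#'
#' @param x Numeric sample with at least 8 observations.
#' @param method `"lilliefors"` (default) or `"ks"`.
#' @param alpha Rejection level for the normality test (default 0.05).
#' @return Logical: `TRUE` if the sample passes the gate.
#' @export
normalityGate <- function(x, method = c("lilliefors", "ks"), alpha = 0.05) {
  method <- match.arg(method)
  x <- x[!is.na(x)]
  if (length(x) < 8L)
    stop("normality gate needs at least 8 observations, got ", length(x))
  if (sd(x) == 0) return(FALSE)
  p <- if (method == "lilliefors") {
    nortest::lillie.test(x)$p.value
  } else {
    suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x))$p.value)
  }
  p > alpha
}

## Mann-Whitney U for group a (rank-sum form), with midranks for ties
.uStatistic <- function(a, b) {
  r <- rank(c(a, b))
  sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
}

#' Two-tailed Mann-Whitney U test
#'
#' Exact when complete enumeration over all assignments of the pooled
#' values is feasible (at most `enumLimit` combinations; ties handled by
#' midranks); otherwise the normal approximation with tie correction and
#' no continuity correction.
#'
#' @param a,b Numeric samples.
#' @param enumLimit Largest number of combinations enumerated exactly.
#' @return List with `U` (statistic for sample `a`), `p` (two-tailed) and
#'   `method` (`"exact"` or `"normal-approximation"`).
#' @examples
#' mannWhitneyU(c(1, 2, 3), c(4, 5, 6))$p  # 0.1
#' @export
mannWhitneyU <- function(a, b, enumLimit = 1e5) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  na <- length(a); nb <- length(b); n <- na + nb
  u <- .uStatistic(a, b)
  if (choose(n, na) <= enumLimit) {
    pool <- c(a, b)
    r <- rank(pool)
    offset <- na * (na + 1) / 2
    idx <- combn(n, na)
    uAll <- colSums(matrix(r[idx], nrow = na)) - offset
    lo <- pmin(uAll, na * nb - uAll)
    p <- mean(lo <= min(u, na * nb - u) + 1e-9)
    list(U = u, p = min(1, p), method = "exact")
  } else {
    wt <- suppressWarnings(
      wilcox.test(a, b, exact = FALSE, correct = FALSE))
    list(U = u, p = wt$p.value, method = "normal-approximation")
  }
}

#' Compare a numeric feature between two groups
#'
#' Both samples pass through the normality gate; if both look normal a
#' Welch two-sample t-test (unequal variances) is used, otherwise the
#' two-tailed Mann-Whitney U test. Group medians are reported either way.
#'
#' @param a,b Numeric samples (group a = essential, group b = viable in
#'   pipeline use).
#' @param feature Feature name for the report row.
#' @param m Bonferroni family size.
#' @param alpha Family-wise level.
#' @param gate Normality-gate method passed to [normalityGate()]; samples
#'   with fewer than 8 observations skip the gate and use the U test.
#' @return One-row data frame: `feature`, `median_a`, `median_b`, `test`,
#'   `statistic`, `p`, `threshold`, `significant`.
#' @export
compareNumeric <- function(a, b, feature = "feature", m = 1L, alpha = 0.05,
                           gate = "lilliefors") {
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  normal <- length(a) >= 8L && length(b) >= 8L &&
    normalityGate(a, method = gate) && normalityGate(b, method = gate)
  thr <- bonferroniThreshold(m, alpha)
  if (normal) {
    tt <- t.test(a, b, var.equal = FALSE)
    stat <- unname(tt$statistic); p <- tt$p.value; test <- "welch_t"
  } else {
    mw <- mannWhitneyU(a, b)
    stat <- mw$U; p <- mw$p; test <- "mann_whitney_u"
  }
  data.frame(feature = feature, median_a = median(a), median_b = median(b),
             test = test, statistic = stat, p = p, threshold = thr,
             significant = p <= thr, stringsAsFactors = FALSE)
}

#' Compare a binary feature frequency between two groups
#'
#' Pearson chi-squared on the 2 x 2 success/failure table without
#' continuity correction; when any expected cell is 5 or smaller the test
#' falls back to Fisher's exact test (flagged in the `test` column).
#'
#' @param k_a,n_a Successes and total in group a.
#' @param k_b,n_b Successes and total in group b.
#' @param feature Feature name for the report row.
#' @param m Bonferroni family size.
#' @param alpha Family-wise level.
#' @return One-row data frame: `feature`, `k_a`, `n_a`, `k_b`, `n_b`,
#'   `pct_a`, `pct_b` (percentages, 1 decimal), `test`, `statistic`, `p`,
#'   `threshold`, `significant`.
#' @examples
#' compareCategorical(213, 1301, 1004, 3451)  # 16.4% vs 29.1%
#' @export
compareCategorical <- function(k_a, n_a, k_b, n_b, feature = "feature",
                               m = 1L, alpha = 0.05) {
  for (v in list(k_a, n_a, k_b, n_b))
    if (!is.numeric(v) || length(v) != 1L || v < 0)
      stop("counts must be single non-negative numbers")
  if (k_a > n_a || k_b > n_b) stop("successes cannot exceed totals")
  if (n_a == 0 || n_b == 0) stop("totals must be positive")
  tab <- matrix(c(k_a, n_a - k_a, k_b, n_b - k_b), nrow = 2, byrow = TRUE)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  thr <- bonferroniThreshold(m, alpha)
  if (any(expected <= 5)) {
    ft <- fisher.test(tab)
    stat <- NA_real_; p <- ft$p.value; test <- "fisher_exact"
  } else {
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    stat <- unname(ct$statistic); p <- ct$p.value; test <- "chi_squared"
  }
  data.frame(feature = feature, k_a = k_a, n_a = n_a, k_b = k_b, n_b = n_b,
             pct_a = round(100 * k_a / n_a, 1),
             pct_b = round(100 * k_b / n_b, 1),
             test = test, statistic = stat, p = p, threshold = thr,
             significant = p <= thr, stringsAsFactors = FALSE)
}

#' Annotation-term over-representation
#'
#' One-tailed Fisher (hypergeometric upper tail) per term for
#' over-representation of the query set against the background, with
#' DAVID-style Bonferroni inflation (corrected p = min(1, m x p) over the m
#' terms tested). Results are sorted by corrected then raw p.
#'
#' @param query Character vector of query gene ids (subset of background).
#' @param background Character vector of background gene ids.
#' @param annotations Data frame with columns `term` and `gene`.
#' @return Data frame: `term`, `query_hits`, `query_size`,
#'   `background_hits`, `background_size`, `fold_enrichment`, `p`,
#'   `p_bonferroni`.
#' @export
termEnrichment <- function(query, background, annotations) {
  query <- unique(query); background <- unique(background)
  if (!all(query %in% background))
    stop("query must be a subset of the background")
  stopifnot(all(c("term", "gene") %in% names(annotations)))
  ann <- annotations[annotations$gene %in% background, , drop = FALSE]
  terms <- unique(ann$term)
  mterms <- length(terms)
  N <- length(background); nq <- length(query)
  rows <- lapply(terms, function(tm) {
    tg <- unique(ann$gene[ann$term == tm])
    K <- length(tg)
    k <- length(intersect(tg, query))
    p <- phyper(k - 1, K, N - K, nq, lower.tail = FALSE)
    data.frame(term = tm, query_hits = k, query_size = nq,
               background_hits = K, background_size = N,
               fold_enrichment = if (K > 0 && nq > 0) (k / nq) / (K / N)
                                 else NA_real_,
               p = p, p_bonferroni = min(1, mterms * p),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$p_bonferroni, out$p), , drop = FALSE]
}
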