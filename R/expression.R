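# Stage-wise EST counts -> TPM, expressed-at-stage frequencies and binned
# expression distributions.

#' Construct a stage-wise EST count table
#'
#' @param counts Non-negative integer matrix, genes x 13 stages. Column
#'   names must be exactly the canonical stages of [developmentalStages()]
#'   in order; unnamed columns are assumed to be in that order.
#' @return A [StageExpression].
#' @export
stageExpression <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts)) && ncol(counts) == 13L)
    colnames(counts) <- DEVELOPMENTAL_STAGES
  obj <- new("StageExpression", counts = counts)
  obj
}

#' EST counts to transcripts per million
#'
#' TPM of gene i at stage j is its EST count divided by the stage's total
#' EST count, times 10^6. A stage with zero total ESTs yields an all-zero
#' column; every other column sums to exactly 10^6 over the genes in the
#' table (the denominator is the total over the supplied genes).
#'
#' @param x A [StageExpression] or a genes x 13 count matrix.
#' @return Numeric matrix of TPM values, same dimensions.
#' @examples
#' m <- matrix(0L, 2, 13, dimnames = list(c("g1", "g2"),
#'             developmentalStages()))
#' m[1, 1] <- 5L; m[2, 1] <- 995L
#' tpmNormalize(m)[1, 1]  # 5000
#' @export
tpmNormalize <- function(x) {
  cts <- if (is(x, "StageExpression")) x@counts else as.matrix(x)
  if (any(cts < 0)) stop("EST counts must be non-negative")
  totals <- colSums(cts)
  tpm <- sweep(cts, 2L, ifelse(totals > 0, totals, 1), "/") * 1e6
  tpm[, totals == 0] <- 0
  tpm
}

#' Per-stage expressed-gene frequencies by group
#'
#' A gene counts as expressed at a stage when its TPM (equivalently its EST
#' count) is greater than zero. Returns the percentage of expressed genes
#' per group at each stage together with a per-stage chi-squared comparison
#' under a Bonferroni family of the 13 stages.
#'
#' @param tpm TPM (or count) matrix, genes x 13 stages, rows named by gene.
#' @param labels Named character vector (`essential`/`viable`) covering all
#'   genes in `tpm`.
#' @param denominators Optional named list with `essential`/`viable` totals
#'   to use as comparison denominators; defaults to the labelled group sizes
#'   present in the matrix.
#' @param m Bonferroni family size (default 13, one test per stage).
#' @param alpha Family-wise significance level.
#' @return Data frame: `stage`, `pct_essential`, `pct_viable`, `test`,
#'   `statistic`, `p`, `threshold`, `significant`.
#' @export
stageExpressionFrequencies <- function(tpm, labels, denominators = NULL,
                                       m = 13L, alpha = 0.05) {
  if (is(tpm, "StageExpression")) tpm <- tpm@counts
  genes <- rownames(tpm)
  if (is.null(genes) || !all(genes %in% names(labels)))
    stop("every gene in the matrix must be labelled")
  lab <- labels[genes]
  nE <- denominators$essential %||% sum(lab == "essential")
  nV <- denominators$viable %||% sum(lab == "viable")
  out <- vector("list", ncol(tpm))
  for (j in seq_len(ncol(tpm))) {
    kE <- sum(tpm[lab == "essential", j] > 0)
    kV <- sum(tpm[lab == "viable", j] > 0)
    cmp <- compareCategorical(kE, nE, kV, nV,
                              feature = colnames(tpm)[j], m = m,
                              alpha = alpha)
    out[[j]] <- data.frame(stage = colnames(tpm)[j],
                           pct_essential = cmp$pct_a,
                           pct_viable = cmp$pct_b,
                           test = cmp$test, statistic = cmp$statistic,
                           p = cmp$p, threshold = cmp$threshold,
                           significant = cmp$significant,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Binned TPM distribution per group
#'
#' Histograms all (gene, stage) TPM cells into half-open bins
#' \[k b, (k+1) b) of width `binSize`, per label group. Bin counts conserve
#' the number of cells.
#'
#' @param tpm TPM matrix, rows named by gene.
#' @param labels Named label vector covering the genes.
#' @param binSize Positive bin width (default 50 TPM).
#' @return Data frame: `group`, `bin_start`, `count` (bins with zero counts
#'   in both groups are omitted).
#' @export
tpmHistogram <- function(tpm, labels, binSize = 50) {
  if (!is.numeric(binSize) || length(binSize) != 1L || binSize <= 0)
    stop("binSize must be a single positive number")
  if (is(tpm, "StageExpression")) tpm <- tpm@counts
  if (nrow(tpm) == 0L)
    return(data.frame(group = character(0), bin_start = numeric(0),
                      count = integer(0)))
  genes <- rownames(tpm)
  if (is.null(genes) || !all(genes %in% names(labels)))
    stop("every gene in the matrix must be labelled")
  lab <- labels[genes]
  out <- lapply(c("essential", "viable"), function(g) {
    vals <- as.numeric(tpm[lab == g, , drop = FALSE])
    if (!length(vals))
      return(data.frame(group = character(0), bin_start = numeric(0),
                        count = integer(0)))
    bins <- floor(vals / binSize)
    tab <- table(bins)
    data.frame(group = g,
               bin_start = as.numeric(names(tab)) * binSize,
               count = as.integer(tab), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
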