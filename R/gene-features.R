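# Gene-level sequence features: length, GC, transcript/exon counts and
# exon/intron lengths, all taken from the longest transcript.

#' Gene-level feature extraction
#'
#' Computes the six genomic features per gene: gene length (bp), GC content
#' (%), number of transcripts, number of exons, total exon length and intron
#' length. For genes with multiple transcripts, the exon count and total exon
#' length come from the transcript with the greatest total exon length;
#' intron length is gene length minus that exon total.
#'
#' @param genes A gene-model data frame as in [cohortGenes()]: columns
#'   `gene_id`, `gene_length`, `gc` (fraction) and a `transcripts`
#'   list-column whose elements are lists of per-transcript exon-length
#'   vectors.
#' @return A data frame with one row per gene and columns `gene_id`,
#'   `gene_length`, `gc_percent`, `n_transcripts`, `n_exons`, `exon_length`,
#'   `intron_length`.
#' @examples
#' g <- data.frame(gene_id = "g1", gene_length = 1000, gc = 0.5)
#' g$transcripts <- list(list(c(100, 200)))
#' geneFeatures(g)
#' @export
geneFeatures <- function(genes) {
  stopifnot(is.data.frame(genes),
            all(c("gene_id", "gene_length", "gc", "transcripts") %in%
                  names(genes)))
  n <- nrow(genes)
  n_exons <- integer(n); exon_length <- numeric(n); n_tx <- integer(n)
  for (i in seq_len(n)) {
    tx <- genes$transcripts[[i]]
    if (length(tx) < 1L)
      stop("gene ", genes$gene_id[i], " has no transcript")
    totals <- vapply(tx, sum, numeric(1))
    if (any(vapply(tx, function(e) any(e <= 0), logical(1))))
      stop("gene ", genes$gene_id[i], " has a non-positive exon length")
    best <- which.max(totals)
    n_tx[i] <- length(tx)
    n_exons[i] <- length(tx[[best]])
    exon_length[i] <- totals[best]
    if (exon_length[i] > genes$gene_length[i])
      stop("gene ", genes$gene_id[i],
           ": total exon length exceeds gene length (",
           exon_length[i], " > ", genes$gene_length[i], ")")
  }
  data.frame(
    gene_id = genes$gene_id,
    gene_length = genes$gene_length,
    gc_percent = round(100 * genes$gc, 2),
    n_transcripts = n_tx,
    n_exons = n_exons,
    exon_length = exon_length,
    intron_length = genes$gene_length - exon_length,
    stringsAsFactors = FALSE)
}
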