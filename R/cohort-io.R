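# Cohort serialisation: FASTA proteins, annotated Newick trees, tab-separated
# gene-model / expression / annotation tables, a label file and a PPI edge
# list. write/read round-trip losslessly.

.newickWithComments <- function(gt) {
  tr <- gt@tree
  ntip <- length(tr$tip.label)
  kids <- split(tr$edge[, 2L], tr$edge[, 1L])
  rec <- function(node) {
    if (node <= ntip) return(tr$tip.label[node])
    j <- node - ntip
    sprintf("(%s)[&age=%s,event=%s]",
            paste(vapply(kids[[as.character(node)]], rec, character(1)),
                  collapse = ","),
            format(gt@ages[j], trim = TRUE, scientific = FALSE),
            gt@events[j])
  }
  paste0(rec(ntip + 1L), ";")
}

.COMMENT_RE <- "\\[&age=([0-9.]+(?:[eE][+-]?[0-9]+)?),event=(duplication|speciation)\\]"

.parseGeneTree <- function(nwk) {
  cleaned <- gsub(.COMMENT_RE, "\\1_\\2", nwk)
  tr <- ape::read.tree(text = cleaned)
  if (is.null(tr)) stop("unparseable Newick string: ", substr(nwk, 1, 60))
  lab <- tr$node.label
  ok <- !is.null(lab) && length(lab) == tr$Nnode &&
    all(grepl("^[0-9.]+(?:[eE][+-]?[0-9]+)?_(duplication|speciation)$", lab))
  if (!ok)
    stop("internal node without [&age=...,event=...] annotation in: ",
         substr(nwk, 1, 60))
  tr2 <- tr; tr2$node.label <- NULL
  geneTree(tr2,
           ages = as.numeric(sub("_.*$", "", lab)),
           events = sub("^[^_]*_", "", lab))
}

#' Write a cohort to a directory
#'
#' Emits seven plain-text artifacts: `proteins.fasta`, `trees.nwk` (one
#' annotated Newick per line), `gene_models.tsv`, `expression.tsv`,
#' `annotations.tsv`, `labels.tsv` (`gene_id<TAB>essential|viable`) and
#' `ppi_edges.tsv`. [readCohort()] restores the cohort losslessly.
#'
#' @param cohort A [SyntheticCohort].
#' @param directory Output directory (created if absent).
#' @return Invisibly, a manifest data frame with columns `file` and
#'   `records`.
#' @export
writeCohort <- function(cohort, directory) {
  stopifnot(is(cohort, "SyntheticCohort"))
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create directory: ", directory)
  fp <- function(f) file.path(directory, f)

  Biostrings::writeXStringSet(cohort@proteins, fp("proteins.fasta"))

  writeLines(vapply(cohort@trees, .newickWithComments, character(1)),
             fp("trees.nwk"))

  g <- cohort@genes
  gm <- data.frame(
    gene_id = g$gene_id,
    gene_length = g$gene_length,
    gc = sprintf("%.17g", g$gc),
    transcripts = vapply(g$transcripts, function(tx)
      paste(vapply(tx, paste, character(1), collapse = ","), collapse = ";"),
      character(1)),
    stringsAsFactors = FALSE)
  write.table(gm, fp("gene_models.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  cts <- cohort@expression@counts
  em <- data.frame(gene_id = rownames(cts) %||% character(0),
                   cts, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(em) <- c("gene_id", DEVELOPMENTAL_STAGES)
  write.table(em, fp("expression.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  write.table(cohort@annotations, fp("annotations.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  lab <- cohort@labels
  write.table(data.frame(names(lab), unname(lab)), fp("labels.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  if (!length(lab)) cat("", file = fp("labels.tsv"))

  e <- igraph::as_edgelist(cohort@ppi)
  write.table(e, fp("ppi_edges.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  if (!nrow(e)) cat("", file = fp("ppi_edges.tsv"))

  files <- c("proteins.fasta", "trees.nwk", "gene_models.tsv",
             "expression.tsv", "annotations.tsv", "labels.tsv",
             "ppi_edges.tsv")
  manifest <- data.frame(
    file = files,
    records = c(length(cohort@proteins), length(cohort@trees),
                nrow(cohort@genes), nrow(cts), nrow(cohort@annotations),
                length(lab), nrow(e)),
    stringsAsFactors = FALSE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a cohort from a directory
#'
#' Restores a [SyntheticCohort] written by [writeCohort()].
#'
#' @param directory Directory containing the seven cohort files.
#' @return A [SyntheticCohort].
#' @export
readCohort <- function(directory) {
  fp <- function(f) file.path(directory, f)
  for (f in c("proteins.fasta", "trees.nwk", "gene_models.tsv",
              "expression.tsv", "annotations.tsv", "labels.tsv",
              "ppi_edges.tsv"))
    if (!file.exists(fp(f))) stop("missing cohort file: ", fp(f))

  lab_raw <- tryCatch(
    read.delim(fp("labels.tsv"), header = FALSE, stringsAsFactors = FALSE),
    error = function(e) data.frame(V1 = character(0), V2 = character(0)))
  labels <- setNames(as.character(lab_raw[[2L]]), as.character(lab_raw[[1L]]))

  proteins <- Biostrings::readAAStringSet(fp("proteins.fasta"))

  nwk <- readLines(fp("trees.nwk"))
  nwk <- nwk[nzchar(nwk)]
  trees <- lapply(nwk, .parseGeneTree)
  names(trees) <- vapply(trees, function(gt) {
    hit <- gt@tree$tip.label[gt@tree$tip.label %in% names(labels)]
    if (length(hit) != 1L)
      stop("tree does not contain exactly one labelled gene leaf")
    hit
  }, character(1))

  gm <- read.delim(fp("gene_models.tsv"), stringsAsFactors = FALSE,
                   colClasses = c("character", "numeric", "numeric",
                                  "character"))
  genes <- data.frame(gene_id = gm$gene_id, gene_length = gm$gene_length,
                      gc = gm$gc, stringsAsFactors = FALSE)
  genes$transcripts <- lapply(gm$transcripts, function(s) {
    if (!nzchar(s)) return(list())
    lapply(strsplit(s, ";", fixed = TRUE)[[1L]],
           function(t) as.numeric(strsplit(t, ",", fixed = TRUE)[[1L]]))
  })

  em <- read.delim(fp("expression.tsv"), check.names = FALSE,
                   stringsAsFactors = FALSE)
  cts <- as.matrix(em[, -1L, drop = FALSE])
  storage.mode(cts) <- "integer"
  rownames(cts) <- em$gene_id
  expr <- new("StageExpression", counts = cts)

  ann <- read.delim(fp("annotations.tsv"), stringsAsFactors = FALSE)

  edges <- tryCatch(
    read.delim(fp("ppi_edges.tsv"), header = FALSE, stringsAsFactors = FALSE),
    error = function(e) data.frame(V1 = character(0), V2 = character(0)))
  ppi <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = if (length(labels)) names(labels) else NULL)

  new("SyntheticCohort", genes = genes, proteins = proteins,
      annotations = ann, expression = expr, ppi = ppi, trees = trees,
      labels = labels)
}
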