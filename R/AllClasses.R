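#' @import methods
NULL

setOldClass("phylo")
setOldClass("igraph")

#' Two-group cohort generator configuration
#'
#' Holds every tunable of the synthetic cohort generator: group sizes,
#' per-group location parameters for gene/protein features, Dirichlet
#' parameters for amino-acid composition, Bernoulli annotation rates,
#' stage-wise expression parameters, PPI attachment fitness and the gene-tree
#' age weights. Construct with [cohortConfig()].
#'
#' All per-group slots are indexed `c(essential, viable)`.
#'
#' @slot nEssential,nViable Group sizes (genes).
#' @slot geneLengthMedian Median gene length per group (bp; log-normal).
#' @slot geneLengthSdlog Log-scale SD of gene length.
#' @slot exonLengthMedian Median total exon length per group (bp).
#' @slot exonLengthSdlog Log-scale SD of total exon length.
#' @slot exonCountMean Mean exon count per group (Poisson truncated >= 1).
#' @slot transcriptCountMean Mean transcript count per group (truncated >= 1).
#' @slot gcMean Mean GC fraction per group (Beta).
#' @slot gcConcentration Beta concentration (alpha + beta) for GC.
#' @slot aaDirichletAlpha 20 x 2 matrix of Dirichlet parameters (rows named by
#'   residue, columns `essential`, `viable`).
#' @slot annotationRates Data frame `flag`, `essential`, `viable` of Bernoulli
#'   annotation-flag rates in \[0, 1\].
#' @slot enzymeClassRates 6 x 2 matrix of per-class enzyme annotation rates
#'   (rows oxidoreductase..ligase); the remainder of each column is
#'   non-enzymatic.
#' @slot tmRate Probability a protein has any transmembrane segment, per group.
#' @slot expressedFraction 13 x 2 matrix; probability a gene has nonzero ESTs
#'   at each stage (one minus the zero-inflation probability).
#' @slot expressionMean Mean EST count per expressed (gene, stage) cell, per
#'   group (gamma-Poisson).
#' @slot expressionDispersion Negative-binomial size parameter.
#' @slot ppiFitnessMultiplier Attachment fitness multiplier (>= 1) for
#'   essential nodes in the preferential-attachment PPI graph.
#' @slot ppiEdgesPerNode Edges added per incoming node.
#' @slot treeDuplicationProb Probability a gene's tree contains a duplication
#'   ancestor.
#' @slot mrdAgeWeights 16 x 2 matrix of sampling weights over the taxon age
#'   groups for a gene's most-recent-duplication (or singleton) age.
#' @slot seed Integer seed driving all randomness.
#' @seealso [generateCohort()]
#' @export
setClass("CohortConfig", representation(
  nEssential = "integer", nViable = "integer",
  geneLengthMedian = "numeric", geneLengthSdlog = "numeric",
  exonLengthMedian = "numeric", exonLengthSdlog = "numeric",
  exonCountMean = "numeric", transcriptCountMean = "numeric",
  gcMean = "numeric", gcConcentration = "numeric",
  aaDirichletAlpha = "matrix",
  annotationRates = "data.frame",
  enzymeClassRates = "matrix",
  tmRate = "numeric",
  expressedFraction = "matrix",
  expressionMean = "numeric", expressionDispersion = "numeric",
  ppiFitnessMultiplier = "numeric", ppiEdgesPerNode = "integer",
  treeDuplicationProb = "numeric",
  mrdAgeWeights = "matrix",
  seed = "integer"
))

.pairOK <- function(x, lo = -Inf, hi = Inf) {
  length(x) == 2L && all(is.finite(x)) && all(x >= lo) && all(x <= hi)
}

setValidity("CohortConfig", function(object) {
  msg <- character(0)
  bad <- function(m) msg <<- c(msg, m)
  if (length(object@nEssential) != 1L || is.na(object@nEssential) ||
      object@nEssential < 0L) bad("nEssential must be a count >= 0")
  if (length(object@nViable) != 1L || is.na(object@nViable) ||
      object@nViable < 0L) bad("nViable must be a count >= 0")
  if (!.pairOK(object@geneLengthMedian, lo = 1)) bad("geneLengthMedian must be two positive values")
  if (!.pairOK(object@exonLengthMedian, lo = 1)) bad("exonLengthMedian must be two positive values")
  if (!.pairOK(object@exonCountMean, lo = 0)) bad("exonCountMean must be two values >= 0")
  if (!.pairOK(object@transcriptCountMean, lo = 0)) bad("transcriptCountMean must be two values >= 0")
  if (!.pairOK(object@gcMean, lo = 0, hi = 1)) bad("gcMean must be two fractions in [0, 1]")
  if (!all(dim(object@aaDirichletAlpha) == c(20L, 2L)))
    bad("aaDirichletAlpha must be a 20 x 2 matrix")
  else if (any(object@aaDirichletAlpha <= 0))
    bad("aaDirichletAlpha entries must be > 0")
  ar <- object@annotationRates
  if (!all(c("flag", "essential", "viable") %in% names(ar)))
    bad("annotationRates needs columns flag, essential, viable")
  else if (any(ar$essential < 0 | ar$essential > 1 | ar$viable < 0 | ar$viable > 1))
    bad("annotationRates rates must lie in [0, 1]")
  if (!all(dim(object@enzymeClassRates) == c(6L, 2L)) ||
      any(object@enzymeClassRates < 0) || any(colSums(object@enzymeClassRates) > 1))
    bad("enzymeClassRates must be a 6 x 2 matrix of rates with column sums <= 1")
  if (!.pairOK(object@tmRate, 0, 1)) bad("tmRate must be two rates in [0, 1]")
  if (!all(dim(object@expressedFraction) == c(13L, 2L)) ||
      any(object@expressedFraction < 0) || any(object@expressedFraction > 1))
    bad("expressedFraction must be a 13 x 2 matrix of rates in [0, 1]")
  if (!.pairOK(object@expressionMean, lo = 1)) bad("expressionMean must be two values >= 1")
  if (length(object@ppiFitnessMultiplier) != 1L || object@ppiFitnessMultiplier < 1)
    bad("ppiFitnessMultiplier must be a single value >= 1")
  if (length(object@treeDuplicationProb) != 1L ||
      object@treeDuplicationProb < 0 || object@treeDuplicationProb > 1)
    bad("treeDuplicationProb must be a probability")
  if (!all(dim(object@mrdAgeWeights) == c(16L, 2L)) ||
      any(object@mrdAgeWeights < 0) || any(colSums(object@mrdAgeWeights) <= 0))
    bad("mrdAgeWeights must be a 16 x 2 matrix of non-negative weights")
  if (length(object@seed) != 1L || is.na(object@seed)) bad("seed must be one integer")
  if (length(msg)) msg else TRUE
})

#' Stage-wise EST count table
#'
#' A genes x stages matrix of non-negative integer EST counts over the 13
#' canonical developmental stages. Construct with [stageExpression()].
#'
#' @slot counts Integer matrix, rows named by gene, columns by stage.
#' @seealso [tpmNormalize()], [stageExpressionFrequencies()]
#' @export
setClass("StageExpression", representation(counts = "matrix"))

setValidity("StageExpression", function(object) {
  cts <- object@counts
  if (!is.numeric(cts)) return("counts must be numeric")
  if (ncol(cts) != 13L || !identical(colnames(cts), DEVELOPMENTAL_STAGES))
    return(paste0("counts must have exactly the 13 canonical stage columns, ",
                  "in order: ", paste(DEVELOPMENTAL_STAGES, collapse = ", ")))
  if (nrow(cts) > 0 && is.null(rownames(cts))) return("counts rows must be named by gene")
  if (any(cts < 0)) return("EST counts must be non-negative")
  if (any(cts != floor(cts))) return("EST counts must be integers")
  TRUE
})

#' Duplication-annotated gene tree
#'
#' A rooted ultrametric-ordered gene tree whose internal nodes carry an age
#' (MYA) and an event type (`duplication` or `speciation`), used to assign
#' MRD/DCA/SCA evolutionary ages to its leaf genes.
#'
#' @slot tree An `ape` `phylo` object.
#' @slot ages Numeric vector of internal node ages (MYA), indexed by internal
#'   node number minus the number of tips.
#' @slot events Character vector (`duplication`/`speciation`), same indexing.
#' @seealso [geneTree()], [assignAges()], [readGeneTrees()]
#' @export
setClass("GeneTree", representation(
  tree = "phylo", ages = "numeric", events = "character"
))

setValidity("GeneTree", function(object) {
  tr <- object@tree
  nint <- tr$Nnode
  if (length(object@ages) != nint || length(object@events) != nint)
    return("one age and one event per internal node required")
  if (any(is.na(object@ages)) || any(object@ages < 0))
    return("node ages must be non-negative numbers")
  if (!all(object@events %in% c("duplication", "speciation")))
    return("events must be 'duplication' or 'speciation'")
  ## root-to-leaf age ordering: every child internal node is no older
  ## than its parent
  ntip <- length(tr$tip.label)
  for (k in seq_len(nrow(tr$edge))) {
    par <- tr$edge[k, 1L]; chl <- tr$edge[k, 2L]
    if (chl > ntip && object@ages[chl - ntip] > object@ages[par - ntip] + 1e-9)
      return("node ages must be non-increasing from root to leaves")
  }
  TRUE
})

#' Synthetic two-group cohort
#'
#' A labelled cohort bundling every data layer the pipeline consumes: gene
#' models, protein sequences, annotation flags, stage-wise expression, the
#' PPI graph and per-gene trees. Produced by [generateCohort()] or
#' [readCohort()]; layers not generated are empty.
#'
#' @slot genes Data frame: `gene_id`, `gene_length`, `gc`, and a `transcripts`
#'   list-column of per-transcript exon-length vectors.
#' @slot proteins An [Biostrings::AAStringSet] named by gene id.
#' @slot annotations Data frame of per-gene annotation flags (logical),
#'   `enzyme_class` and `tm_count`.
#' @slot expression A [StageExpression] (possibly zero rows).
#' @slot ppi An `igraph` undirected simple graph.
#' @slot trees Named list of [GeneTree] objects.
#' @slot labels Named character vector, values `essential` or `viable`.
#' @export
setClass("SyntheticCohort", representation(
  genes = "data.frame",
  proteins = "AAStringSet",
  annotations = "data.frame",
  expression = "StageExpression",
  ppi = "igraph",
  trees = "list",
  labels = "character"
))

setValidity("SyntheticCohort", function(object) {
  lab <- object@labels
  if (length(lab) && is.null(names(lab))) return("labels must be named by gene id")
  if (!all(lab %in% c("essential", "viable")))
    return("labels must be 'essential' or 'viable'")
  if (anyDuplicated(names(lab))) return("each gene must carry exactly one label")
  gid <- object@genes$gene_id
  if (length(gid) && !all(gid %in% names(lab)))
    return("every gene needs a label")
  pid <- names(object@proteins)
  if (length(pid) && (anyDuplicated(pid) || !all(pid %in% names(lab))))
    return("protein ids must map 1-1 to labelled gene ids")
  TRUE
})

#' Pipeline report bundle
#'
#' The full output of one [runPipeline()] invocation: one comparison table
#' per feature block (each row a [compareNumeric()]/[compareCategorical()]
#' result), per-node PPI metric tables, age-frequency tables, and a run
#' manifest recording the seed, group sizes and family sizes.
#'
#' @slot tables Named list of data frames.
#' @slot manifest Data frame of run provenance (one row per dataset/block).
#' @export
setClass("ReportBundle", representation(
  tables = "list", manifest = "data.frame"
))

setMethod("show", "CohortConfig", function(object) {
  cat("CohortConfig:", object@nEssential, "essential /", object@nViable,
      "viable genes; seed", object@seed, "\n")
  cat("  gene length medians (bp):",
      paste(object@geneLengthMedian, collapse = " / "), "\n")
  cat("  annotation flags:", nrow(object@annotationRates),
      "; PPI fitness x", object@ppiFitnessMultiplier,
      "; P(duplication) =", object@treeDuplicationProb, "\n")
})

setMethod("show", "StageExpression", function(object) {
  cat("StageExpression:", nrow(object@counts), "genes x 13 stages; total ESTs",
      sum(object@counts), "\n")
})

setMethod("show", "GeneTree", function(object) {
  cat("GeneTree:", length(object@tree$tip.label), "leaves; root",
      object@ages[1L], "MYA (", object@events[1L], ");",
      sum(object@events == "duplication"), "duplication node(s)\n")
})

setMethod("show", "SyntheticCohort", function(object) {
  n <- table(factor(object@labels, c("essential", "viable")))
  cat("SyntheticCohort:", n[["essential"]], "essential /", n[["viable"]],
      "viable genes\n")
  cat("  proteins:", length(object@proteins),
      " | expression rows:", nrow(object@expression@counts),
      " | PPI nodes:", igraph::vcount(object@ppi),
      " | trees:", length(object@trees), "\n")
})

setMethod("show", "ReportBundle", function(object) {
  cat("ReportBundle with", length(object@tables), "tables:\n")
  for (nm in names(object@tables)) {
    tb <- object@tables[[nm]]
    sig <- if ("significant" %in% names(tb)) sum(tb$significant) else NA
    cat("  ", nm, ": ", nrow(tb), " rows",
        if (!is.na(sig)) paste0(" (", sig, " significant)"), "\n", sep = "")
  }
})

#' Accessors for cohort and report components
#'
#' `cohortLabels()` returns the named essential/viable label vector,
#' `cohortGenes()` the gene-model table, `cohortProteins()` the protein
#' sequences, `cohortExpression()` the stage-wise EST counts,
#' `cohortPPI()` the interaction graph and `cohortTrees()` the gene trees.
#' `reportTables()` and `reportManifest()` unwrap a [ReportBundle].
#'
#' @param x A [SyntheticCohort] or [ReportBundle].
#' @return The corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
cohortLabels <- function(x) x@labels
#' @rdname accessors
#' @export
cohortGenes <- function(x) x@genes
#' @rdname accessors
#' @export
cohortProteins <- function(x) x@proteins
#' @rdname accessors
#' @export
cohortAnnotations <- function(x) x@annotations
#' @rdname accessors
#' @export
cohortExpression <- function(x) x@expression
#' @rdname accessors
#' @export
cohortPPI <- function(x) x@ppi
#' @rdname accessors
#' @export
cohortTrees <- function(x) x@trees
#' @rdname accessors
#' @export
reportTables <- function(x) x@tables
#' @rdname accessors
#' @export
reportManifest <- function(x) x@manifest

#' @rdname accessors
#' @export
estCounts <- function(x) {
  if (is(x, "SyntheticCohort")) x@expression@counts else x@counts
}
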