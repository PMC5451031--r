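# End-to-end orchestration: cohort -> feature extraction -> (optional
# redundancy culling) -> per-block two-group comparisons under per-family
# Bonferroni control -> ReportBundle.

## default Bonferroni family sizes, one per comparison block
.FAMILY_DEFAULTS <- list(
  gene_features = 6L,       # six genomic features
  pepstats = 13L,           # length, MW, charge, pI + nine categories
  amino_acids = 20L,
  expression_stages = 13L,
  age_groups = 16L,
  enzyme_class = 6L,
  keywords = 4L,            # phosphoprotein, glycoprotein, acetylation,
                            # transcription
  signal_peptide = 1L,
  subcellular = 12L,
  housekeeping = 2L,
  ppi_centrality = 5L,      # degree, asp, bc, cco, cc
  ppi_hub = 4L              # bn, epc, mnc, dmnc
)

.KEYWORD_FLAGS <- c("phosphoprotein", "glycoprotein", "acetylation",
                    "transcription")

.withDataset <- function(df, dataset) {
  if (is.null(df) || !nrow(df)) return(df)
  cbind(data.frame(dataset = dataset, stringsAsFactors = FALSE), df)
}

.compareFlagBlock <- function(ann, lab, flags, m, alpha) {
  nE <- sum(lab == "essential"); nV <- sum(lab == "viable")
  do.call(rbind, lapply(flags, function(fl) {
    compareCategorical(sum(ann[[fl]][lab == "essential"]), nE,
                       sum(ann[[fl]][lab == "viable"]), nV,
                       feature = fl, m = m, alpha = alpha)
  }))
}

.compareNumericBlock <- function(tab, lab, cols, m, alpha, gate) {
  do.call(rbind, lapply(cols, function(cl) {
    x <- tab[[cl]]
    a <- x[lab == "essential"]; a <- a[!is.na(a)]
    b <- x[lab == "viable"];    b <- b[!is.na(b)]
    compareNumeric(a, b, feature = cl, m = m, alpha = alpha, gate = gate)
  }))
}

.featureBlocks <- function(cohort, ids, dataset, fam, alpha, gate) {
  lab0 <- cohort@labels[ids]
  tables <- list()

  gf <- geneFeatures(cohort@genes[match(ids, cohort@genes$gene_id), ,
                                  drop = FALSE])
  lab <- lab0
  tables$gene_features <- .withDataset(
    .compareNumericBlock(gf, lab,
                         c("gene_length", "gc_percent", "n_transcripts",
                           "n_exons", "exon_length", "intron_length"),
                         fam$gene_features, alpha, gate), dataset)

  pf <- proteinFeatureTable(cohort@proteins[ids])
  tables$pepstats <- .withDataset(
    .compareNumericBlock(pf, lab,
                         c("length", "mw", "charge", "pI",
                           paste0("cat_", names(AA_CATEGORIES))),
                         fam$pepstats, alpha, gate), dataset)
  tables$amino_acids <- .withDataset(
    .compareNumericBlock(pf, lab, paste0("freq_", AA_STANDARD),
                         fam$amino_acids, alpha, gate), dataset)

  ann <- cohort@annotations[match(ids, cohort@annotations$gene_id), ,
                            drop = FALSE]
  tables$keywords <- .withDataset(
    .compareFlagBlock(ann, lab, .KEYWORD_FLAGS, fam$keywords, alpha),
    dataset)
  tables$signal_peptide <- .withDataset(
    .compareFlagBlock(ann, lab, "signal_peptide", fam$signal_peptide,
                      alpha), dataset)
  loc <- grep("^loc_", names(ann), value = TRUE)
  if (length(loc))
    tables$subcellular <- .withDataset(
      .compareFlagBlock(ann, lab, loc, length(loc), alpha), dataset)
  tables$housekeeping <- .withDataset(
    .compareFlagBlock(ann, lab, c("housekeeping", "tissue_enriched"),
                      fam$housekeeping, alpha), dataset)

  nE <- sum(lab == "essential"); nV <- sum(lab == "viable")
  cls <- rownames(.ENZYME_RATES_DEFAULT)
  tables$enzyme_class <- .withDataset(do.call(rbind, lapply(cls, function(cl)
    compareCategorical(sum(ann$enzyme_class[lab == "essential"] == cl), nE,
                       sum(ann$enzyme_class[lab == "viable"] == cl), nV,
                       feature = cl, m = fam$enzyme_class, alpha = alpha))),
    dataset)
  tables
}

#' Run the full comparison pipeline
#'
#' Generates (or accepts) a labelled cohort, extracts every feature layer,
#' runs the per-block two-group comparisons under their Bonferroni family
#' sizes (six genomic features; 13 protein features; 20 residue
#' frequencies; 13 developmental stages; 16 age groups each for MRD and
#' DCA; six enzyme classes; four keywords; subcellular locations;
#' housekeeping/tissue enrichment; five centrality and four hub PPI
#' metrics), and — when culling thresholds are supplied — repeats the
#' sequence-derived blocks on each non-redundant subset.
#'
#' @param config A [CohortConfig] (used when `cohort` is `NULL`).
#' @param cohort Optionally a ready [SyntheticCohort] (e.g. from
#'   [readCohort()]).
#' @param cullingThresholds Numeric vector of identity thresholds (subset
#'   of 20/40/60/80 typically); empty for no culled datasets.
#' @param familySizes Named list overriding entries of the default family
#'   sizes.
#' @param alpha Family-wise significance level.
#' @param gate Normality-gate method for numeric comparisons.
#' @param epcRepetitions,epcRetention EPC Monte-Carlo parameters.
#' @param snapAges Passed to [assignAgesAll()].
#' @param verbose Log stage timings to stderr.
#' @return A [ReportBundle].
#' @export
runPipeline <- function(config = cohortConfig(), cohort = NULL,
                        cullingThresholds = numeric(0),
                        familySizes = list(), alpha = 0.05,
                        gate = "lilliefors",
                        epcRepetitions = 100L, epcRetention = 0.5,
                        snapAges = FALSE, verbose = FALSE) {
  fam <- utils::modifyList(.FAMILY_DEFAULTS, familySizes)
  t0 <- Sys.time()
  log_ <- function(...) if (verbose)
    message(format(Sys.time(), "%H:%M:%S "), ...)

  if (is.null(cohort)) {
    log_("generating cohort (seed ", config@seed, ")")
    cohort <- generateCohort(config)
  }
  seed <- if (!is.null(config)) config@seed else NA_integer_
  lab <- cohort@labels
  ids <- names(lab)
  nE <- sum(lab == "essential"); nV <- sum(lab == "viable")
  if (nE == 0L || nV == 0L) stop("both groups must be non-empty")

  log_("feature comparisons, non-culled (", nE, " / ", nV, ")")
  tables <- .featureBlocks(cohort, ids, "non-culled", fam, alpha, gate)

  ## expression block
  cts <- cohort@expression@counts
  if (nrow(cts)) {
    tpm <- tpmNormalize(cts)
    tables$expression_stages <- .withDataset(
      stageExpressionFrequencies(tpm, lab, m = fam$expression_stages,
                                 alpha = alpha), "non-culled")
  }

  ## evolutionary age block
  if (length(cohort@trees)) {
    log_("age assignment (", length(cohort@trees), " trees)")
    assg <- assignAgesAll(cohort@trees, snapAges = snapAges)
    tables$age_mrd <- .withDataset(
      ageGroupFrequencies(assg, lab, mode = "MRD", alpha = alpha),
      "non-culled")
    tables$age_dca <- .withDataset(
      ageGroupFrequencies(assg, lab, mode = "DCA", alpha = alpha),
      "non-culled")
  }

  ## PPI topology block
  if (igraph::vcount(cohort@ppi) > 0L) {
    log_("PPI topology (", igraph::vcount(cohort@ppi), " nodes)")
    nm <- nodeMetrics(cohort@ppi, epcRepetitions = epcRepetitions,
                      epcRetention = epcRetention,
                      epcSeed = if (is.na(seed)) NULL else seed + 1L)
    nmlab <- lab[nm$node]
    keep <- !is.na(nmlab)
    nm <- nm[keep, , drop = FALSE]; nmlab <- nmlab[keep]
    tables$ppi_metrics <- .withDataset(nm, "non-culled")
    tables$ppi_centrality <- .withDataset(
      .compareNumericBlock(nm, nmlab, c("degree", "asp", "bc", "cco", "cc"),
                           fam$ppi_centrality, alpha, gate), "non-culled")
    tables$ppi_hub <- .withDataset(
      .compareNumericBlock(nm, nmlab, c("bn", "epc", "mnc", "dmnc"),
                           fam$ppi_hub, alpha, gate), "non-culled")
  }

  ## culled datasets: sequence-derived blocks only
  for (thr in cullingThresholds) {
    log_("culling at ", thr, "% identity")
    res <- cullSequences(as.character(cohort@proteins), threshold = thr)
    kept <- res$retained
    name <- paste0("culled-", thr)
    blk <- .featureBlocks(cohort, kept, name, fam, alpha, gate)
    for (nm2 in names(blk))
      tables[[nm2]] <- rbind(tables[[nm2]], blk[[nm2]])
  }

  manifest <- data.frame(
    block = names(tables),
    rows = vapply(tables, nrow, integer(1)),
    n_essential = nE, n_viable = nV, seed = seed,
    alpha = alpha,
    culled = paste(cullingThresholds, collapse = ","),
    stringsAsFactors = FALSE)
  rownames(manifest) <- NULL
  log_("done in ",
       round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 1), " s")
  new("ReportBundle", tables = tables, manifest = manifest)
}

#' Validate cohort inputs
#'
#' Non-destructive diagnostics over a cohort (or a cohort directory):
#' label coverage of genes/proteins, canonical stage names, tree
#' parseability and focal leaves, PPI edge sanity. Problems are returned,
#' not thrown.
#'
#' @param x A [SyntheticCohort] or a directory written by [writeCohort()].
#' @return Data frame with columns `level` (`"error"`/`"warning"`) and
#'   `message`; zero rows when everything checks out.
#' @export
validateInputs <- function(x) {
  diags <- list()
  add <- function(level, msg)
    diags[[length(diags) + 1L]] <<- data.frame(level = level, message = msg,
                                               stringsAsFactors = FALSE)
  if (is.character(x)) {
    x <- tryCatch(readCohort(x), error = function(e) {
      add("error", conditionMessage(e)); NULL
    })
    if (is.null(x))
      return(do.call(rbind, diags))
  }
  lab <- x@labels
  gid <- x@genes$gene_id
  if (length(gid)) {
    miss <- setdiff(gid, names(lab))
    if (length(miss))
      add("error", paste("unlabelled genes:",
                         paste(head(miss, 5L), collapse = ", ")))
  }
  orphan <- setdiff(names(lab), gid)
  if (length(gid) && length(orphan))
    add("warning", paste("labelled genes absent from gene models:",
                         paste(head(orphan, 5L), collapse = ", ")))
  pid <- names(x@proteins)
  if (length(pid)) {
    missp <- setdiff(names(lab), pid)
    if (length(missp))
      add("warning", paste("labelled genes without protein sequence:",
                           paste(head(missp, 5L), collapse = ", ")))
  }
  cts <- x@expression@counts
  if (ncol(cts) != 13L || !identical(colnames(cts), DEVELOPMENTAL_STAGES)) {
    missing_stages <- setdiff(DEVELOPMENTAL_STAGES, colnames(cts))
    add("error", paste("expression table must have the 13 canonical stages;",
                       "missing:", paste(missing_stages, collapse = ", ")))
  }
  if (length(x@trees)) {
    nofocal <- names(x@trees)[!vapply(seq_along(x@trees), function(i)
      names(x@trees)[i] %in% x@trees[[i]]@tree$tip.label, logical(1))]
    if (length(nofocal))
      add("error", paste("trees whose focal gene is not a leaf:",
                         paste(head(nofocal, 5L), collapse = ", ")))
  }
  if (igraph::vcount(x@ppi) > 0L) {
    if (any(igraph::which_loop(x@ppi)))
      add("warning", "PPI graph contains self-loops; run cleanGraph()")
    if (any(igraph::which_multiple(x@ppi)))
      add("warning", "PPI graph contains duplicate edges; run cleanGraph()")
    unk <- setdiff(igraph::V(x@ppi)$name, names(lab))
    if (length(unk))
      add("warning", paste("PPI nodes without labels:",
                           paste(head(unk, 5L), collapse = ", ")))
  }
  out <- do.call(rbind, diags)
  if (is.null(out))
    out <- data.frame(level = character(0), message = character(0),
                      stringsAsFactors = FALSE)
  out
}
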