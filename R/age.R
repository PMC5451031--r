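# Evolutionary age assignment from duplication-annotated gene trees:
# MRD (nearest duplication ancestor), DCA (farthest duplication ancestor),
# SCA fallback (root age) for genes without duplicates, and the 16-row
# taxon-group frequency tables.

.ancestorPath <- function(tree, tip) {
  ## internal node numbers from the tip's parent up to the root
  ntip <- length(tree$tip.label)
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  path <- integer(0)
  node <- tip
  while (parent[node] != 0L) {
    node <- parent[node]
    path <- c(path, node)
    if (node == ntip + 1L) break
  }
  path
}

.ageToTaxon <- function(age, snap = FALSE) {
  hit <- which(abs(TAXON_AGES$age - age) < 1e-9)
  if (length(hit) == 1L) return(TAXON_AGES$taxon[hit])
  if (!snap)
    stop("age ", age, " MYA is not one of the 16 taxon ages; ",
         "use snapAges = TRUE to map to the nearest group")
  TAXON_AGES$taxon[which.min(abs(TAXON_AGES$age - age))]
}

#' Assign MRD and DCA evolutionary ages to a gene
#'
#' Walks the ancestor chain of the gene's leaf. The MRD age is that of the
#' nearest ancestor flagged as a duplication; the DCA age is that of the
#' farthest duplication ancestor. A gene with no duplication ancestor is a
#' singleton: both ages fall back to the SCA, the age of the tree root.
#' Ages are mapped to the 16 taxon groups of [taxonAgeTable()].
#'
#' @param tree A [GeneTree].
#' @param gene_id A leaf label of the tree.
#' @param snapAges If `TRUE`, non-matching ages snap to the nearest taxon
#'   age; the default requires exact matches and errors otherwise, to
#'   surface data problems.
#' @return Data frame with one row: `gene_id`, `mrd_sca_age`,
#'   `dca_sca_age`, `mrd_group`, `dca_group`, `is_singleton`.
#' @examples
#' tr <- ape::read.tree(text = "((g1,p1),og);")
#' gt <- geneTree(tr, ages = c(937, 167),
#'                events = c("speciation", "duplication"))
#' assignAges(gt, "g1")  # MRD 167 (Mammalia), DCA 167
#' @export
assignAges <- function(tree, gene_id, snapAges = FALSE) {
  stopifnot(is(tree, "GeneTree"))
  tr <- tree@tree
  tip <- match(gene_id, tr$tip.label)
  if (is.na(tip)) stop("gene '", gene_id, "' is not a leaf of the tree")
  ntip <- length(tr$tip.label)
  path <- .ancestorPath(tr, tip)       # nearest ancestor first
  ages <- tree@ages[path - ntip]
  events <- tree@events[path - ntip]
  dup <- which(events == "duplication")
  if (length(dup)) {
    mrd <- ages[dup[1L]]               # nearest duplication
    dca <- max(ages[dup])              # farthest (oldest) duplication
    singleton <- FALSE
  } else {
    mrd <- dca <- ages[length(ages)]   # SCA: root age
    singleton <- TRUE
  }
  data.frame(gene_id = gene_id, mrd_sca_age = mrd, dca_sca_age = dca,
             mrd_group = .ageToTaxon(mrd, snapAges),
             dca_group = .ageToTaxon(dca, snapAges),
             is_singleton = singleton, stringsAsFactors = FALSE)
}

#' Age assignments for a collection of gene trees
#'
#' @param trees Named list of [GeneTree] objects (names are gene ids, each
#'   a leaf of its tree), as in [cohortTrees()].
#' @param snapAges Passed to [assignAges()].
#' @return Data frame with one row per gene.
#' @export
assignAgesAll <- function(trees, snapAges = FALSE) {
  do.call(rbind, lapply(names(trees), function(id)
    assignAges(trees[[id]], id, snapAges = snapAges)))
}

#' Age-group frequency table with per-row comparisons
#'
#' Tabulates the percentage of each group's genes falling in each of the 16
#' taxon age groups (columns sum to 100 within rounding) and compares the
#' two groups per row by chi-squared test under a Bonferroni family of 16.
#'
#' @param assignments Data frame from [assignAgesAll()].
#' @param labels Named label vector (`essential`/`viable`).
#' @param mode `"MRD"` or `"DCA"`: which age assignment to tabulate.
#' @param alpha Family-wise significance level.
#' @return Data frame with 16 rows: `taxon`, `age`, `pct_essential`,
#'   `pct_viable`, `test`, `statistic`, `p`, `threshold`, `significant`.
#' @export
ageGroupFrequencies <- function(assignments, labels, mode = c("MRD", "DCA"),
                                alpha = 0.05) {
  mode <- match.arg(mode)
  col <- if (mode == "MRD") "mrd_group" else "dca_group"
  lab <- labels[assignments$gene_id]
  if (any(is.na(lab))) stop("every assigned gene must be labelled")
  nE <- sum(lab == "essential"); nV <- sum(lab == "viable")
  if (nE == 0L || nV == 0L)
    stop("both groups must be non-empty for a frequency comparison")
  grp <- factor(assignments[[col]], levels = TAXON_AGES$taxon)
  tabE <- table(grp[lab == "essential"])
  tabV <- table(grp[lab == "viable"])
  out <- vector("list", 16L)
  for (r in seq_len(16L)) {
    cmp <- compareCategorical(as.integer(tabE[r]), nE,
                              as.integer(tabV[r]), nV,
                              feature = TAXON_AGES$taxon[r], m = 16L,
                              alpha = alpha)
    out[[r]] <- data.frame(taxon = TAXON_AGES$taxon[r],
                           age = TAXON_AGES$age[r],
                           pct_essential = cmp$pct_a,
                           pct_viable = cmp$pct_b,
                           test = cmp$test, statistic = cmp$statistic,
                           p = cmp$p, threshold = cmp$threshold,
                           significant = cmp$significant,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Read annotated gene trees from a Newick file
#'
#' Reads one tree per line; internal nodes must carry
#' `[&age=<MYA>,event=<duplication|speciation>]` comments. Each tree is
#' keyed by the single leaf found in `gene_ids`.
#'
#' @param path Newick file.
#' @param gene_ids Character vector of gene ids expected as leaves.
#' @return Named list of [GeneTree] objects.
#' @export
readGeneTrees <- function(path, gene_ids) {
  nwk <- readLines(path)
  nwk <- nwk[nzchar(nwk)]
  trees <- lapply(nwk, .parseGeneTree)
  names(trees) <- vapply(trees, function(gt) {
    hit <- gt@tree$tip.label[gt@tree$tip.label %in% gene_ids]
    if (length(hit) != 1L)
      stop("a tree does not contain exactly one known gene leaf")
    hit
  }, character(1))
  trees
}
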