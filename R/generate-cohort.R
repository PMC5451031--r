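# Synthetic two-group cohort generation. All randomness flows from the
# config seed; generation order is fixed so identical configs give
# byte-identical cohorts.

.rtruncpois <- function(n, lambda) {
  ## Poisson truncated at >= 1 via inverse CDF on the truncated support
  if (n == 0L) return(integer(0))
  lambda <- pmax(lambda, 1e-8)
  u <- runif(n)
  p0 <- exp(-lambda)
  stats::qpois(p0 + u * (1 - p0), lambda)
}

.rdirichlet1 <- function(alpha) {
  x <- rgamma(length(alpha), shape = alpha)
  if (sum(x) <= 0) x[which.max(alpha)] <- 1
  x / sum(x)
}

.splitLength <- function(total, k) {
  ## partition `total` into k positive integer parts, Dirichlet proportions
  if (k == 1L) return(total)
  w <- .rdirichlet1(rep(2, k))
  parts <- pmax(1L, floor(w * total))
  parts[1L] <- parts[1L] + (total - sum(parts))
  if (parts[1L] < 1L) { # pathological rounding; rebalance
    parts <- rep(floor(total / k), k)
    parts[1L] <- total - sum(parts[-1L])
  }
  parts
}

#' Construct a duplication-annotated gene tree
#'
#' @param tree An `ape` `phylo` object (rooted).
#' @param ages Numeric ages (MYA) of the internal nodes, in `phylo` internal
#'   node order (root first for trees read by [ape::read.tree()]).
#' @param events Character vector, `"duplication"` or `"speciation"`, same
#'   order as `ages`.
#' @return A [GeneTree].
#' @examples
#' tr <- ape::read.tree(text = "((g1,g2),og);")
#' geneTree(tr, ages = c(400, 167), events = c("speciation", "duplication"))
#' @export
geneTree <- function(tree, ages, events) {
  new("GeneTree", tree = tree, ages = as.numeric(ages),
      events = as.character(events))
}

.simulateTree <- function(gene_id, group, mrdWeights, dupProb) {
  ages16 <- TAXON_AGES$age
  mrd_age <- sample(ages16, 1L, prob = mrdWeights[, group])
  has_dup <- runif(1) < dupProb
  if (!has_dup) {
    tr <- ape::read.tree(text = sprintf("(%s,og1);", gene_id))
    return(geneTree(tr, ages = mrd_age, events = "speciation"))
  }
  older <- ages16[ages16 >= mrd_age]
  root_age <- if (length(older) > 1L) sample(older, 1L) else older
  add_dca <- runif(1) < 0.5
  mid <- ages16[ages16 >= mrd_age & ages16 <= root_age]
  if (add_dca && length(mid) > 1L) {
    dca_age <- sample(mid, 1L)
    ## root (speciation) > dca duplication > mrd duplication > gene
    tr <- ape::read.tree(text = sprintf("(((%s,par1),par2),og1);", gene_id))
    ## read.tree numbers internal nodes root-first on this topology
    geneTree(tr, ages = c(root_age, max(dca_age, mrd_age), mrd_age),
             events = c("speciation", "duplication", "duplication"))
  } else {
    tr <- ape::read.tree(text = sprintf("((%s,par1),og1);", gene_id))
    geneTree(tr, ages = c(root_age, mrd_age),
             events = c("speciation", "duplication"))
  }
}

.simulatePPI <- function(ids, labels, fitness_mult, m) {
  n <- length(ids)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  igraph::V(g)$name <- ids
  if (n < 2L) return(g)
  fit <- ifelse(labels[ids] == "essential", fitness_mult, 1)
  ord <- sample.int(n)          # arrival order
  deg <- numeric(n)
  from <- integer(0); to <- integer(0)
  for (t in 2:n) {
    v <- ord[t]
    prev <- ord[seq_len(t - 1L)]
    k <- min(m, t - 1L)
    w <- (deg[prev] + 1) * fit[prev]
    tgt <- prev[sample.int(t - 1L, k, prob = w)]
    deg[tgt] <- deg[tgt] + 1
    deg[v] <- deg[v] + k
    from <- c(from, rep(v, k)); to <- c(to, tgt)
  }
  igraph::add_edges(g, rbind(from, to))
}

#' Generate a labelled synthetic cohort
#'
#' Draws a two-group cohort under the generator families of
#' [cohortConfig()]: per-gene log-normal lengths, truncated-Poisson exon and
#' transcript counts, Beta GC, proteins with Dirichlet-multinomial residue
#' composition (length = longest-transcript exon length / 3, minimum 30 aa),
#' Bernoulli annotation flags, zero-inflated gamma-Poisson EST counts over
#' the 13 stages, a preferential-attachment PPI graph in which essential
#' nodes carry an attachment fitness multiplier, and per-gene
#' duplication-annotated trees rooted at the 16 taxon ages.
#'
#' @param config A [CohortConfig].
#' @param parts Which data layers to generate; any subset of
#'   `c("genes", "proteins", "expression", "ppi", "trees")`. Layers are
#'   drawn in this fixed order from one seeded stream, so a given layer is
#'   reproducible whenever the same prefix of layers is requested.
#' @return A [SyntheticCohort]; omitted layers are empty.
#' @examples
#' coh <- generateCohort(cohortConfig(nEssential = 20, nViable = 30, seed = 7),
#'                       parts = c("genes", "proteins"))
#' table(cohortLabels(coh))
#' @export
generateCohort <- function(config,
                           parts = c("genes", "proteins", "expression",
                                     "ppi", "trees")) {
  stopifnot(is(config, "CohortConfig"))
  msg <- validObject(config, test = TRUE)
  if (is.character(msg)) stop("invalid cohort configuration: ", msg[1L])
  parts <- match.arg(parts, several.ok = TRUE)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config@seed)

  nE <- config@nEssential; nV <- config@nViable; n <- nE + nV
  ids <- sprintf("gene%05d", seq_len(n))
  grp <- rep(c("essential", "viable"), c(nE, nV))
  gi <- match(grp, c("essential", "viable"))   # 1 = essential, 2 = viable
  labels <- setNames(grp, ids)

  genes <- data.frame(gene_id = character(0), gene_length = numeric(0),
                      gc = numeric(0), stringsAsFactors = FALSE)
  genes$transcripts <- list()
  proteins <- Biostrings::AAStringSet()
  annotations <- data.frame(gene_id = character(0), stringsAsFactors = FALSE)
  expr <- new("StageExpression",
              counts = matrix(integer(0), 0, 13,
                              dimnames = list(NULL, DEVELOPMENTAL_STAGES)))
  ppi <- igraph::make_empty_graph(0, directed = FALSE)
  trees <- list()
  exon_total <- integer(n)

  if ("genes" %in% parts) {
    gene_length <- pmax(200L, round(rlnorm(n, log(config@geneLengthMedian[gi]),
                                           config@geneLengthSdlog)))
    exon_total <- pmax(90L, round(rlnorm(n, log(config@exonLengthMedian[gi]),
                                         config@exonLengthSdlog)))
    exon_total <- pmin(exon_total, gene_length)
    n_exons <- .rtruncpois(n, config@exonCountMean[gi])
    n_tx <- .rtruncpois(n, config@transcriptCountMean[gi])
    gc <- rbeta(n, config@gcMean[gi] * config@gcConcentration,
                (1 - config@gcMean[gi]) * config@gcConcentration)
    tx <- vector("list", n)
    for (i in seq_len(n)) {
      main <- .splitLength(exon_total[i], min(n_exons[i], exon_total[i]))
      others <- if (n_tx[i] > 1L) {
        lapply(seq_len(n_tx[i] - 1L), function(j) {
          tot <- max(1L, floor(runif(1, 0.3, 0.95) * exon_total[i]))
          k <- max(1L, min(length(main), .rtruncpois(1L, length(main) * 0.7)))
          .splitLength(tot, min(k, tot))
        })
      } else list()
      tx[[i]] <- c(list(main), others)
    }
    genes <- data.frame(gene_id = ids, gene_length = as.numeric(gene_length),
                        gc = gc, stringsAsFactors = FALSE)
    genes$transcripts <- tx
  }

  if ("proteins" %in% parts) {
    plen <- pmax(30L, exon_total %/% 3L)
    if (!("genes" %in% parts)) # proteins without gene layer: draw lengths
      plen <- pmax(30L, round(rlnorm(n, log(config@exonLengthMedian[gi] / 3),
                                     config@exonLengthSdlog)))
    seqs <- character(n)
    alpha <- config@aaDirichletAlpha
    for (i in seq_len(n)) {
      p <- .rdirichlet1(alpha[, gi[i]])
      seqs[i] <- paste(sample(AA_STANDARD, plen[i], replace = TRUE, prob = p),
                       collapse = "")
    }
    proteins <- Biostrings::AAStringSet(setNames(seqs, ids))

    ar <- config@annotationRates
    annotations <- data.frame(gene_id = ids, stringsAsFactors = FALSE)
    for (k in seq_len(nrow(ar)))
      annotations[[ar$flag[k]]] <-
        runif(n) < c(ar$essential[k], ar$viable[k])[gi]
    ez <- config@enzymeClassRates
    cls <- c(rownames(ez), "none")
    annotations$enzyme_class <- vapply(seq_len(n), function(i) {
      pr <- c(ez[, gi[i]], 1 - sum(ez[, gi[i]]))
      sample(cls, 1L, prob = pr)
    }, character(1))
    tm_probs <- list(
      essential = c(0.525, 0.10, 0.07, 0.06, 0.05, 0.04, 0.10, rep(0.011, 5)),
      viable    = c(0.50, 0.08, 0.05, 0.04, 0.03, 0.03, 0.19, rep(0.016, 5)))
    has_tm <- runif(n) < config@tmRate[gi]
    annotations$tm_count <- ifelse(
      has_tm,
      vapply(gi, function(g) sample(1:12, 1L, prob = tm_probs[[g]]),
             numeric(1)),
      0L)
  }

  if ("expression" %in% parts) {
    ef <- config@expressedFraction
    mu <- config@expressionMean; sz <- config@expressionDispersion
    counts <- matrix(0L, n, 13, dimnames = list(ids, DEVELOPMENTAL_STAGES))
    for (j in seq_len(13L)) {
      expressed <- runif(n) < ef[j, gi]
      extra <- rnbinom(n, size = sz, mu = pmax(mu[gi] - 1, 0.01))
      counts[, j] <- as.integer(ifelse(expressed, 1 + extra, 0))
    }
    storage.mode(counts) <- "integer"
    expr <- new("StageExpression", counts = counts)
  }

  if ("ppi" %in% parts)
    ppi <- .simulatePPI(ids, labels, config@ppiFitnessMultiplier,
                        config@ppiEdgesPerNode)

  if ("trees" %in% parts) {
    trees <- lapply(seq_len(n), function(i)
      .simulateTree(ids[i], grp[i], config@mrdAgeWeights,
                    config@treeDuplicationProb))
    names(trees) <- ids
  }

  new("SyntheticCohort", genes = genes, proteins = proteins,
      annotations = annotations, expression = expr, ppi = ppi,
      trees = trees, labels = labels)
}
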