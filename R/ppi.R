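# PPI graph cleaning and the nine per-node topology scores. Degree,
# shortest-path distances, betweenness and local clustering delegate to
# igraph; the paper-literal closeness (1 / sum of distances within the
# node's component), BottleNeck (compiled BFS-tree kernel), EPC, MNC and
# DMNC are implemented here. Isolated nodes score 0 for betweenness,
# clustering and closeness, and have no defined average shortest path (NA).

#' @useDynLib essprofile, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Clean a raw interaction edge list
#'
#' Builds a canonical undirected simple graph: self-loops and duplicate
#' (order-insensitive) edges are removed and the removal counts reported.
#'
#' @param edges Two-column matrix/data frame of endpoint ids, a file path to
#'   a two-column tab-separated edge list, or a SIF file (three columns:
#'   source, relation, target).
#' @return An undirected simple `igraph`; graph attributes
#'   `self_loops_removed` and `duplicates_removed` record the cleaning.
#' @examples
#' g <- cleanGraph(rbind(c("a", "a"), c("a", "b"), c("b", "a")))
#' igraph::ecount(g)  # 1
#' @export
cleanGraph <- function(edges) {
  if (is.character(edges) && length(edges) == 1L && file.exists(edges)) {
    lines <- readLines(edges)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf != 2L & nf != 3L))
      stop("malformed edge list at line ", which(nf != 2L & nf != 3L)[1L],
           ": expected 2 (tab-separated) or 3 (SIF) fields")
    edges <- t(vapply(parts, function(p)
      if (length(p) == 3L) p[c(1L, 3L)] else p, character(2)))
  }
  edges <- as.matrix(edges)
  if (length(edges) && ncol(edges) != 2L)
    stop("edge input must have two endpoint columns")
  mode(edges) <- "character"
  if (!nrow(edges))
    return(igraph::make_empty_graph(0, directed = FALSE))
  loops <- edges[, 1L] == edges[, 2L]
  edges2 <- edges[!loops, , drop = FALSE]
  key <- paste(pmin(edges2[, 1L], edges2[, 2L]),
               pmax(edges2[, 1L], edges2[, 2L]), sep = "\r")
  dup <- duplicated(key)
  edges3 <- edges2[!dup, , drop = FALSE]
  verts <- sort(unique(as.vector(edges)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges3[, 1L], to = edges3[, 2L],
               stringsAsFactors = FALSE),
    directed = FALSE, vertices = verts)
  g <- igraph::set_graph_attr(g, "self_loops_removed", sum(loops))
  igraph::set_graph_attr(g, "duplicates_removed", sum(dup))
}

## name-sorted, 0-based, ascending adjacency list for the compiled kernel
.sortedAdjacency <- function(g) {
  nms <- sort(igraph::V(g)$name)
  g2 <- igraph::permute(g, match(igraph::V(g)$name, nms))
  el <- igraph::as_edgelist(g2, names = FALSE)
  adj <- vector("list", length(nms))
  for (i in seq_along(nms)) adj[[i]] <- integer(0)
  if (nrow(el)) {
    both <- rbind(el, el[, 2:1, drop = FALSE])
    sp <- split(both[, 2L], both[, 1L])
    for (k in names(sp)) adj[[as.integer(k)]] <- sort(unique(sp[[k]])) - 1L
  }
  list(names = nms, adj = adj)
}

#' BottleNeck scores
#'
#' For every root r, a deterministic BFS shortest-path tree T_r is built
#' (parents tie-broken to the lexicographically smallest id). A node b is a
#' bottleneck for r when at least n_r / 4 nodes of T_r route to r through b,
#' where n_r is the number of nodes of T_r and the count excludes b itself.
#' The BN score of b is the number of roots for which it is a bottleneck.
#'
#' @param g An undirected `igraph` with named vertices.
#' @return Named integer vector of BN scores.
#' @export
bottleneckScores <- function(g) {
  sa <- .sortedAdjacency(g)
  setNames(.bnScoresCpp(sa$adj), sa$names)
}

#' Edge percolation component scores
#'
#' Monte-Carlo EPC: in each of `repetitions` replicate graphs every edge is
#' kept independently with probability `retention`; the EPC of a node is
#' the replicate-average number of other nodes it remains connected to.
#' With retention 1 this equals (component size - 1); with retention 0 it
#' is 0.
#'
#' @param g An undirected `igraph` with named vertices.
#' @param repetitions Number of replicate graphs (default 100).
#' @param retention Per-edge retention probability (default 0.5).
#' @param seed Optional integer seed; the caller's RNG state is restored.
#' @return Named numeric vector of EPC scores.
#' @export
epcScores <- function(g, repetitions = 100L, retention = 0.5, seed = NULL) {
  if (repetitions < 1L) stop("repetitions must be >= 1")
  if (retention < 0 || retention > 1)
    stop("retention must be a probability")
  nms <- igraph::V(g)$name
  acc <- setNames(numeric(length(nms)), nms)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  ne <- igraph::ecount(g)
  for (i in seq_len(repetitions)) {
    keep <- runif(ne) < retention
    sub <- igraph::subgraph_from_edges(g, which(keep),
                                       delete.vertices = FALSE)
    acc <- acc + {
      comp <- igraph::components(sub)
      (comp$csize[comp$membership] - 1)
    }
  }
  acc / repetitions
}

#' Maximum neighbourhood component size and density
#'
#' `mncScore` is the node count of the largest connected component of the
#' subgraph induced by a node's neighbourhood (the node itself excluded).
#' `dmncScore` is the density variant: edges of that component divided by
#' its node count raised to `e` = 1.7; neighbourhood components with fewer
#' than two nodes or no edges score 0.
#'
#' @param g An undirected `igraph` with named vertices.
#' @param v A vertex name.
#' @param e Density exponent (1.7).
#' @return A single number.
#' @examples
#' tri <- cleanGraph(rbind(c("a", "b"), c("b", "c"), c("a", "c")))
#' mncScore(tri, "a")   # 2
#' dmncScore(tri, "a")  # 1 / 2^1.7
#' @export
mncScore <- function(g, v) {
  .mncDmnc(g, v)$mnc
}

#' @rdname mncScore
#' @export
dmncScore <- function(g, v, e = 1.7) {
  .mncDmnc(g, v, e)$dmnc
}

.mncDmnc <- function(g, v, e = 1.7) {
  nb <- igraph::neighbors(g, v)
  if (!length(nb)) return(list(mnc = 0, dmnc = 0))
  sub <- igraph::induced_subgraph(g, nb)
  comp <- igraph::components(sub)
  big <- which.max(comp$csize)
  mnc <- comp$csize[big]
  if (mnc < 2L) return(list(mnc = mnc, dmnc = 0))
  cc <- igraph::induced_subgraph(sub, which(comp$membership == big))
  E_M <- igraph::ecount(cc)
  list(mnc = mnc, dmnc = if (E_M == 0L) 0 else E_M / mnc^e)
}

#' Per-node PPI topology metrics
#'
#' Computes the nine per-node scores for every node of a cleaned PPI graph:
#' degree; average shortest path length to reachable nodes (`NA` for
#' isolated nodes); betweenness centrality normalised by (N-1)(N-2)/2 into
#' \[0, 1\]; local clustering coefficient; closeness as the literal
#' reciprocal of the sum of shortest-path lengths within the node's
#' component (set `closeness = "normalized"` for the conventional
#' (reachable nodes)/sum variant); BottleNeck; EPC; MNC; DMNC.
#'
#' @param g An undirected simple `igraph` with named vertices (see
#'   [cleanGraph()]).
#' @param epcRepetitions,epcRetention,epcSeed EPC Monte-Carlo parameters,
#'   see [epcScores()].
#' @param closeness `"reciprocal-sum"` (the literal definition) or
#'   `"normalized"`.
#' @param rawBetweenness If `TRUE`, emit unnormalised shortest-path counts
#'   instead of the \[0, 1\] normalisation.
#' @return Data frame, one row per node: `node`, `degree`, `asp`, `bc`,
#'   `cco`, `cc`, `bn`, `epc`, `mnc`, `dmnc`.
#' @examples
#' g <- cleanGraph(rbind(c("a", "b"), c("b", "c")))
#' nodeMetrics(g, epcRepetitions = 10, epcSeed = 1)
#' @export
nodeMetrics <- function(g, epcRepetitions = 100L, epcRetention = 0.5,
                        epcSeed = NULL,
                        closeness = c("reciprocal-sum", "normalized"),
                        rawBetweenness = FALSE) {
  closeness <- match.arg(closeness)
  stopifnot(igraph::is_igraph(g))
  nms <- igraph::V(g)$name
  if (is.null(nms) && igraph::vcount(g) > 0L)
    stop("graph vertices must be named")
  n <- igraph::vcount(g)
  if (n == 0L)
    return(data.frame(node = character(0), degree = integer(0),
                      asp = numeric(0), bc = numeric(0), cco = numeric(0),
                      cc = numeric(0), bn = integer(0), epc = numeric(0),
                      mnc = numeric(0), dmnc = numeric(0)))

  deg <- igraph::degree(g)
  d <- igraph::distances(g)
  fin <- is.finite(d)
  diag(fin) <- FALSE
  reach <- rowSums(fin)
  sumd <- rowSums(ifelse(fin, d, 0))
  asp <- ifelse(reach > 0, sumd / reach, NA_real_)
  bc_raw <- igraph::betweenness(g, directed = FALSE)
  bc <- if (rawBetweenness) bc_raw else {
    if (n < 3L) setNames(rep(0, n), nms)
    else bc_raw / ((n - 1) * (n - 2) / 2)
  }
  cco <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  names(cco) <- nms
  cc <- ifelse(reach > 0,
               if (closeness == "reciprocal-sum") 1 / pmax(sumd, 1e-300)
               else reach / pmax(sumd, 1e-300),
               0)
  bn <- bottleneckScores(g)[nms]
  epc <- epcScores(g, repetitions = epcRepetitions,
                   retention = epcRetention, seed = epcSeed)[nms]
  md <- lapply(nms, function(v) .mncDmnc(g, v))

  data.frame(node = nms, degree = as.integer(deg[nms]),
             asp = as.numeric(asp),
             bc = as.numeric(bc[nms]), cco = as.numeric(cco[nms]),
             cc = as.numeric(cc), bn = as.integer(bn),
             epc = as.numeric(epc),
             mnc = vapply(md, function(x) as.numeric(x$mnc), numeric(1)),
             dmnc = vapply(md, function(x) x$dmnc, numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}
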