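# Non-redundant dataset construction: global pairwise identity, similarity
# graph at an identity threshold, and removal of a small vertex set so that
# no retained pair meets the threshold.

#' Global pairwise sequence identity
#'
#' Needleman-Wunsch global alignment with affine gaps (BLOSUM62, gap open
#' 10, gap extension 0.5); identity is 100 x matches / alignment length
#' (gaps count in the denominator), a conservative convention that yields
#' more similarity edges and stricter culling than a shorter-sequence
#' denominator.
#'
#' @param seq_a,seq_b Amino-acid strings.
#' @return Identity percentage in \[0, 100\]; symmetric in its arguments.
#' @examples
#' pairwiseIdentity("ACDEF", "ACDEG")  # 80
#' @export
pairwiseIdentity <- function(seq_a, seq_b) {
  if (!nzchar(seq_a) || !nzchar(seq_b))
    stop("sequences must be non-empty")
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5, type = "global")
  100 * Biostrings::nmatch(al) / Biostrings::nchar(al)
}

#' Build a similarity graph over sequences
#'
#' Aligns all pairs and connects two sequences whenever their global
#' identity is at or above `threshold`. Thresholds below 20% are refused:
#' below that level sequence identity no longer implies redundancy, so
#' culled sets are not constructed there.
#'
#' @param sequences Named character vector or [Biostrings::AAStringSet].
#' @param threshold Identity threshold in percent, in \[20, 100\].
#' @return An undirected `igraph` whose vertices are the sequence ids and
#'   whose edges carry an `identity` attribute.
#' @export
buildSimilarityGraph <- function(sequences, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 100)
    stop("threshold must be a single percentage in (0, 100]")
  if (threshold < 20)
    stop("thresholds below 20% identity are not supported: ",
         "at that level identity no longer implies redundancy")
  seqs <- if (is.character(sequences)) sequences
          else as.character(sequences)   # XStringSet keeps its names
  ids <- names(seqs)
  if (is.null(ids) || anyDuplicated(ids))
    stop("sequences must carry unique names")
  n <- length(seqs)
  from <- character(0); to <- character(0); ident <- numeric(0)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        pid <- pairwiseIdentity(seqs[i], seqs[j])
        if (pid >= threshold) {
          from <- c(from, ids[i]); to <- c(to, ids[j])
          ident <- c(ident, pid)
        }
      }
    }
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, identity = ident,
               stringsAsFactors = FALSE),
    directed = FALSE, vertices = ids)
  g <- igraph::set_graph_attr(g, "threshold", threshold)
  g
}

## exact maximum independent set by exhaustive search over vertex subsets,
## scanning larger sets first; vertices indexed 1..n, adj = logical matrix
.exactMIS <- function(adj) {
  n <- nrow(adj)
  if (n == 0L) return(integer(0))
  best <- integer(0)
  ## enumerate subsets via bit masks
  for (mask in seq_len(2^n) - 1L) {
    members <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    if (length(members) <= length(best)) next
    if (length(members) < 2L || !any(adj[members, members])) best <- members
  }
  best
}

.greedyCullComponent <- function(g) {
  ## iteratively delete the max-degree vertex (ties: lexicographically
  ## smallest name) until no edge remains; returns retained names
  while (igraph::ecount(g) > 0L) {
    deg <- igraph::degree(g)
    cand <- names(deg)[deg == max(deg)]
    g <- igraph::delete_vertices(g, sort(cand)[1L])
  }
  igraph::V(g)$name
}

#' Cull a similarity graph to an independent set
#'
#' Removes a set of sequences so that no retained pair meets the identity
#' threshold: connected components with at most `exactLimit` vertices are
#' solved exactly for a maximum independent set; larger components are
#' culled greedily by repeatedly removing the highest-degree vertex
#' (ties broken to the lexicographically smallest id).
#'
#' @param graph A similarity graph from [buildSimilarityGraph()] (any
#'   undirected `igraph` with named vertices works).
#' @param exactLimit Largest component size solved exhaustively.
#' @return A list with `retained` and `removed` (character vectors
#'   partitioning the vertex ids) and `threshold` (taken from the graph
#'   attribute when present).
#' @examples
#' g <- igraph::make_graph(~ a - b)
#' cullRedundant(g)$removed  # one of a, b
#' @export
cullRedundant <- function(graph, exactLimit = 12L) {
  stopifnot(igraph::is_igraph(graph))
  ids <- igraph::V(graph)$name
  if (is.null(ids)) stop("graph vertices must be named")
  comps <- igraph::components(graph)
  retained <- character(0)
  for (ci in seq_len(comps$no)) {
    members <- ids[comps$membership == ci]
    sub <- igraph::induced_subgraph(graph, members)
    if (igraph::ecount(sub) == 0L) {
      retained <- c(retained, members)
    } else if (length(members) <= exactLimit) {
      members <- sort(members)
      sub <- igraph::induced_subgraph(graph, members)
      adj <- as.matrix(igraph::as_adjacency_matrix(sub)) > 0
      adj <- adj[members, members, drop = FALSE]
      keep <- .exactMIS(adj)
      retained <- c(retained, members[keep])
    } else {
      retained <- c(retained, .greedyCullComponent(sub))
    }
  }
  retained <- sort(retained)
  list(retained = retained,
       removed = sort(setdiff(ids, retained)),
       threshold = igraph::graph_attr(graph, "threshold") %||% NA_real_)
}

#' One-step non-redundant set construction
#'
#' Convenience wrapper: build the similarity graph over `sequences` at
#' `threshold` and cull it.
#'
#' @inheritParams buildSimilarityGraph
#' @param exactLimit Passed to [cullRedundant()].
#' @return The [cullRedundant()] result.
#' @export
cullSequences <- function(sequences, threshold, exactLimit = 12L) {
  cullRedundant(buildSimilarityGraph(sequences, threshold),
                exactLimit = exactLimit)
}
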