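# Independent brute-force oracles. These deliberately avoid the package's
# algorithms: centralities come from exhaustive simple-path enumeration,
# independent sets from subset search, and Mann-Whitney p-values from
# direct enumeration over group assignments.

## all simple paths between a and b in an adjacency matrix; returns a list
## of vertex index vectors
all_simple_paths_bf <- function(adj, a, b) {
  n <- nrow(adj)
  out <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == b) { out[[length(out) + 1L]] <<- path; return(invisible()) }
    for (w in which(adj[v, ] == 1)) {
      if (!(w %in% path)) walk(c(path, w))
    }
  }
  walk(a)
  out
}

## exhaustive centralities for an undirected simple graph given as a 0/1
## adjacency matrix with dimnames
oracle_centralities <- function(adj) {
  n <- nrow(adj)
  nms <- rownames(adj)
  dist <- matrix(Inf, n, n)
  diag(dist) <- 0
  nshort <- matrix(0, n, n)          # number of shortest paths
  through <- array(0, c(n, n, n))    # shortest b-c paths through v (interior)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a >= b) next
    paths <- all_simple_paths_bf(adj, a, b)
    if (!length(paths)) next
    lens <- vapply(paths, length, integer(1)) - 1L
    d <- min(lens)
    sp <- paths[lens == d]
    dist[a, b] <- dist[b, a] <- d
    nshort[a, b] <- nshort[b, a] <- length(sp)
    for (p in sp) {
      interior <- setdiff(p, c(a, b))
      through[a, b, interior] <- through[a, b, interior] + 1
    }
  }
  degree <- rowSums(adj)
  asp <- vapply(seq_len(n), function(v) {
    dd <- dist[v, -v]; dd <- dd[is.finite(dd)]
    if (!length(dd)) NA_real_ else mean(dd)
  }, numeric(1))
  bc_raw <- vapply(seq_len(n), function(v) {
    s <- 0
    for (a in seq_len(n)) for (b in seq_len(n)) {
      if (a >= b || a == v || b == v) next
      if (nshort[a, b] > 0) s <- s + through[a, b, v] / nshort[a, b]
    }
    s
  }, numeric(1))
  bc <- if (n < 3) rep(0, n) else bc_raw / ((n - 1) * (n - 2) / 2)
  cc <- vapply(seq_len(n), function(v) {
    dd <- dist[v, -v]; dd <- dd[is.finite(dd)]
    if (!length(dd)) 0 else 1 / sum(dd)
  }, numeric(1))
  cco <- vapply(seq_len(n), function(v) {
    nb <- which(adj[v, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    e <- sum(adj[nb, nb]) / 2
    2 * e / (k * (k - 1))
  }, numeric(1))
  data.frame(node = nms, degree = degree, asp = asp, bc = bc, cco = cco,
             cc = cc, stringsAsFactors = FALSE)
}

## seeded random simple graph as adjacency matrix with letter names
random_adjacency <- function(n, p = 0.35) {
  adj <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (runif(1) < p) adj[i, j] <- adj[j, i] <- 1L
  }
  dimnames(adj) <- list(letters[seq_len(n)], letters[seq_len(n)])
  adj
}

adjacency_to_igraph <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}

## exhaustive maximum independent set size
oracle_mis_size <- function(adj) {
  n <- nrow(adj)
  best <- 0L
  for (mask in seq_len(2^n) - 1L) {
    members <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    if (length(members) <= best) next
    if (length(members) < 2L || !any(adj[members, members] == 1))
      best <- length(members)
  }
  best
}

## two-tailed Mann-Whitney p by enumeration; U counted as concordant pairs
## (x > y) + half ties, enumerated over every assignment of pooled values
oracle_mwu_p <- function(a, b) {
  u_pairs <- function(x, y) {
    s <- 0
    for (xi in x) for (yj in y) {
      s <- s + (xi > yj) + 0.5 * (xi == yj)
    }
    s
  }
  pool <- c(a, b)
  na <- length(a); nb <- length(b)
  u_obs <- u_pairs(a, b)
  sets <- combn(length(pool), na)
  lo_obs <- min(u_obs, na * nb - u_obs)
  cnt <- 0L
  for (k in seq_len(ncol(sets))) {
    x <- pool[sets[, k]]; y <- pool[-sets[, k]]
    u <- u_pairs(x, y)
    if (min(u, na * nb - u) <= lo_obs + 1e-9) cnt <- cnt + 1L
  }
  min(1, cnt / ncol(sets))
}

## hypergeometric upper tail by direct summation
oracle_hyper_p <- function(k, K, N, nq) {
  sum(vapply(k:min(K, nq), function(i)
    choose(K, i) * choose(N - K, nq - i), numeric(1))) / choose(N, nq)
}
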