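# PPI graph cleaning and the nine topology scores.

path5 <- function() cleanGraph(rbind(c("a", "b"), c("b", "c"),
                                     c("c", "d"), c("d", "e")))
star4 <- function() cleanGraph(rbind(c("hub", "l1"), c("hub", "l2"),
                                     c("hub", "l3"), c("hub", "l4")))
triangle <- function() cleanGraph(rbind(c("a", "b"), c("b", "c"),
                                        c("a", "c")))

test_that("graph cleaning drops self-loops and duplicate edges", {
  g <- cleanGraph(rbind(c("a", "a"), c("a", "b"), c("b", "a")))
  expect_equal(igraph::ecount(g), 1L)
  expect_equal(igraph::graph_attr(g, "self_loops_removed"), 1L)
  expect_equal(igraph::graph_attr(g, "duplicates_removed"), 1L)
  expect_equal(igraph::vcount(cleanGraph(matrix(character(0), 0, 2))), 0L)

  ## 10 random pairs with 3 duplicates -> 7 edges
  e <- rbind(c("a","b"), c("c","d"), c("e","f"), c("a","c"), c("b","d"),
             c("d","e"), c("f","a"), c("b","a"), c("d","c"), c("e","d"))
  expect_equal(igraph::ecount(cleanGraph(e)), 7L)

  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("a\tb", "b\tpp\tc", "oops"), f)
  expect_error(cleanGraph(f), "line 3")
  writeLines(c("a\tb", "b\tpp\tc"), f)
  expect_equal(igraph::ecount(cleanGraph(f)), 2L)
})

test_that("hand-computed metrics on small motifs are reproduced", {
  m <- nodeMetrics(cleanGraph(rbind(c("a", "b"), c("b", "c"))),
                   epcRepetitions = 5, epcSeed = 1)
  rownames(m) <- m$node
  expect_equal(m["b", "degree"], 2L)
  expect_equal(m["b", "asp"], 1)
  expect_equal(m["b", "bc"], 1)      # only a-c path routes through b
  expect_equal(m["b", "cc"], 0.5)    # 1 / (1 + 1)
  expect_equal(m["a", "bc"], 0)

  s <- nodeMetrics(star4(), epcRepetitions = 5, epcSeed = 1)
  rownames(s) <- s$node
  expect_equal(s["hub", "asp"], 1)
  expect_equal(s["l1", "asp"], 1.75)     # (1 + 2 + 2 + 2) / 4
  expect_equal(s["hub", "cc"], 0.25)     # 1 / 4
  expect_equal(s["hub", "cco"], 0)
  expect_equal(s["hub", "mnc"], 1)       # leaves are mutually unconnected
  expect_equal(s["hub", "dmnc"], 0)

  tri <- nodeMetrics(triangle(), epcRepetitions = 5, epcSeed = 1)
  expect_equal(tri$cco, rep(1, 3))
  expect_equal(tri$mnc, rep(2, 3))
  expect_equal(tri$dmnc, rep(1 / 2^1.7, 3), tolerance = 1e-12)
  expect_equal(tri$bn, rep(0L, 3))   # strict n/4 with self excluded

  ## K4: no intermediaries anywhere
  k4 <- cleanGraph(t(combn(c("a", "b", "c", "d"), 2)))
  mk4 <- nodeMetrics(k4, epcRepetitions = 5, epcSeed = 1)
  expect_equal(mk4$bc, rep(0, 4))
  ## K4 minus one edge: nodes incident to the gap have cco 2/3
  k4e <- cleanGraph(rbind(c("a","b"), c("a","c"), c("a","d"),
                          c("b","c"), c("b","d")))
  mke <- nodeMetrics(k4e, epcRepetitions = 5, epcSeed = 1)
  rownames(mke) <- mke$node
  expect_equal(mke["a", "cco"], 2/3)  # a sees the c-d gap: 2 of 3 pairs
  expect_equal(mke["c", "cco"], 1)    # c's two neighbours are connected
})

test_that("isolated nodes follow the zero conventions", {
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(c("iso", "x", "y")) + igraph::edges(c("x", "y"))
  m <- nodeMetrics(g, epcRepetitions = 5, epcSeed = 1)
  rownames(m) <- m$node
  expect_equal(m["iso", "degree"], 0L)
  expect_true(is.na(m["iso", "asp"]))
  expect_equal(m["iso", "bc"], 0)
  expect_equal(m["iso", "cco"], 0)
  expect_equal(m["iso", "cc"], 0)
  expect_equal(m["iso", "bn"], 0L)
  expect_equal(m["iso", "epc"], 0)
  expect_equal(m["iso", "mnc"], 0)
  expect_equal(m["iso", "dmnc"], 0)
  ## edge pair: closeness 1 by the literal reciprocal-sum definition
  expect_equal(m["x", "cc"], 1)
})

test_that("BottleNeck follows the deterministic BFS-tree definition", {
  bn <- bottleneckScores(path5())
  expect_gte(unname(bn["c"]), 2)   # roots a and e at least
  expect_equal(unname(bn["c"]), 4L)
  expect_identical(bn, bottleneckScores(path5()))
  ## mnc never exceeds degree on connected nodes
  set.seed(12)
  for (i in 1:10) {
    adj <- random_adjacency(sample(4:8, 1), p = 0.45)
    g <- adjacency_to_igraph(adj)
    m <- nodeMetrics(g, epcRepetitions = 3, epcSeed = 1)
    pos <- m$degree > 0
    expect_true(all(m$mnc[pos] <= m$degree[pos]))
  }
})

test_that("EPC has the right degenerate limits and Monte-Carlo accuracy", {
  g <- cleanGraph(rbind(c("a", "b"), c("b", "c")))
  full <- epcScores(g, repetitions = 3, retention = 1, seed = 1)
  expect_equal(unname(full), c(2, 2, 2))  # component size - 1
  none <- epcScores(g, repetitions = 3, retention = 0, seed = 1)
  expect_equal(unname(none), c(0, 0, 0))

  ## single edge, retention 0.5: E[EPC(a)] = 0.5, within 3 SE at n = 10000
  e1 <- cleanGraph(rbind(c("a", "b")))
  epc <- epcScores(e1, repetitions = 10000, retention = 0.5, seed = 42)
  se <- sqrt(0.25 / 10000)
  expect_lt(abs(epc[["a"]] - 0.5), 3 * se)

  ## two-edge path: E[EPC(b)] = 2p, E[EPC(a)] = p + p^2
  p2 <- epcScores(g, repetitions = 10000, retention = 0.5, seed = 7)
  expect_lt(abs(p2[["b"]] - 1.0), 3 * sqrt(0.5 / 10000))
  expect_lt(abs(p2[["a"]] - 0.75), 3 * sqrt(0.6875 / 10000))
})

test_that("centralities agree with the brute-force path-enumeration oracle", {
  set.seed(99)
  for (i in 1:60) {
    n <- sample(4:8, 1)
    adj <- random_adjacency(n)
    g <- adjacency_to_igraph(adj)
    got <- nodeMetrics(g, epcRepetitions = 2, epcSeed = 1)
    want <- oracle_centralities(adj)
    expect_equal(got$degree, as.integer(want$degree))
    expect_equal(got$asp, want$asp, tolerance = 1e-12)
    expect_equal(got$bc, want$bc, tolerance = 1e-12)
    expect_equal(got$cco, want$cco, tolerance = 1e-12)
    expect_equal(got$cc, want$cc, tolerance = 1e-12)
  }
})

test_that("metrics other than BN are invariant under relabelling", {
  set.seed(55)
  adj <- random_adjacency(7, p = 0.4)
  g <- adjacency_to_igraph(adj)
  perm <- sample(rownames(adj))
  adj2 <- adj[perm, perm]
  g2 <- adjacency_to_igraph(adj2)
  m1 <- nodeMetrics(g, epcRepetitions = 2, epcSeed = 1)
  m2 <- nodeMetrics(g2, epcRepetitions = 2, epcSeed = 1)
  rownames(m1) <- m1$node; rownames(m2) <- m2$node
  for (col in c("degree", "asp", "bc", "cco", "cc", "mnc", "dmnc"))
    expect_equal(m1[rownames(adj), col], m2[rownames(adj), col],
                 tolerance = 1e-12, ignore_attr = TRUE)
})
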