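# Random-network generation and degree-preserving shuffle scripts.

test_that("generators are seeded and deterministic", {
  for (model in c("er", "ws", "ba")) {
    g1 <- generateNetwork(model, size = 200, degree = 8, seed = 5)
    g2 <- generateNetwork(model, size = 200, degree = 8, seed = 5)
    expect_identical(sort(graphEdgeKeys(g1)), sort(graphEdgeKeys(g2)))
    g3 <- generateNetwork(model, size = 200, degree = 8, seed = 6)
    expect_false(identical(sort(graphEdgeKeys(g1)), sort(graphEdgeKeys(g3))))
  }
})

test_that("realised average degree tracks the target at scale", {
  for (model in c("er", "ws", "ba")) {
    g <- generateNetwork(model, size = 1000, degree = 10, seed = 1)
    avg <- 2 * igraph::ecount(g) / igraph::vcount(g)
    expect_lt(abs(avg - 10) / 10, 0.1)
    expect_true(igraph::is_simple(g))
  }
})

test_that("BA edge count follows the growth rule", {
  g <- generateNetwork("ba", size = 100, degree = 10, seed = 2)
  m <- 5
  # each arriving node attaches min(existing, m) edges
  expect_equal(igraph::ecount(g), sum(pmin(seq_len(99), m)))
})

test_that("infeasible configurations are rejected", {
  expect_error(generateNetwork("ba", size = 3, degree = 2), "at least 4")
  expect_error(generateNetwork("er", size = 10, degree = 12), "smaller")
  expect_error(shuffleScript(demoGraph(), nOps = 6, seed = 1), "divisible")
})

test_that("shuffle scripts preserve degrees after every complete shuffle", {
  for (model in c("er", "ws", "ba")) {
    g <- generateNetwork(model, size = 100, degree = 6, seed = 3)
    sc <- shuffleScript(g, nOps = 40, seed = 4)
    expect_equal(nrow(sc), 40)
    deg0 <- igraph::degree(g)
    cur <- g
    for (s in seq_len(10)) {
      chunk <- sc[(4 * s - 3):(4 * s), , drop = FALSE]
      class(chunk) <- c("editScript", "data.frame")
      cur <- applyEditScript(cur, chunk)  # validates op consistency too
      expect_equal(igraph::degree(cur)[names(deg0)], deg0)
      expect_equal(igraph::ecount(cur), igraph::ecount(g))
      expect_true(igraph::is_simple(cur))
    }
  }
})

test_that("zero-length shuffle scripts are empty", {
  expect_equal(nrow(shuffleScript(demoGraph(), 0, seed = 1)), 0)
})

test_that("4-cycle shuffles reject existing replacements, keep diagonals", {
  cyc <- graphFromEdges(c("a", "b", "c", "d"), c("b", "c", "d", "a"))
  # brute force over the 4-cycle: rewirings that reproduce cycle edges are
  # rejected, so the only valid shuffles create the two diagonals
  sc <- shuffleScript(cyc, 4, seed = 1)
  out <- applyEditScript(cyc, sc)
  # one node-disjoint cycle pair is rewired into the two diagonals; the
  # other pair survives untouched
  expect_true(all(c("a|c", "b|d") %in% graphEdgeKeys(out)))
  expect_equal(igraph::ecount(out), 4)
  expect_equal(igraph::degree(out)[c("a", "b", "c", "d")],
               igraph::degree(cyc)[c("a", "b", "c", "d")])
})

test_that("graphs with no node-disjoint edge pair cannot be shuffled", {
  star <- graphFromEdges(c("x", "x", "x"), c("p", "q", "r"))
  expect_error(shuffleScript(star, 4, seed = 1, maxTries = 50),
               "no valid degree-preserving shuffle")
})

test_that("shuffle scripts apply cleanly to dynamic counters across seeds", {
  for (seed in 1:3) {
    g <- generateNetwork("er", size = 60, degree = 6, seed = seed)
    sc <- shuffleScript(g, 40, seed = seed + 50)
    ctr <- dynamicMotifCounter(g, motif("path2"))
    expect_no_error(applyEditScript(ctr, sc))
  }
})
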