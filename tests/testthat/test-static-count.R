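# Static enumeration (F1), the overlap graph, and the min-degree greedy
# (F2 edge-disjoint / F3 node-disjoint).

test_that("triangle counting on the demo graph matches the worked example", {
  g <- demoGraph()
  res <- motifCount(g, motif("triangle"), f3 = TRUE, embeddings = TRUE)
  expect_equal(res$f1, 4)
  expect_equal(res$f2, 2)
  expect_equal(res$f3, 1)
  expect_same_embeddings(res$embeddings, demoTriangles())
})

test_that("the demo overlap graph has the two expected conflicts", {
  emb <- enumerateEmbeddings(demoGraph(), motif("triangle"))
  og <- overlapGraph(emb, mode = "edge")
  expect_equal(igraph::vcount(og), 4)
  expect_equal(igraph::ecount(og), 2)
  # the overlapping pairs share (a,e) and (a,d) respectively
  pairs <- igraph::as_edgelist(og)
  shared <- vapply(seq_len(nrow(pairs)), function(i) {
    intersect(emb[as.integer(pairs[i, 1]), ], emb[as.integer(pairs[i, 2]), ])
  }, character(1))
  expect_setequal(shared, c("a|e", "a|d"))
  # greedy on the explicit overlap graph gives F2 = 2
  expect_length(greedyDisjoint(og), 2)
  # node-sharing conflicts: all four triangles meet at the hub
  ogn <- overlapGraph(emb, mode = "node")
  expect_equal(igraph::ecount(ogn), 6)
  expect_length(greedyDisjoint(ogn), 1)
})

test_that("K4 counts: 4 triangles (F2 = 1) and 12 three-edge paths", {
  k4 <- graphFromEdges(c("a", "a", "a", "b", "b", "c"),
                       c("b", "c", "d", "c", "d", "d"))
  res <- motifCount(k4, motif("triangle"))
  expect_equal(res$f1, 4)
  expect_equal(res$f2, exactDisjointMax(
    enumerateEmbeddings(k4, motif("triangle")), "edge"))
  expect_equal(res$f2, 1)
  # brute-force-derived F1 for the 3-edge path in K4
  expect_equal(motifCount(k4, motif("path3"))$f1,
               nrow(bruteEmbeddings(k4, motif("path3"))))
  # every pair of K4 triangles shares an edge: complete overlap graph
  og <- overlapGraph(enumerateEmbeddings(k4, motif("triangle")))
  expect_equal(igraph::ecount(og), 6)
})

test_that("degenerate hosts give empty embedding sets", {
  empty <- graphFromEdges(character(0), character(0), nodes = c("a", "b"))
  expect_equal(motifCount(empty, motif("path2"))$f1, 0)
  expect_equal(motifCount(empty, motif("path2"))$f2, 0)
  expect_equal(nrow(enumerateEmbeddings(empty, motif("triangle"))), 0)
})

test_that("enumeration equals the exhaustive oracle on random graphs", {
  motifs <- c(basicMotifs(),
              list(path4 = motif(rbind(c("1", "2"), c("2", "3"),
                                       c("3", "4"), c("4", "5")), "path4"),
                   square = motif(rbind(c("1", "2"), c("2", "3"),
                                        c("3", "4"), c("4", "1")), "square")))
  for (seed in 1:6) {
    g <- smallRandomGraph(8, 0.25, seed)
    if (igraph::ecount(g) > 12) next
    for (m in motifs) {
      expect_same_embeddings(enumerateEmbeddings(g, m), bruteEmbeddings(g, m))
    }
  }
})

test_that("greedy sets are valid, maximal, and bounded by the exact optimum", {
  for (seed in 1:8) {
    g <- smallRandomGraph(9, 0.3, seed)
    for (mode in c("edge", "node")) {
      m <- motif("triangle")
      emb <- enumerateEmbeddings(g, m)
      if (nrow(emb) == 0 || nrow(emb) > 18) next
      og <- overlapGraph(emb, mode = mode)
      sel <- greedyDisjoint(og)
      adj <- conflictAdj(emb, mode)
      # independent set
      if (length(sel) > 1) {
        expect_false(any(adj[sel, sel]))
      }
      # maximal: every excluded embedding conflicts with a selected one
      for (i in setdiff(seq_len(nrow(emb)), sel)) {
        expect_true(any(adj[i, sel]))
      }
      # never exceeds the exact maximum independent set
      expect_lte(length(sel), exactDisjointMax(emb, mode))
    }
  }
})

test_that("greedy in the engine and the explicit R overlap-graph greedy agree", {
  for (seed in 1:6) {
    g <- smallRandomGraph(10, 0.3, seed)
    for (mname in c("path2", "triangle", "path3")) {
      m <- motif(mname)
      res <- motifCount(g, m, embeddings = TRUE)
      og <- overlapGraph(res$embeddings)
      expect_equal(sort(res$f2Members), greedyDisjoint(og),
                   info = paste(seed, mname))
    }
  }
})

test_that("F3 <= F2 <= F1 on varied inputs", {
  for (seed in 1:6) {
    g <- smallRandomGraph(12, 0.25, seed)
    for (m in basicMotifs()) {
      res <- motifCount(g, m, f3 = TRUE)
      expect_lte(res$f3, res$f2)
      expect_lte(res$f2, res$f1)
    }
  }
})
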