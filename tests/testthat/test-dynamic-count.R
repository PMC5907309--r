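# Incremental F1/F2 maintenance: exactness of F1, the deletion-repair and
# insertion-admission rules for F2, and store consistency.

test_that("initialisation reproduces the static counts", {
  g <- demoGraph()
  ctr <- dynamicMotifCounter(g, motif("triangle"))
  expect_equal(f1Count(ctr), 4)
  expect_equal(f2Count(ctr), 2)
  expect_same_embeddings(liveEmbeddings(ctr), demoTriangles())
  # members are the worked-example pair {S1, S3}
  expect_same_embeddings(f2Members(ctr),
                         rbind(c("a|b", "a|e", "b|e"),
                               c("a|c", "a|d", "c|d")))

  empty <- graphFromEdges(character(0), character(0), nodes = "a")
  ctr0 <- dynamicMotifCounter(empty, motif("triangle"))
  expect_equal(f1Count(ctr0), 0)
  expect_equal(f2Count(ctr0), 0)
})

test_that("deleting (a,e) destroys two triangles and loses one F2 member", {
  ctr <- dynamicMotifCounter(demoGraph(), motif("triangle"))
  applyEdit(ctr, "-", "a", "e")
  expect_equal(f1Count(ctr), 2)
  # X = S1 lost; its only neighbour S2 died too, so no replacement exists
  expect_equal(f2Count(ctr), 1)
  # brute force on the residual graph: the optimum is also 1
  g2 <- applyEdit(demoGraph(), "-", "a", "e")
  expect_equal(exactDisjointMax(bruteEmbeddings(g2, motif("triangle"))), 1)
})

test_that("deleting (b,e) repairs the F2 set with the freed neighbour", {
  ctr <- dynamicMotifCounter(demoGraph(), motif("triangle"))
  applyEdit(ctr, "-", "b", "e")
  expect_equal(f1Count(ctr), 3)
  # S1 dies but S2 = {(a,e),(a,f),(e,f)} becomes free and replaces it
  expect_equal(f2Count(ctr), 2)
  expect_true(paste(c("a|e", "a|f", "e|f"), collapse = ";") %in%
                apply(f2Members(ctr), 1, function(r) paste(sort(r), collapse = ";")))
})

test_that("inserting (c,g) creates two triangles but no free F2 candidate", {
  ctr <- dynamicMotifCounter(demoGraph(), motif("triangle"))
  applyEdit(ctr, "+", "c", "g")
  expect_equal(f1Count(ctr), 6)
  expect_equal(f2Count(ctr), 2)
  got <- liveEmbeddings(ctr)
  expect_same_embeddings(got, rbind(demoTriangles(),
                                    c("a|c", "a|g", "c|g"),
                                    c("c|d", "c|g", "d|g")))
  # the optimum over all six embeddings is still 2
  expect_equal(exactDisjointMax(got), 2)
})

test_that("insertion between fresh nodes and no-op edits change nothing", {
  ctr <- dynamicMotifCounter(demoGraph(), motif("triangle"))
  applyEdit(ctr, "+", "y", "z")
  expect_equal(f1Count(ctr), 4)
  expect_equal(f2Count(ctr), 2)
  applyEdit(ctr, "-", "y", "z")
  expect_equal(f1Count(ctr), 4)
  expect_equal(f2Count(ctr), 2)
})

test_that("a 2-path counter picks up embeddings sharing the bridge edge", {
  g <- graphFromEdges(c("a", "c"), c("b", "d"))
  ctr <- dynamicMotifCounter(g, motif("path2"))
  expect_equal(f1Count(ctr), 0)
  applyEdit(ctr, "+", "b", "c")
  expect_equal(f1Count(ctr), 2)   # {ab,bc} and {bc,cd}
  expect_equal(f2Count(ctr), 1)   # both share (b,c)
})

test_that("delete-then-reinsert restores F1 exactly (and F2 here)", {
  ctr <- dynamicMotifCounter(demoGraph(), motif("triangle"))
  tl <- applyEditScript(ctr, editScript(c("-", "+"), c("a", "a"), c("e", "e")))
  expect_equal(nrow(tl), 2)
  expect_equal(tl$f1, c(2, 4))
  expect_equal(tl$f2[2], 2)
  expect_same_embeddings(liveEmbeddings(ctr), demoTriangles())
})

test_that("script-consistency errors are raised with their step", {
  ctr <- dynamicMotifCounter(demoGraph(), motif("triangle"))
  expect_error(applyEdit(ctr, "-", "c", "g"), "script-consistency")
  expect_error(applyEdit(ctr, "+", "a", "b"), "script-consistency")
  sc <- editScript(c("-", "-"), c("a", "b"), c("b", "e"))
  sc2 <- editScript(c("-", "-"), c("a", "a"), c("b", "b"))
  expect_error(applyEditScript(dynamicMotifCounter(demoGraph(),
                                                   motif("triangle")), sc2))
  tl <- applyEditScript(dynamicMotifCounter(demoGraph(), motif("triangle")), sc)
  expect_equal(nrow(tl), 2)
})

test_that("empty scripts leave the state untouched", {
  ctr <- dynamicMotifCounter(demoGraph(), motif("path2"))
  before <- f1Count(ctr)
  tl <- applyEditScript(ctr, editScript())
  expect_equal(nrow(tl), 0)
  expect_equal(f1Count(ctr), before)
})

test_that("dynamic store equals static enumeration after random scripts", {
  for (seed in 1:4) {
    g <- smallRandomGraph(25, 0.18, seed)
    sc <- shuffleScript(g, 60, seed = seed + 100)
    for (m in basicMotifs()) {
      ctr <- dynamicMotifCounter(g, m)
      applyEditScript(ctr, sc)
      gFinal <- applyEditScript(g, sc)
      expect_same_embeddings(liveEmbeddings(ctr),
                             enumerateEmbeddings(gFinal, m))
      expect_equal(f1Count(ctr), motifCount(gFinal, m)$f1)
    }
  }
})

test_that("F2 members stay a valid, live, edge-disjoint set at every step", {
  for (seed in 1:3) {
    g <- smallRandomGraph(20, 0.2, seed)
    sc <- shuffleScript(g, 40, seed = seed + 7)
    ctr <- dynamicMotifCounter(g, motif("triangle"))
    for (i in seq_len(nrow(sc))) {
      applyEdit(ctr, sc$op[i], sc$u[i], sc$v[i])
      keys <- liveEmbeddings(ctr)
      mem <- keys[attr(keys, "member"), , drop = FALSE]
      expect_equal(nrow(mem), f2Count(ctr))
      # pairwise edge-disjoint
      expect_false(anyDuplicated(as.vector(mem)) > 0)
      # every member is a live embedding of the current graph
      expect_same_embeddings(keys,
                             enumerateEmbeddings(currentGraph(ctr),
                                                 motif("triangle")))
    }
  }
})

test_that("seeded random tie-breaking is reproducible and valid", {
  g <- smallRandomGraph(20, 0.25, seed = 3)
  run <- function() {
    set.seed(99)
    ctr <- dynamicMotifCounter(g, motif("triangle"), tieBreak = "random")
    applyEditScript(ctr, shuffleScript(g, 20, seed = 5))
    c(f1Count(ctr), f2Count(ctr))
  }
  a <- run(); b <- run()
  expect_equal(a, b)
  st <- motifCount(applyEditScript(g, shuffleScript(g, 20, seed = 5)),
                   motif("triangle"))
  expect_equal(a[1], st$f1)
})
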