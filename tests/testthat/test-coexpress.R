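# Co-expression network construction and network diffing.

test_that("pearsonMatrix handles exact relations and degenerate genes", {
  expr <- rbind(g1 = c(1, 2, 3), g2 = c(2, 4, 6), g3 = c(3, 2, 1),
                flat = c(5, 5, 5))
  pm <- pearsonMatrix(expr)
  expect_equal(pm["g1", "g1"], 1)
  expect_equal(pm["g1", "g2"], 1)
  expect_equal(pm["g1", "g3"], -1)
  expect_true(all(is.na(pm["flat", c("g1", "g2", "g3")])))
  expect_true(all(pm[!is.na(pm)] >= -1 & pm[!is.na(pm)] <= 1))
  expect_error(pearsonMatrix(expr[, 1:2]), "3 samples")
})

# build two tiny expression matrices whose gene-pair correlations are
# controlled exactly through shared/opposed profiles plus tiny tweaks
.pairExpr <- function(rUV_primary, rUV_secondary) {
  base <- c(1, 2, 3, 4, 5, 6)
  mk <- function(r) {
    # mix a shared profile with an orthogonal contrast to dial correlation
    ortho <- c(1, -2, 1, 1, -2, 1)  # zero-mean, orthogonal to centred base
    w <- sqrt((1 - r^2))
    rbind(u = base / stats::sd(base),
          v = r * base / stats::sd(base) + w * ortho / stats::sd(ortho))
  }
  list(primary = mk(rUV_primary), secondary = mk(rUV_secondary))
}

test_that("the stringent/relaxed two-condition rule matches its truth table", {
  # (1) primary 0.97 -> edge, whatever the secondary says
  e <- .pairExpr(0.97, 0.10)
  g <- buildCoexpressionNetwork(e$primary, e$secondary)
  expect_true("u|v" %in% graphEdgeKeys(g))
  # (2) primary 0.80, secondary 0.96 -> edge via the relaxed path
  e <- .pairExpr(0.80, 0.96)
  g <- buildCoexpressionNetwork(e$primary, e$secondary)
  expect_true("u|v" %in% graphEdgeKeys(g))
  # primary 0.70, secondary 0.99 -> no edge (relaxed test fails)
  e <- .pairExpr(0.70, 0.99)
  g <- buildCoexpressionNetwork(e$primary, e$secondary)
  expect_false("u|v" %in% graphEdgeKeys(g))
  # negative correlation never makes an edge, even if perfectly strong
  e <- .pairExpr(-0.99, -0.99)
  g <- buildCoexpressionNetwork(e$primary, e$secondary)
  expect_false("u|v" %in% graphEdgeKeys(g))
  expect_true("u|v" %in% graphEdgeKeys(
    buildCoexpressionNetwork(e$primary, e$secondary, absolute = TRUE)))
})

test_that("secondary = primary reduces to the single stringent threshold", {
  set.seed(21)
  expr <- simulateExpression(40, 12, nModules = 4, noiseSd = 0.25, seed = 21)
  g1 <- buildCoexpressionNetwork(expr, expr)
  g2 <- buildCoexpressionNetwork(expr, NULL)
  pm <- pearsonMatrix(expr)
  pm[lower.tri(pm, diag = TRUE)] <- NA
  want <- which(pm > 0.95, arr.ind = TRUE)
  expect_setequal(graphEdgeKeys(g1),
                  edgeKey(rownames(pm)[want[, 1]], colnames(pm)[want[, 2]]))
  expect_setequal(graphEdgeKeys(g1), graphEdgeKeys(g2))
})

test_that("threshold validation", {
  expr <- simulateExpression(10, 5, seed = 1)
  expect_error(buildCoexpressionNetwork(expr, stringent = 1.2), "0, 1")
  expect_error(buildCoexpressionNetwork(expr, stringent = 0.7, relaxed = 0.9),
               "exceed")
})

test_that("module structure shows up as motif-rich co-expression networks", {
  expr1 <- simulateExpression(60, 15, nModules = 6, noiseSd = 0.2, seed = 8)
  expr2 <- simulateExpression(60, 15, nModules = 6, noiseSd = 0.2, seed = 9)
  g <- buildCoexpressionNetwork(expr1, expr2)
  expect_gt(igraph::ecount(g), 20)
  expect_gt(motifCount(g, motif("triangle"))$f1, 0)
})

test_that("diffToScript round-trips arbitrary graph pairs", {
  expect_equal(nrow(diffToScript(demoGraph(), demoGraph(), seed = 1)), 0)
  sc <- diffToScript(graphFromEdges("a", "b"), graphFromEdges("b", "c"),
                     seed = 2)
  expect_equal(nrow(sc), 2)
  expect_setequal(paste(sc$op, edgeKey(sc$u, sc$v)), c("- a|b", "+ b|c"))
  for (seed in 1:5) {
    start <- smallRandomGraph(25, 0.12, seed)
    final <- smallRandomGraph(25, 0.12, seed + 40)
    igraph::V(final)$name <- igraph::V(start)$name
    sc <- diffToScript(start, final, seed = seed)
    got <- applyEditScript(start, sc)
    expect_setequal(graphEdgeKeys(got), graphEdgeKeys(final))
  }
})

test_that("expression matrices round-trip through TSV", {
  expr <- simulateExpression(8, 5, seed = 3)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeExpressionMatrix(expr, f)
  back <- readExpressionMatrix(f)
  expect_equal(back, expr[rownames(back), colnames(back)],
               ignore_attr = TRUE, tolerance = 1e-12)
})
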