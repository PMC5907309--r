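# Shared fixtures and independent oracles. The oracles deliberately avoid
# the package's counting path: embeddings are enumerated by exhaustive
# subset search with igraph's isomorphism test, and disjoint-set sizes by
# exact maximum-independent-set recursion.

# 10-edge demo graph: a wheel-like network with four triangles through the
# hub "a", two overlapping pairs
demoGraph <- function() {
  graphFromEdges(c("a", "a", "b", "a", "e", "a", "a", "c", "a", "d"),
                 c("b", "e", "e", "f", "f", "c", "d", "d", "g", "g"))
}

demoTriangles <- function() {
  rbind(c("a|b", "a|e", "b|e"),
        c("a|e", "a|f", "e|f"),
        c("a|c", "a|d", "c|d"),
        c("a|d", "a|g", "d|g"))
}

sortEmb <- function(mat) {
  if (nrow(mat) == 0) return(mat)
  mat <- t(apply(mat, 1, sort))
  mat[order(apply(mat, 1, paste, collapse = ";")), , drop = FALSE]
}

expect_same_embeddings <- function(got, want) {
  expect_equal(sortEmb(got), sortEmb(want), ignore_attr = TRUE)
}

# exhaustive F1 oracle: every edge subset of motif size, kept if connected
# and isomorphic (igraph's isomorphism test, independent of the package's
# canonical form)
bruteEmbeddings <- function(graph, m) {
  if (!methods::is(m, "Motif")) m <- motif(m)
  keys <- sort(graphEdgeKeys(graph))
  q <- m@nEdges
  if (length(keys) < q) return(matrix(character(0), 0, q))
  sel <- utils::combn(length(keys), q)
  rows <- list()
  for (j in seq_len(ncol(sel))) {
    ek <- keys[sel[, j]]
    parts <- do.call(rbind, strsplit(ek, "|", fixed = TRUE))
    sg <- graphFromEdges(parts[, 1], parts[, 2])
    if (igraph::is_connected(sg) &&
        igraph::vcount(sg) == m@nNodes &&
        igraph::isomorphic(sg, m@graph)) {
      rows[[length(rows) + 1L]] <- ek
    }
  }
  if (!length(rows)) return(matrix(character(0), 0, q))
  sortEmb(do.call(rbind, rows))
}

# conflict adjacency of an embedding matrix (edge or node sharing)
conflictAdj <- function(emb, mode = "edge") {
  n <- nrow(emb)
  adj <- matrix(FALSE, n, n)
  keys <- lapply(seq_len(n), function(i) {
    if (mode == "edge") emb[i, ]
    else unique(unlist(strsplit(emb[i, ], "|", fixed = TRUE)))
  })
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && length(intersect(keys[[i]], keys[[j]]))) {
      adj[i, j] <- adj[j, i] <- TRUE
    }
  }
  adj
}

# exact maximum independent set size by branch and bound (<= ~20 embeddings)
exactDisjointMax <- function(emb, mode = "edge") {
  n <- nrow(emb)
  if (n == 0) return(0)
  adj <- conflictAdj(emb, mode)
  rec <- function(avail) {
    if (!length(avail)) return(0L)
    v <- avail[which.max(colSums(adj[avail, avail, drop = FALSE]))]
    rest <- setdiff(avail, v)
    max(rec(rest), 1L + rec(setdiff(rest, which(adj[v, ]))))
  }
  rec(seq_len(n))
}

# small seeded ER graph handy for randomised property tests
smallRandomGraph <- function(n, p, seed) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- paste0("v", seq_len(n))
  g
}
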