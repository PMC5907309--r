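# Static counting: enumerate all embeddings of a motif (F1), build the
# overlap graph, and run the min-degree greedy for the edge-disjoint (F2)
# and node-disjoint (F3) embedding sets.
#
# The scalable path goes through the C++ engine (which never materialises
# the overlap graph); `overlapGraph()` + `greedyDisjoint()` expose the same
# construction explicitly, in pure R, for inspection and cross-checking at
# small scale.

# Deterministic label <-> id mapping for the engine: labels in lexicographic
# order, edges sorted by canonical key. Returns engine pointer plus mapping.
.engine_new <- function(graph, m, tieBreak = c("id", "random")) {
  tieBreak <- match.arg(tieBreak)
  stopifnot(is(m, "Motif"))
  graph <- .check_simple(.as_named_graph(graph))
  labels <- sort(igraph::V(graph)$name)
  el <- igraph::as_edgelist(graph, names = TRUE)
  if (nrow(el)) {
    a <- pmin(el[, 1], el[, 2])
    b <- pmax(el[, 1], el[, 2])
    o <- order(a, b)
    ids <- cbind(match(a[o], labels), match(b[o], labels)) - 1L
  } else {
    ids <- matrix(integer(0), 0, 2)
  }
  storage.mode(ids) <- "integer"
  ptr <- .eng_new(ids, length(labels), .motif_edge_matrix(m@graph),
                  m@nNodes, tieBreak == "random")
  list(ptr = ptr, labels = labels)
}

# (nEmb x 2q) id matrix from the engine -> character matrix of canonical
# edge keys, one row per embedding, columns sorted within each row
.emb_key_matrix <- function(embList, labels) {
  mat <- embList$edges
  if (nrow(mat) == 0)
    return(matrix(character(0), 0, max(1L, ncol(mat) / 2L)))
  q <- ncol(mat) / 2L
  keys <- vapply(seq_len(q), function(t) {
    edgeKey(labels[mat[, 2 * t - 1] + 1L], labels[mat[, 2 * t] + 1L])
  }, character(nrow(mat)))
  keys <- matrix(keys, nrow = nrow(mat))
  t(apply(keys, 1, sort))
}

#' Enumerate all embeddings of a motif
#'
#' An embedding is a connected edge subset of the host graph whose induced
#' subgraph is isomorphic to the motif; it is identified by its edge set, so
#' automorphic re-mappings of the same edges count once. The number of rows
#' is the F1 count.
#'
#' @param graph an undirected igraph with named vertices.
#' @param m a [Motif-class] (or anything [motif()] accepts).
#' @return a character matrix with one row per embedding and one column per
#'   motif edge, entries being canonical edge keys (sorted within each row).
#' @examples
#' g <- graphFromEdges(c("a", "b", "c"), c("b", "c", "a"))
#' enumerateEmbeddings(g, motif("triangle"))
#' @export
enumerateEmbeddings <- function(graph, m) {
  if (!is(m, "Motif")) m <- motif(m)
  eng <- .engine_new(graph, m)
  .emb_key_matrix(.eng_embeddings(eng$ptr), eng$labels)
}

#' Build the overlap graph of an embedding set
#'
#' One node per embedding; an edge joins two embeddings that conflict —
#' share at least one host edge (`mode = "edge"`) or at least one node
#' (`mode = "node"`). Independent sets of the edge-mode overlap graph are
#' exactly the edge-disjoint embedding sets (and likewise for node mode).
#' Intended for small embedding sets; the scalable counters use the
#' equivalent implicit construction.
#'
#' @param embeddings a character matrix as returned by
#'   [enumerateEmbeddings()].
#' @param mode conflict relation: `"edge"` (F2) or `"node"` (F3).
#' @return an igraph whose vertices are named by embedding row index, with
#'   the embedding matrix attached as graph attribute `embeddings`.
#' @export
overlapGraph <- function(embeddings, mode = c("edge", "node")) {
  mode <- match.arg(mode)
  n <- nrow(embeddings)
  keysOf <- function(i) {
    ek <- embeddings[i, ]
    if (mode == "edge") ek else unique(unlist(strsplit(ek, "|", fixed = TRUE)))
  }
  og <- igraph::make_empty_graph(n = n, directed = FALSE)
  igraph::V(og)$name <- as.character(seq_len(n))
  if (n > 1) {
    keys <- lapply(seq_len(n), keysOf)
    pairs <- utils::combn(n, 2)
    hit <- vapply(seq_len(ncol(pairs)), function(j) {
      length(intersect(keys[[pairs[1, j]]], keys[[pairs[2, j]]])) > 0
    }, logical(1))
    if (any(hit))
      og <- igraph::add_edges(og, as.vector(pairs[, hit, drop = FALSE]))
  }
  og <- igraph::set_graph_attr(og, "embeddings", embeddings)
  igraph::set_graph_attr(og, "mode", mode)
}

#' Min-degree greedy independent set of an overlap graph
#'
#' Visits the overlap-graph nodes in ascending order of their degree
#' (computed once, on the full overlap graph), selecting every node still
#' unremoved and removing it together with its neighbours. The selected
#' nodes form a maximal independent set; its size is the F2 count
#' (edge-mode overlap graph) or F3 count (node mode). Ties are broken
#' deterministically by smallest embedding id, or uniformly at random
#' within each equal-degree group with `tieBreak = "random"` (seed via
#' [set.seed()]). Static initial degrees keep the cost linear in the
#' embeddings' conflict lists, which is what makes hub-dense hosts
#' tractable; the scalable counters use the identical policy, so results
#' agree across both routes.
#'
#' @param overlap an igraph, typically from [overlapGraph()].
#' @param tieBreak `"id"` (default) or `"random"`.
#' @return integer vector of selected embedding indices, ascending.
#' @export
greedyDisjoint <- function(overlap, tieBreak = c("id", "random")) {
  tieBreak <- match.arg(tieBreak)
  n <- igraph::vcount(overlap)
  if (n == 0) return(integer(0))
  adjm <- igraph::as_adjacency_matrix(overlap, sparse = FALSE) > 0
  degs <- igraph::degree(overlap)
  ord <- order(degs, seq_len(n))
  if (tieBreak == "random") {
    # split() returns the equal-degree groups in ascending degree order
    ord <- unlist(lapply(split(ord, degs[ord]), function(grp) {
      if (length(grp) > 1) sample(grp) else grp
    }), use.names = FALSE)
  }
  state <- integer(n)  # 0 residual, 1 selected, 2 removed
  for (i in ord) {
    if (state[i] != 0L) next
    state[i] <- 1L
    state[adjm[i, ] & state == 0L] <- 2L
  }
  which(state == 1L)
}

#' Motif counts in a static graph
#'
#' Enumerates every embedding of the motif (F1) and reduces the set to
#' maximal edge-disjoint (F2) and, optionally, node-disjoint (F3)
#' subsets with the min-degree greedy.
#'
#' @param graph an undirected igraph with named vertices.
#' @param m a [Motif-class] (or anything [motif()] accepts).
#' @param f3 also compute the node-disjoint count (skipped by default: it
#'   is not maintained dynamically and can be expensive on large graphs).
#' @param embeddings attach the embedding matrix and the selected member
#'   rows to the result.
#' @param tieBreak greedy tie-break policy, as in [greedyDisjoint()].
#' @return a list with elements `f1`, `f2` (and `f3` if requested), plus
#'   `embeddings`, `f2Members` (and `f3Members`) when `embeddings = TRUE`.
#' @examples
#' g <- graphFromEdges(c("a","a","b","a","e","a","a","c","a","d"),
#'                     c("b","e","e","f","f","c","d","d","g","g"))
#' motifCount(g, motif("triangle"), f3 = TRUE)[c("f1", "f2", "f3")]
#' @export
motifCount <- function(graph, m, f3 = FALSE, embeddings = FALSE,
                       tieBreak = c("id", "random")) {
  if (!is(m, "Motif")) m <- motif(m)
  tieBreak <- match.arg(tieBreak)
  eng <- .engine_new(graph, m, tieBreak)
  cts <- .eng_counts(eng$ptr)
  out <- list(f1 = unname(cts["f1"]), f2 = unname(cts["f2"]))
  emb <- NULL
  if (f3 || embeddings) emb <- .eng_embeddings(eng$ptr)
  if (f3) {
    res <- .eng_f3(eng$ptr)
    out$f3 <- res$f3
    if (embeddings) out$f3Members <- match(res$ids, emb$ids)
  }
  if (embeddings) {
    out$embeddings <- .emb_key_matrix(emb, eng$labels)
    out$f2Members <- which(emb$member == 1L)
  }
  # engine memory is only reclaimed at gc; on large hosts do it eagerly so
  # repeated recounts (checkpointing) keep a flat footprint
  if (igraph::ecount(graph) > 2000) { rm(eng); gc(FALSE) }
  out
}
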