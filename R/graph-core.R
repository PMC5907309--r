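# Undirected simple-graph utilities, edit operations and the distance /
# neighbourhood primitives the counting algorithms rely on. Host graphs are
# igraph objects with character vertex names; an edge is identified by the
# unordered pair of names, canonically oriented with the lexicographically
# smaller endpoint first.

.as_named_graph <- function(graph) {
  if (!igraph::is_igraph(graph)) stop("`graph` must be an igraph object")
  if (igraph::is_directed(graph)) stop("`graph` must be undirected")
  if (is.null(igraph::V(graph)$name))
    igraph::V(graph)$name <- as.character(seq_len(igraph::vcount(graph)))
  graph
}

.check_simple <- function(graph) {
  if (igraph::any_loop(graph) || igraph::any_multiple(graph))
    stop("graph must be simple (no self-loops or parallel edges)")
  graph
}

#' Canonical edge keys
#'
#' Collapses an unordered node pair into the canonical string
#' `"<min>|<max>"` (lexicographic order on the label strings), the edge
#' identity used throughout the package.
#'
#' @param u,v character vectors of endpoint labels (recycled).
#' @return character vector of canonical edge keys.
#' @examples
#' edgeKey(c("b", "a"), c("a", "c"))
#' @export
edgeKey <- function(u, v) {
  u <- as.character(u)
  v <- as.character(v)
  paste(pmin(u, v), pmax(u, v), sep = "|")
}

#' Canonical edge-key set of a graph
#'
#' @param graph an undirected igraph with named vertices.
#' @return character vector, one canonical key per edge.
#' @export
graphEdgeKeys <- function(graph) {
  graph <- .as_named_graph(graph)
  if (igraph::ecount(graph) == 0) return(character(0))
  el <- igraph::as_edgelist(graph, names = TRUE)
  edgeKey(el[, 1], el[, 2])
}

#' Read / write an edge-list TSV
#'
#' One edge per line, two tab-separated node labels; lines starting with
#' `#` are comments. The graph is undirected and simple; duplicate edges
#' (in either orientation) and self-loops are rejected.
#'
#' @param path file path.
#' @return `readEdgeList` returns an igraph; `writeEdgeList` returns the
#'   path invisibly.
#' @export
readEdgeList <- function(path) {
  tab <- utils::read.table(path, sep = "\t", comment.char = "#",
                           colClasses = "character", header = FALSE)
  if (ncol(tab) < 2) stop("edge list must have two tab-separated columns")
  u <- tab[[1]]; v <- tab[[2]]
  if (any(u == v)) stop("self-loop in edge list")
  if (anyDuplicated(edgeKey(u, v))) stop("duplicate edge in edge list")
  graphFromEdges(u, v)
}

#' @rdname readEdgeList
#' @param graph an undirected igraph with named vertices.
#' @export
writeEdgeList <- function(graph, path) {
  graph <- .as_named_graph(graph)
  el <- igraph::as_edgelist(graph, names = TRUE)
  el <- cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
  utils::write.table(el, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Build a graph from parallel endpoint vectors
#'
#' @param u,v character vectors of endpoint labels.
#' @param nodes optional character vector of additional (possibly isolated)
#'   node labels.
#' @return an undirected simple igraph with named vertices.
#' @export
graphFromEdges <- function(u, v, nodes = character(0)) {
  u <- as.character(u)
  v <- as.character(v)
  verts <- sort(unique(c(u, v, as.character(nodes))))
  g <- igraph::make_empty_graph(n = length(verts), directed = FALSE)
  igraph::V(g)$name <- verts
  if (length(u))
    g <- igraph::add_edges(g, rbind(match(u, verts), match(v, verts)))
  .check_simple(g)
}

#' Edit scripts
#'
#' An edit script is an ordered sequence of single-edge operations: `op` is
#' `"+"` (insert) or `"-"` (delete), `u` and `v` are endpoint labels. Each
#' insert must target a non-edge of the current graph and each delete a
#' current edge; [applyEditScript()] validates this and fails loudly on
#' inconsistent scripts.
#'
#' @param op character vector of `"+"` / `"-"`.
#' @param u,v character vectors of endpoint labels.
#' @return a `data.frame` with columns `op`, `u`, `v` and class
#'   `"editScript"`.
#' @examples
#' editScript(c("-", "+"), c("a", "a"), c("e", "e"))
#' @export
editScript <- function(op = character(0), u = character(0), v = character(0)) {
  op <- as.character(op)
  u <- as.character(u)
  v <- as.character(v)
  if (!all(op %in% c("+", "-"))) stop("`op` must be '+' or '-'")
  if (length(u) != length(op) || length(v) != length(op))
    stop("`op`, `u`, `v` must have equal length")
  if (any(u == v)) stop("edit endpoints must be distinct")
  out <- data.frame(op = op, u = u, v = v, stringsAsFactors = FALSE)
  class(out) <- c("editScript", "data.frame")
  out
}

#' @rdname editScript
#' @param path file path; scripts are stored as three tab-separated columns
#'   (`op`, `u`, `v`), `#`-comment lines allowed.
#' @export
readEditScript <- function(path) {
  tab <- utils::read.table(path, sep = "\t", comment.char = "#",
                           colClasses = "character", header = FALSE)
  if (ncol(tab) < 3) stop("edit script must have three tab-separated columns")
  editScript(tab[[1]], tab[[2]], tab[[3]])
}

#' @rdname editScript
#' @param script an `editScript`.
#' @export
writeEditScript <- function(script, path) {
  stopifnot(inherits(script, "editScript"))
  utils::write.table(script, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Reverse an edit script
#'
#' Inverts every operation and reverses their order, so that applying a
#' script followed by its reverse restores the original edge set.
#'
#' @param script an `editScript`.
#' @return an `editScript`.
#' @export
reverseScript <- function(script) {
  stopifnot(inherits(script, "editScript"))
  n <- nrow(script)
  if (n == 0) return(script)
  idx <- rev(seq_len(n))
  editScript(ifelse(script$op[idx] == "+", "-", "+"),
             script$u[idx], script$v[idx])
}

#' Apply a single edit operation
#'
#' For graphs, returns the updated graph; inserting an edge whose endpoint
#' is a new label implicitly adds that node (node insertion reduces to edge
#' insertions), and deleting the last edge of a node leaves the node in
#' place. Inserting an existing edge or deleting an absent one is a
#' script-consistency error.
#'
#' @param x an igraph (or a [DynamicMotifCounter]; see
#'   [applyEdit,DynamicMotifCounter-method]).
#' @param op `"+"` or `"-"`.
#' @param u,v endpoint labels.
#' @return the updated object.
#' @export
setGeneric("applyEdit", function(x, op, u, v) standardGeneric("applyEdit"))

#' @describeIn applyEdit edit an igraph, returning the new graph.
#' @export
setMethod("applyEdit", "igraph", function(x, op, u, v) {
  x <- .as_named_graph(x)
  u <- as.character(u)
  v <- as.character(v)
  if (u == v) stop("script-consistency error: self-loop edit")
  present <- all(c(u, v) %in% igraph::V(x)$name) &&
    igraph::are_adjacent(x, u, v)
  if (op == "+") {
    if (present)
      stop(sprintf("script-consistency error: inserting existing edge (%s, %s)",
                   u, v))
    new <- setdiff(c(u, v), igraph::V(x)$name)
    if (length(new)) x <- igraph::add_vertices(x, length(new), name = new)
    igraph::add_edges(x, c(u, v))
  } else if (op == "-") {
    if (!present)
      stop(sprintf("script-consistency error: deleting absent edge (%s, %s)",
                   u, v))
    igraph::delete_edges(x, igraph::get_edge_ids(x, c(u, v)))
  } else stop("`op` must be '+' or '-'")
})

#' Apply an edit script
#'
#' @param x an igraph or a [DynamicMotifCounter].
#' @param script an `editScript`.
#' @return for graphs, the final graph; for counters, a per-step timeline
#'   (see the counter method).
#' @export
setGeneric("applyEditScript", function(x, script) {
  standardGeneric("applyEditScript")
})

#' @describeIn applyEditScript apply to an igraph, returning the final graph.
#' @export
setMethod("applyEditScript", "igraph", function(x, script) {
  stopifnot(inherits(script, "editScript"))
  for (i in seq_len(nrow(script))) {
    x <- tryCatch(
      applyEdit(x, script$op[i], script$u[i], script$v[i]),
      error = function(e) stop(sprintf("step %d: %s", i, conditionMessage(e)),
                               call. = FALSE))
  }
  x
})

#' Shortest-path distance between two nodes
#'
#' Number of edges on a shortest path; 0 for a node against itself and
#' `Inf` for disconnected pairs.
#'
#' @param graph an undirected igraph with named vertices.
#' @param u,v node labels.
#' @return a non-negative number, possibly `Inf`.
#' @export
nodeDistance <- function(graph, u, v) {
  graph <- .as_named_graph(graph)
  u <- as.character(u)
  v <- as.character(v)
  if (!all(c(u, v) %in% igraph::V(graph)$name)) stop("unknown node")
  as.numeric(igraph::distances(graph, v = u, to = v))
}

#' k-neighbourhood of an edge
#'
#' The subgraph formed by every edge with at least one endpoint within
#' distance `k` of either endpoint of the seed edge, together with the
#' endpoints of those edges. Always contains the seed edge, and is monotone
#' in `k`.
#'
#' @param graph an undirected igraph with named vertices.
#' @param u,v endpoints of the seed edge, which must be present.
#' @param k non-negative integer radius.
#' @return an igraph subgraph.
#' @export
kNeighborhood <- function(graph, u, v, k) {
  graph <- .as_named_graph(graph)
  u <- as.character(u)
  v <- as.character(v)
  if (!all(c(u, v) %in% igraph::V(graph)$name) ||
      !igraph::are_adjacent(graph, u, v))
    stop("seed edge not present in graph")
  k <- as.integer(k)
  if (k < 0) stop("`k` must be non-negative")
  d <- igraph::distances(graph, v = c(u, v))
  near <- igraph::V(graph)$name[apply(d, 2, min) <= k]
  el <- igraph::as_edgelist(graph, names = TRUE)
  keep <- el[, 1] %in% near | el[, 2] %in% near
  graphFromEdges(el[keep, 1], el[keep, 2])
}
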