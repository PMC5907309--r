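# Motif (pattern) representation. A motif is a small connected unlabeled
# topology; isomorphic inputs collapse to the same canonical form, computed
# by exhaustive minimisation of the adjacency-matrix encoding over all node
# permutations (exact at motif scale).

#' Motif: a small connected unlabeled pattern
#'
#' Wraps the pattern topology together with its cached diameter (the search
#' radius used after an edge insertion) and canonical form (the equivalence
#' class key under isomorphism).
#'
#' @slot graph the pattern topology as an undirected igraph.
#' @slot name display name.
#' @slot nNodes,nEdges pattern size.
#' @slot diameter maximum pairwise node distance in the pattern.
#' @slot canonical canonical-form key; identical for isomorphic patterns.
#' @export
setClass("Motif",
         representation(graph = "ANY", name = "character",
                        nNodes = "integer", nEdges = "integer",
                        diameter = "integer", canonical = "character"))

setValidity("Motif", function(object) {
  g <- object@graph
  if (!igraph::is_igraph(g)) return("pattern must be an igraph")
  if (igraph::ecount(g) < 1) return("pattern must have at least one edge")
  if (!igraph::is_connected(g)) return("pattern must be connected")
  if (igraph::any_loop(g) || igraph::any_multiple(g))
    return("pattern must be simple")
  TRUE
})

# 0-based edge matrix on nodes 0..n-1 (internal exchange format with C++)
.motif_edge_matrix <- function(g) {
  el <- igraph::as_edgelist(g, names = FALSE)
  storage.mode(el) <- "integer"
  el - 1L
}

.builtin_motifs <- list(
  path2    = rbind(c("1", "2"), c("2", "3")),
  path3    = rbind(c("1", "2"), c("2", "3"), c("3", "4")),
  triangle = rbind(c("1", "2"), c("2", "3"), c("1", "3")),
  star3    = rbind(c("1", "2"), c("1", "3"), c("1", "4"))
)

#' Construct a motif
#'
#' @param x a built-in motif name (`"path2"`, `"path3"`, `"triangle"`,
#'   `"star3"`), an undirected igraph, or a two-column matrix /
#'   data.frame of endpoint labels.
#' @param name optional display name.
#' @return a [Motif-class] object.
#' @examples
#' motif("triangle")
#' motif(rbind(c("a", "b"), c("b", "c")))  # the 2-edge path
#' @export
motif <- function(x, name = NULL) {
  if (is.character(x) && length(x) == 1) {
    if (!x %in% names(.builtin_motifs))
      stop("unknown built-in motif; use one of: ",
           paste(names(.builtin_motifs), collapse = ", "))
    if (is.null(name)) name <- x
    x <- .builtin_motifs[[x]]
  }
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.matrix(x)) {
    g <- graphFromEdges(x[, 1], x[, 2])
  } else if (igraph::is_igraph(x)) {
    g <- .check_simple(.as_named_graph(x))
  } else stop("cannot build a motif from ", class(x)[1])
  if (is.null(name)) name <- "motif"
  new("Motif", graph = g, name = name,
      nNodes = as.integer(igraph::vcount(g)),
      nEdges = as.integer(igraph::ecount(g)),
      diameter = as.integer(igraph::diameter(g)),
      canonical = .canon_cpp(igraph::vcount(g), .motif_edge_matrix(g)))
}

#' Read a motif from an edge-list TSV
#'
#' @param path file path (same format as [readEdgeList()]).
#' @param name optional display name.
#' @return a [Motif-class].
#' @export
readMotif <- function(path, name = NULL) {
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  motif(readEdgeList(path), name = name)
}

#' The four basic motifs
#'
#' All connected topologies with two or three edges, in the package's fixed
#' reporting order: Motif 1 = 2-edge path, Motif 2 = 3-edge path,
#' Motif 3 = triangle, Motif 4 = 3-edge star. The numbering is a package
#' convention (any fixed order of these four topologies is equivalent for
#' counting purposes).
#'
#' @return a named list of four [Motif-class] objects
#'   (`path2`, `path3`, `triangle`, `star3`).
#' @examples
#' sapply(basicMotifs(), function(m) m@diameter)
#' @export
basicMotifs <- function() {
  lapply(setNames(nm = names(.builtin_motifs)), motif)
}

#' Canonical form of a small graph
#'
#' Equivalence-class key under graph isomorphism: the minimum
#' adjacency-matrix encoding over all node permutations, prefixed with the
#' node count. Two graphs get the same key iff they are isomorphic
#' (exhaustive, so limited to graphs with at most 10 nodes).
#'
#' @param x a [Motif-class], an igraph, or a two-column edge matrix.
#' @return a character scalar.
#' @export
canonicalForm <- function(x) {
  if (is(x, "Motif")) return(x@canonical)
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.matrix(x)) x <- graphFromEdges(x[, 1], x[, 2])
  x <- .as_named_graph(x)
  .canon_cpp(igraph::vcount(x), .motif_edge_matrix(x))
}

#' Test two small graphs for isomorphism
#'
#' True iff an edge-preserving bijection between the node sets exists.
#' Decided by comparing canonical forms; exact for graphs with at most 10
#' nodes.
#'
#' @param g1,g2 [Motif-class] objects, igraphs, or two-column edge
#'   matrices.
#' @return logical scalar.
#' @examples
#' areIsomorphic(motif("triangle"), rbind(c("x", "y"), c("y", "z"), c("z", "x")))
#' @export
areIsomorphic <- function(g1, g2) {
  .nodes_of <- function(x) {
    if (is(x, "Motif")) return(x@nNodes)
    if (is.data.frame(x)) x <- as.matrix(x)
    if (is.matrix(x)) return(length(unique(c(x[, 1], x[, 2]))))
    igraph::vcount(.as_named_graph(x))
  }
  if (.nodes_of(g1) != .nodes_of(g2)) return(FALSE)
  identical(canonicalForm(g1), canonicalForm(g2))
}

setMethod("show", "Motif", function(object) {
  cat(sprintf("Motif '%s': %d nodes, %d edges, diameter %d\n",
              object@name, object@nNodes, object@nEdges, object@diameter))
  cat("  canonical form:", object@canonical, "\n")
  invisible(object)
})
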