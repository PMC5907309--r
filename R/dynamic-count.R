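# Dynamic counting: the live state that keeps F1 (exactly) and F2 (by local
# repair) current across edge insertions and deletions.
#
# On deletion of edge e, every embedding indexed under e dies and F1 drops
# by |D_e|; if one of them was an F2 member X, its edges are released and
# its surviving overlap-graph neighbours are scanned for a replacement
# whose edges are all free. On insertion, the embeddings containing the new
# edge are discovered by anchored enumeration within the motif-diameter
# neighbourhood, F1 grows by their number, and at most one all-free new
# embedding joins the F2 set.

#' DynamicMotifCounter: live F1/F2 state of one (graph, motif) pair
#'
#' Created by [dynamicMotifCounter()]; updated in place by [applyEdit()]
#' and [applyEditScript()] (the external-pointer engine is mutable, so the
#' counter behaves reference-like: keep using the same object).
#'
#' @slot ptr external pointer to the counting engine.
#' @slot motif the counted [Motif-class].
#' @slot env environment holding the node-label table.
#' @export
setClass("DynamicMotifCounter",
         representation(ptr = "externalptr", motif = "Motif",
                        env = "environment"))

#' Initialise dynamic motif counting
#'
#' Enumerates all embeddings of the motif in the starting graph, builds the
#' per-edge embedding index, and selects the initial F2 member set with the
#' min-degree greedy — the same procedure a static count uses, so counts at
#' step 0 match [motifCount()] exactly under the same tie-break policy.
#'
#' @param graph the starting network, an undirected igraph with named
#'   vertices.
#' @param m a [Motif-class] (or anything [motif()] accepts).
#' @param tieBreak `"id"` (deterministic, default) or `"random"` (seed via
#'   [set.seed()]); applies to the initial greedy and to all subsequent
#'   repair/admission choices.
#' @return a [DynamicMotifCounter-class].
#' @examples
#' g <- graphFromEdges(c("a", "b", "c"), c("b", "c", "a"))
#' ctr <- dynamicMotifCounter(g, motif("path2"))
#' f1Count(ctr)
#' @export
dynamicMotifCounter <- function(graph, m, tieBreak = c("id", "random")) {
  if (!is(m, "Motif")) m <- motif(m)
  eng <- .engine_new(graph, m, tieBreak)
  env <- new.env(parent = emptyenv())
  env$labels <- eng$labels
  new("DynamicMotifCounter", ptr = eng$ptr, motif = m, env = env)
}

# label -> 0-based engine id, registering new labels
.dyn_ids <- function(x, labels) {
  labs <- x@env$labels
  new <- setdiff(unique(labels), labs)
  if (length(new)) {
    labs <- c(labs, new)
    x@env$labels <- labs
  }
  match(labels, labs) - 1L
}

#' @describeIn applyEdit apply one edit to a live counter (mutates the
#'   counter; returns it invisibly).
#' @export
setMethod("applyEdit", "DynamicMotifCounter", function(x, op, u, v) {
  ids <- .dyn_ids(x, c(as.character(u), as.character(v)))
  if (op == "+") .eng_insert(x@ptr, ids[1], ids[2])
  else if (op == "-") .eng_delete(x@ptr, ids[1], ids[2])
  else stop("`op` must be '+' or '-'")
  invisible(x)
})

#' @describeIn applyEditScript apply a whole script to a live counter;
#'   returns a per-step timeline `data.frame` with columns `step`, `op`,
#'   `u`, `v`, `f1`, `f2` (the counter is mutated in place).
#' @export
setMethod("applyEditScript", "DynamicMotifCounter", function(x, script) {
  stopifnot(inherits(script, "editScript"))
  n <- nrow(script)
  if (n == 0)
    return(data.frame(step = integer(0), op = character(0),
                      u = character(0), v = character(0),
                      f1 = numeric(0), f2 = numeric(0)))
  uid <- .dyn_ids(x, script$u)
  vid <- .dyn_ids(x, script$v)
  ops <- cbind(ifelse(script$op == "+", 1L, -1L), uid, vid)
  storage.mode(ops) <- "integer"
  tl <- .eng_apply(x@ptr, ops)
  data.frame(step = seq_len(n), op = script$op, u = script$u, v = script$v,
             f1 = tl[, 1], f2 = tl[, 2], stringsAsFactors = FALSE)
})

#' Current counts of a dynamic counter
#'
#' @param x a [DynamicMotifCounter-class].
#' @return a number.
#' @export
setGeneric("f1Count", function(x) standardGeneric("f1Count"))

#' @rdname f1Count
#' @export
setGeneric("f2Count", function(x) standardGeneric("f2Count"))

#' @rdname f1Count
#' @export
setMethod("f1Count", "DynamicMotifCounter", function(x) {
  unname(.eng_counts(x@ptr)["f1"])
})

#' @rdname f1Count
#' @export
setMethod("f2Count", "DynamicMotifCounter", function(x) {
  unname(.eng_counts(x@ptr)["f2"])
})

#' Live embeddings and F2 members of a dynamic counter
#'
#' @param x a [DynamicMotifCounter-class].
#' @return `liveEmbeddings`: a character matrix of canonical edge keys, one
#'   row per live embedding (same format as [enumerateEmbeddings()]), with
#'   attribute `member` flagging the rows currently counted toward F2.
#'   `f2Members`: just the member rows.
#' @export
setGeneric("liveEmbeddings", function(x) standardGeneric("liveEmbeddings"))

#' @rdname liveEmbeddings
#' @export
setMethod("liveEmbeddings", "DynamicMotifCounter", function(x) {
  emb <- .eng_embeddings(x@ptr)
  keys <- .emb_key_matrix(emb, x@env$labels)
  attr(keys, "member") <- emb$member == 1L
  keys
})

#' @rdname liveEmbeddings
#' @export
setGeneric("f2Members", function(x) standardGeneric("f2Members"))

#' @rdname liveEmbeddings
#' @export
setMethod("f2Members", "DynamicMotifCounter", function(x) {
  keys <- liveEmbeddings(x)
  keys[attr(keys, "member"), , drop = FALSE]
})

#' Current graph tracked by a dynamic counter
#'
#' @param x a [DynamicMotifCounter-class].
#' @return an igraph with the counter's current edge set (isolated nodes
#'   that never carried an edge are not reconstructed).
#' @export
setGeneric("currentGraph", function(x) standardGeneric("currentGraph"))

#' @rdname currentGraph
#' @export
setMethod("currentGraph", "DynamicMotifCounter", function(x) {
  el <- .eng_edges(x@ptr)
  labs <- x@env$labels
  graphFromEdges(labs[el[, 1] + 1L], labs[el[, 2] + 1L], nodes = labs)
})

setMethod("show", "DynamicMotifCounter", function(object) {
  cts <- .eng_counts(object@ptr)
  cat(sprintf("DynamicMotifCounter for motif '%s'\n", object@motif@name))
  cat(sprintf("  F1 = %g, F2 = %g (%d node labels registered)\n",
              cts["f1"], cts["f2"], length(object@env$labels)))
  invisible(object)
})
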