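# Random-network generation (ER / WS / BA) and degree-preserving edge
# shuffling compiled into edit scripts.

#' Generate a random network
#'
#' Seeded generation of undirected simple networks under three standard
#' models, parameterised by node count (`size`) and target average degree:
#' \describe{
#'   \item{`"er"`}{Erdos-Renyi G(n, p) with `p = degree / (size - 1)`.}
#'   \item{`"ws"`}{Watts-Strogatz ring lattice with
#'     `degree / 2` neighbours on each side (so lattice degree equals
#'     `degree` rounded to even) and rewiring probability `wsRewire`;
#'     simplified afterwards, so the realised degree can fall slightly
#'     short.}
#'   \item{`"ba"`}{Barabasi-Albert growth with attachment parameter
#'     `m = round(degree / 2)`.}
#' }
#' Vertices are named `n1 ... n<size>`.
#'
#' @param model `"er"`, `"ws"` or `"ba"`.
#' @param size node count (>= 4).
#' @param degree target average degree (>= 2).
#' @param seed RNG seed; the same configuration and seed always yield the
#'   identical edge set.
#' @param wsRewire Watts-Strogatz rewiring probability (default 0.1, the
#'   conventional small-world regime).
#' @return an undirected simple igraph with named vertices.
#' @examples
#' g <- generateNetwork("er", size = 100, degree = 6, seed = 1)
#' igraph::ecount(g)
#' @export
generateNetwork <- function(model = c("er", "ws", "ba"), size, degree, seed,
                            wsRewire = 0.1) {
  model <- match.arg(model)
  size <- as.integer(size)
  if (size < 4) stop("`size` must be at least 4")
  if (degree < 2) stop("`degree` must be at least 2")
  if (degree >= size) stop("`degree` must be smaller than `size`")
  set.seed(as.integer(seed))
  g <- switch(model,
    er = igraph::sample_gnp(size, p = degree / (size - 1)),
    ws = {
      nei <- max(1L, round(degree / 2))
      igraph::simplify(
        igraph::sample_smallworld(dim = 1, size = size, nei = nei,
                                  p = wsRewire))
    },
    ba = {
      m <- max(1L, round(degree / 2))
      if (m >= size) stop("BA attachment parameter must be below `size`")
      igraph::sample_pa(size, m = m, directed = FALSE)
    })
  igraph::V(g)$name <- paste0("n", seq_len(size))
  .check_simple(g)
}

#' Degree-preserving shuffle script
#'
#' Compiles `nOps / 4` degree-preserving edge shuffles into an edit script.
#' Each shuffle draws two node-disjoint edges (a,b) and (u,v) and replaces
#' them with (a,v) and (u,b); candidates whose replacement edges already
#' exist are rejected and resampled, so the evolving graph stays simple.
#' Every shuffle contributes two deletions and two insertions, emitted in a
#' random order (any interleaving is valid once a candidate passes the
#' rejection rule, since the four edges are pairwise distinct). Applying
#' the script leaves every node's degree unchanged after each complete
#' shuffle.
#'
#' @param graph the starting network (undirected, simple, >= 2
#'   node-disjoint edges).
#' @param nOps script length; must be divisible by 4.
#' @param seed RNG seed.
#' @param maxTries resampling budget per shuffle before giving up.
#' @return an `editScript` of length `nOps`.
#' @examples
#' g <- generateNetwork("er", size = 50, degree = 6, seed = 1)
#' sc <- shuffleScript(g, nOps = 20, seed = 2)
#' table(sc$op)
#' @export
shuffleScript <- function(graph, nOps, seed, maxTries = 1000L) {
  graph <- .check_simple(.as_named_graph(graph))
  nOps <- as.integer(nOps)
  if (nOps %% 4L != 0L) stop("`nOps` must be divisible by 4")
  set.seed(as.integer(seed))
  el <- igraph::as_edgelist(graph, names = TRUE)
  eu <- pmin(el[, 1], el[, 2])
  ev <- pmax(el[, 1], el[, 2])
  o <- order(eu, ev)
  eu <- eu[o]; ev <- ev[o]
  present <- new.env(parent = emptyenv())
  for (k in edgeKey(eu, ev)) assign(k, TRUE, envir = present)
  has <- function(a, b) exists(edgeKey(a, b), envir = present)
  m <- length(eu)
  if (m < 2) stop("graph has too few edges to shuffle")

  op <- character(nOps); su <- character(nOps); sv <- character(nOps)
  pos <- 0L
  for (s in seq_len(nOps %/% 4L)) {
    done <- FALSE
    for (try in seq_len(maxTries)) {
      ij <- sample.int(m, 2)
      a <- eu[ij[1]]; b <- ev[ij[1]]; u <- eu[ij[2]]; v <- ev[ij[2]]
      # edge orientation is arbitrary: flip at random so both rewirings of
      # an unordered edge pair are reachable
      if (stats::runif(1) < 0.5) { t <- a; a <- b; b <- t }
      if (stats::runif(1) < 0.5) { t <- u; u <- v; v <- t }
      if (length(unique(c(a, b, u, v))) < 4) next        # shared node
      if (has(a, v) || has(u, b)) next                   # replacement exists
      ops <- rbind(c("-", a, b), c("-", u, v), c("+", a, v), c("+", u, b))
      ops <- ops[sample.int(4), , drop = FALSE]
      idx <- pos + seq_len(4L)
      op[idx] <- ops[, 1]; su[idx] <- ops[, 2]; sv[idx] <- ops[, 3]
      pos <- pos + 4L
      rm(list = c(edgeKey(a, b), edgeKey(u, v)), envir = present)
      assign(edgeKey(a, v), TRUE, envir = present)
      assign(edgeKey(u, b), TRUE, envir = present)
      eu[ij[1]] <- min(a, v); ev[ij[1]] <- max(a, v)
      eu[ij[2]] <- min(u, b); ev[ij[2]] <- max(u, b)
      done <- TRUE
      break
    }
    if (!done) stop("no valid degree-preserving shuffle found after ",
                    maxTries, " attempts")
  }
  editScript(op, su, sv)
}
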