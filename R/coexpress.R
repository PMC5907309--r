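# Paired gene co-expression network construction (stringent / relaxed
# two-condition rule) and network diffing into edit scripts.

#' Read / write an expression matrix TSV
#'
#' Genes in rows, samples in columns; a header row of sample ids and the
#' gene id in the first column.
#'
#' @param path file path.
#' @return `readExpressionMatrix` returns a numeric matrix with gene row
#'   names and sample column names.
#' @export
readExpressionMatrix <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                           check.names = FALSE)
  as.matrix(tab)
}

#' @rdname readExpressionMatrix
#' @param expr numeric gene-by-sample matrix with row and column names.
#' @export
writeExpressionMatrix <- function(expr, path) {
  utils::write.table(data.frame(gene = rownames(expr), expr,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.check_expr <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr))
    stop("expression data must be a numeric matrix (genes x samples)")
  if (is.null(rownames(expr))) stop("expression matrix needs gene row names")
  if (anyDuplicated(rownames(expr))) stop("duplicate gene ids")
  if (ncol(expr) < 3)
    stop("at least 3 samples are required for Pearson correlation")
  expr
}

#' Gene-pair Pearson correlation matrix
#'
#' Pearson correlation between the expression profiles of every gene pair.
#' Genes with zero variance yield `NA` rows/columns (they can never pass a
#' correlation threshold and are excluded from network edges).
#'
#' @param expr numeric gene-by-sample matrix (>= 3 samples).
#' @return symmetric correlation matrix with unit diagonal (where defined).
#' @examples
#' expr <- rbind(g1 = c(1, 2, 3), g2 = c(2, 4, 6), g3 = c(3, 2, 1))
#' pearsonMatrix(expr)
#' @export
pearsonMatrix <- function(expr) {
  expr <- .check_expr(expr)
  suppressWarnings(stats::cor(t(expr), method = "pearson"))
}

#' Build a paired co-expression network
#'
#' Includes an edge between genes u and v iff (1) their correlation in the
#' primary data set is above the stringent cutoff, or (2) their correlation
#' in the secondary data set is above the stringent cutoff while that in
#' the primary data set is above the relaxed cutoff. "Above" is strict, and
#' thresholds apply to the signed correlation (so negative correlations
#' never produce edges) unless `absolute = TRUE`. With `secondary = NULL`
#' (or identical data) the rule reduces to the single stringent threshold.
#'
#' @param primary,secondary numeric gene-by-sample matrices; `secondary`
#'   may be `NULL`.
#' @param stringent,relaxed correlation cutoffs in \[0, 1\] with
#'   `relaxed <= stringent` (defaults 0.95 and 0.75).
#' @param absolute threshold `|r|` instead of the signed correlation.
#' @param genes `"intersect"` (default) restricts condition (2) to genes
#'   present in both matrices and drops all others; `"union"` keeps genes
#'   private to one matrix, reachable through condition (1) only.
#' @return an undirected simple igraph on gene ids (including isolated
#'   genes of the primary matrix).
#' @export
buildCoexpressionNetwork <- function(primary, secondary = NULL,
                                     stringent = 0.95, relaxed = 0.75,
                                     absolute = FALSE,
                                     genes = c("intersect", "union")) {
  genes <- match.arg(genes)
  if (stringent < 0 || stringent > 1 || relaxed < 0 || relaxed > 1)
    stop("thresholds must lie in [0, 1]")
  if (relaxed > stringent) stop("`relaxed` must not exceed `stringent`")
  primary <- .check_expr(primary)
  if (is.null(secondary)) secondary <- primary else .check_expr(secondary)

  shared <- intersect(rownames(primary), rownames(secondary))
  keep <- if (genes == "intersect") shared else rownames(primary)
  # zero-variance genes can never pass: drop them up front
  keep <- keep[apply(primary[keep, , drop = FALSE], 1, stats::sd) > 0]
  if (length(keep) < 2)
    return(graphFromEdges(character(0), character(0), nodes = keep))

  cp <- pearsonMatrix(primary[keep, , drop = FALSE])
  if (absolute) cp <- abs(cp)
  cond1 <- cp > stringent
  cond2 <- matrix(FALSE, length(keep), length(keep))
  sh <- intersect(keep, shared)
  sh <- sh[apply(secondary[sh, , drop = FALSE], 1, stats::sd) > 0]
  if (length(sh) >= 2) {
    cs <- pearsonMatrix(secondary[sh, , drop = FALSE])
    if (absolute) cs <- abs(cs)
    ii <- match(sh, keep)
    cond2[ii, ii] <- (cs > stringent) & (cp[ii, ii] > relaxed)
  }
  hit <- (cond1 | cond2)
  hit[is.na(hit)] <- FALSE
  hit[lower.tri(hit, diag = TRUE)] <- FALSE
  idx <- which(hit, arr.ind = TRUE)
  graphFromEdges(keep[idx[, 1]], keep[idx[, 2]], nodes = keep)
}

#' Edit script between two networks
#'
#' One deletion per edge private to the start network and one insertion
#' per edge private to the final network, in a seeded uniform-random order
#' (the true temporal order of the edits is unknown). Applying the script
#' to the start network reproduces the final network's edge set exactly.
#'
#' @param start,final undirected igraphs with named vertices.
#' @param seed RNG seed for the edit ordering.
#' @return an `editScript`.
#' @examples
#' g1 <- graphFromEdges("a", "b")
#' g2 <- graphFromEdges("b", "c")
#' diffToScript(g1, g2, seed = 1)
#' @export
diffToScript <- function(start, final, seed) {
  ks <- graphEdgeKeys(start)
  kf <- graphEdgeKeys(final)
  dels <- setdiff(ks, kf)
  inss <- setdiff(kf, ks)
  ops <- c(rep("-", length(dels)), rep("+", length(inss)))
  pairs <- do.call(rbind, strsplit(c(dels, inss), "|", fixed = TRUE))
  set.seed(as.integer(seed))
  idx <- sample.int(length(ops))
  if (length(ops) == 0) return(editScript())
  editScript(ops[idx], pairs[idx, 1], pairs[idx, 2])
}

#' Simulate a module-structured expression matrix
#'
#' Latent-module model used as the synthetic stand-in for real transcription
#' data: genes are partitioned into modules, each module shares a latent
#' sample profile, and every gene observes that profile plus independent
#' Gaussian noise. Genes within a module are therefore strongly positively
#' correlated (tunable via `noiseSd`), giving co-expression networks with
#' dense, motif-rich neighbourhoods; genes in different modules are
#' asymptotically uncorrelated.
#'
#' @param nGenes,nSamples matrix dimensions (`nSamples >= 3`).
#' @param nModules number of latent modules.
#' @param noiseSd per-gene noise standard deviation (latent profiles are
#'   standard normal; expected within-module correlation is
#'   `1 / (1 + noiseSd^2)`).
#' @param seed RNG seed.
#' @return numeric matrix with genes `g1...` in rows, samples `s1...` in
#'   columns, and the module assignment attached as attribute `module`.
#' @export
simulateExpression <- function(nGenes, nSamples, nModules = 5,
                               noiseSd = 0.3, seed = 1) {
  if (nSamples < 3) stop("`nSamples` must be at least 3")
  set.seed(as.integer(seed))
  module <- rep_len(seq_len(nModules), nGenes)
  latent <- matrix(stats::rnorm(nModules * nSamples), nModules, nSamples)
  expr <- latent[module, , drop = FALSE] +
    matrix(stats::rnorm(nGenes * nSamples, sd = noiseSd), nGenes, nSamples)
  dimnames(expr) <- list(paste0("g", seq_len(nGenes)),
                         paste0("s", seq_len(nSamples)))
  attr(expr, "module") <- module
  expr
}
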