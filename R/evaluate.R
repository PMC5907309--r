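# Evaluation harness: run dynamic counting along a script, periodically
# recount statically from scratch, and report the accuracy of the dynamic
# F2 count relative to the static one.

#' Dynamic-vs-static accuracy
#'
#' `100 * cDynamic / cStatic`, the dynamic count as a percentage of the
#' statically recomputed count on the same topology; 100 when both counts
#' are zero (perfect agreement on an empty result). Values above 100 are
#' possible — the static reference is itself a greedy heuristic — and are
#' reported as-is, never clamped.
#'
#' @param cDynamic,cStatic non-negative counts (vectorised).
#' @return numeric percentage(s).
#' @examples
#' accuracy(97, 100)
#' accuracy(0, 0)
#' @export
accuracy <- function(cDynamic, cStatic) {
  ifelse(cStatic == 0 & cDynamic == 0, 100, 100 * cDynamic / cStatic)
}

#' Run a dynamic-counting accuracy experiment
#'
#' For every (model, seed) configuration: generate a network, compile a
#' degree-preserving shuffle script, initialise a dynamic counter per
#' motif, apply the script, and at each checkpoint compare the dynamically
#' maintained counts against a fresh static recount (full enumeration plus
#' greedy) of the current topology. The final operation is always a
#' checkpoint. F1 accuracy is exactly 100 at every checkpoint (the F1
#' update is exact); F2 accuracy measures the drift of the local repair
#' heuristic relative to the static greedy.
#'
#' @param models subset of `c("er", "ws", "ba")`.
#' @param size,degree network size and target average degree.
#' @param nOps edit-script length (divisible by 4).
#' @param checkpointEvery static-recount period in edit operations.
#' @param motifs named list of [Motif-class] objects
#'   (default [basicMotifs()]).
#' @param seeds integer vector; one network + script per (model, seed).
#' @param includeStart also record a step-0 checkpoint.
#' @param wsRewire Watts-Strogatz rewiring probability.
#' @param tieBreak greedy tie-break policy for both the dynamic and the
#'   static side (deterministic `"id"` default, so step-0 accuracy is
#'   exactly 100).
#' @param verbose print one progress line per (model, seed, motif).
#' @return a `data.frame` with one row per (model, seed, motif,
#'   checkpoint): columns `model`, `size`, `degree`, `seed`, `motif`,
#'   `step`, `f1Dynamic`, `f1Static`, `f2Dynamic`, `f2Static`,
#'   `accuracyF1`, `accuracyF2`.
#' @examples
#' rep <- runExperiment("er", size = 60, degree = 6, nOps = 40,
#'                      checkpointEvery = 20, seeds = 1,
#'                      motifs = basicMotifs()["triangle"])
#' rep[, c("motif", "step", "f2Dynamic", "f2Static", "accuracyF2")]
#' @export
runExperiment <- function(models = c("er", "ws", "ba"), size, degree,
                          nOps = 1000, checkpointEvery = 100,
                          motifs = basicMotifs(), seeds = 1:5,
                          includeStart = FALSE, wsRewire = 0.1,
                          tieBreak = c("id", "random"), verbose = FALSE) {
  models <- match.arg(models, several.ok = TRUE)
  tieBreak <- match.arg(tieBreak)
  if (is(motifs, "Motif")) motifs <- list(motif = motifs)
  if (is.null(names(motifs)))
    names(motifs) <- vapply(motifs, function(m) m@name, character(1))
  steps <- unique(c(seq(checkpointEvery, nOps, by = checkpointEvery), nOps))
  steps <- steps[steps >= 1]
  rows <- list()
  for (model in models) {
    for (seed in seeds) {
      g0 <- generateNetwork(model, size = size, degree = degree, seed = seed,
                            wsRewire = wsRewire)
      script <- shuffleScript(g0, nOps = nOps, seed = seed + 500000L)
      for (mn in names(motifs)) {
        m <- motifs[[mn]]
        ctr <- dynamicMotifCounter(g0, m, tieBreak = tieBreak)
        at <- if (includeStart) c(0L, steps) else steps
        prev <- 0L
        for (s in at) {
          if (s > prev) {
            chunk <- script[(prev + 1L):s, , drop = FALSE]
            class(chunk) <- c("editScript", "data.frame")
            applyEditScript(ctr, chunk)
            prev <- s
          }
          st <- motifCount(currentGraph(ctr), m, tieBreak = tieBreak)
          cts <- .eng_counts(ctr@ptr)
          rows[[length(rows) + 1L]] <- data.frame(
            model = model, size = size, degree = degree, seed = seed,
            motif = mn, step = s,
            f1Dynamic = unname(cts["f1"]), f1Static = st$f1,
            f2Dynamic = unname(cts["f2"]), f2Static = st$f2,
            accuracyF1 = accuracy(unname(cts["f1"]), st$f1),
            accuracyF2 = accuracy(unname(cts["f2"]), st$f2),
            stringsAsFactors = FALSE)
        }
        if (verbose)
          message(sprintf("%s seed %d motif %-8s final F2 acc %.2f%%",
                          model, seed, mn,
                          rows[[length(rows)]]$accuracyF2))
        rm(ctr)
        if (size * degree > 4000) gc(FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Summarise the final-checkpoint accuracy of an experiment report
#'
#' @param report output of [runExperiment()].
#' @return a list with the final-step rows (`final`), the minimum and mean
#'   final F2 accuracy over all runs and motifs (`minF2`, `meanF2`), and
#'   the per-motif mean final F2 accuracy (`byMotif`).
#' @export
summarizeAccuracy <- function(report) {
  fin <- do.call(rbind, lapply(
    split(report, list(report$model, report$seed, report$motif), drop = TRUE),
    function(d) d[which.max(d$step), , drop = FALSE]))
  rownames(fin) <- NULL
  list(final = fin,
       minF2 = min(fin$accuracyF2),
       meanF2 = mean(fin$accuracyF2),
       byMotif = tapply(fin$accuracyF2, fin$motif, mean))
}
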