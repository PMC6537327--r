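# Gold-standard construction: candidate selection, cutoff calibration,
# labeling, and restriction to the genes of a given dataset.

#' Select the candidate edges of a confidence-scored network
#'
#' Takes the first `n` edges. By default "first" means file order, which for
#' ranked network downloads is the intended candidate prefix; alternatively
#' the top `n` by descending confidence.
#'
#' @param edges `data.frame` `gene_a`, `gene_b`, `confidence` (see
#'   [readEdgeList()]).
#' @param n number of candidates; default 100000. Larger than the list
#'   clamps with a warning.
#' @param order `"file"` (default) or `"confidence"` (descending, stable).
#' @return The selected edges, same columns, `min(n, nrow(edges))` rows.
#' @export
takeCandidateEdges <- function(edges, n = 100000L,
                               order = c("file", "confidence")) {
  order <- match.arg(order)
  .checkEdgeList(edges)
  if (length(n) != 1L || !is.finite(n) || n <= 0)
    .configError("n must be a positive integer, got %s", format(n))
  if (order == "confidence")
    edges <- edges[base::order(-edges$confidence), , drop = FALSE]
  if (n > nrow(edges)) {
    warning(sprintf("requested %d candidate edges but only %d available; using all",
                    as.integer(n), nrow(edges)), call. = FALSE)
    n <- nrow(edges)
  }
  out <- edges[seq_len(n), , drop = FALSE]
  rownames(out) <- NULL
  .log("candidate edges: kept %d of %d (%s order)", nrow(out),
       nrow(edges), order)
  out
}

#' Calibrate the true/false confidence cutoffs to balance label counts
#'
#' Iterative balancing of the two thresholds: starting from `low0` / `high0`,
#' each iteration counts prospective *true* edges (confidence > high) and
#' *false* edges (confidence < low). If the larger count exceeds the smaller
#' by more than `balanceTol`-fold, the cutoff guarding the smaller set is
#' moved to admit more of it: the low cutoff is raised by `stepLow` when
#' false edges are in deficit, otherwise the high cutoff is lowered by
#' `stepHigh`. One single-sided move per iteration keeps the schedule
#' deterministic. The procedure fails (classed
#' `coexBenchCalibrationError`, carrying the last cutoffs and counts) if the
#' cutoffs collide, leave \[0, 1\], or `maxIter` is reached.
#'
#' @param edges edge `data.frame` (or bare numeric confidence vector).
#' @param low0,high0 starting cutoffs; defaults 0.01 and 0.7.
#' @param stepLow,stepHigh per-iteration increments; defaults 0.005 and 0.05.
#' @param balanceTol stop once `max(nTrue, nFalse) / min(...) <= balanceTol`;
#'   default 1.25.
#' @param maxIter non-termination guard.
#' @return list with `cutoffFalse`, `cutoffTrue`, `nTrue`, `nFalse`,
#'   `iterations`.
#' @export
calibrateCutoffs <- function(edges, low0 = 0.01, high0 = 0.7,
                             stepLow = 0.005, stepHigh = 0.05,
                             balanceTol = 1.25, maxIter = 10000L) {
  conf <- if (is.numeric(edges)) edges else .checkEdgeList(edges)$confidence
  if (!(low0 >= 0 && low0 < high0 && high0 <= 1))
    .configError("need 0 <= low0 < high0 <= 1 (got %g, %g)", low0, high0)
  if (stepLow <= 0 || stepHigh <= 0)
    .configError("cutoff steps must be positive")
  if (balanceTol < 1)
    .configError("balanceTol must be >= 1")
  low <- low0; high <- high0
  for (iter in seq_len(maxIter)) {
    nTrue <- sum(conf > high)
    nFalse <- sum(conf < low)
    ratio <- max(nTrue, nFalse) / max(1L, min(nTrue, nFalse))
    if (ratio <= balanceTol) {
      .log("calibration converged after %d iteration(s): low=%g high=%g (%d true / %d false)",
           iter - 1L, low, high, nTrue, nFalse)
      return(list(cutoffFalse = low, cutoffTrue = high,
                  nTrue = nTrue, nFalse = nFalse, iterations = iter - 1L))
    }
    if (nTrue > nFalse) low <- low + stepLow else high <- high - stepHigh
    if (low >= high || low < 0 || low > 1 || high < 0 || high > 1)
      .err("coexBenchCalibrationError",
           paste("cutoff calibration failed: cutoffs collided or left [0,1]",
                 "at low=%g high=%g (last counts: %d true / %d false,",
                 "iteration %d)"),
           low, high, nTrue, nFalse, iter,
           data = list(cutoffFalse = low, cutoffTrue = high,
                       nTrue = nTrue, nFalse = nFalse, iterations = iter))
  }
  .err("coexBenchCalibrationError",
       "cutoff calibration did not terminate within %d iterations (low=%g high=%g)",
       maxIter, low, high,
       data = list(cutoffFalse = low, cutoffTrue = high,
                   iterations = maxIter))
}

#' Label edges into a gold standard by confidence thresholds
#'
#' Confidence strictly above `cutoffTrue` labels an edge *true* (1), strictly
#' below `cutoffFalse` labels it *false* (0); mid-range edges are discarded.
#' Both label classes must end up non-empty, otherwise the standard is
#' unusable for ROC analysis and an error is raised.
#'
#' @param edges edge `data.frame` (`gene_a`, `gene_b`, `confidence`).
#' @param cutoffTrue,cutoffFalse thresholds; defaults 0.5 and 0.025.
#' @return A [GoldStandard-class].
#' @export
buildGoldStandard <- function(edges, cutoffTrue = 0.5, cutoffFalse = 0.025) {
  .checkEdgeList(edges)
  if (cutoffFalse >= cutoffTrue)
    .configError("cutoffFalse (%g) must be below cutoffTrue (%g)",
                 cutoffFalse, cutoffTrue)
  lab <- ifelse(edges$confidence > cutoffTrue, 1L,
                ifelse(edges$confidence < cutoffFalse, 0L, NA_integer_))
  keep <- !is.na(lab)
  out <- edges[keep, c("gene_a", "gene_b", "confidence"), drop = FALSE]
  out$label <- lab[keep]
  rownames(out) <- NULL
  if (sum(out$label == 1) == 0L || sum(out$label == 0) == 0L)
    .validationError("gold standard needs both labels; got %d true / %d false",
                     sum(out$label == 1), sum(out$label == 0))
  .log("gold standard: %d true / %d false edges (dropped %d mid-range)",
       sum(out$label == 1), sum(out$label == 0), sum(!keep))
  new("GoldStandard", edges = out, cutoffTrue = cutoffTrue,
      cutoffFalse = cutoffFalse)
}

#' @describeIn GoldStandard-class Keep only edges whose both genes are
#'   measured in the expression matrix (genes absent after e.g.
#'   low-expression filtering take their edges with them); errors if either
#'   label class empties.
#' @export
setMethod("restrictToDataset", signature("GoldStandard", "matrix"),
  function(gs, expr) {
    .checkExpression(expr, requireFinite = FALSE)
    e <- gs@edges
    keep <- e$gene_a %in% rownames(expr) & e$gene_b %in% rownames(expr)
    removed <- e[!keep, , drop = FALSE]
    .log("dataset restriction removed %d true and %d false edge(s)",
         sum(removed$label == 1), sum(removed$label == 0))
    e <- e[keep, , drop = FALSE]
    rownames(e) <- NULL
    if (sum(e$label == 1) == 0L || sum(e$label == 0) == 0L)
      .validationError(
        "restriction left %d true / %d false edges; both classes required",
        sum(e$label == 1), sum(e$label == 0))
    new("GoldStandard", edges = e, cutoffTrue = gs@cutoffTrue,
        cutoffFalse = gs@cutoffFalse)
  })
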