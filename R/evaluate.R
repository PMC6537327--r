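# Method comparison: ROC/AUC of edge scores against gold-standard labels and
# distribution summaries of the Spearman estimates.

#' ROC curve and AUC of scores against binary labels
#'
#' The AUC is computed by the rank (Mann-Whitney) formulation, which gives
#' tied score pairs exactly half credit; the emitted curve sweeps thresholds
#' over the distinct score values (tied scores enter together, producing
#' diagonal segments), so its trapezoidal area equals the AUC to machine
#' precision — an internal cross-check enforced by the class validity.
#'
#' @param scores numeric vector; higher = more evidence for label 1.
#' @param labels 0/1 vector, both classes present.
#' @param method label stored in the result.
#' @return A [RocResult-class].
#' @export
rocAuc <- function(scores, labels, method = "scores") {
  if (length(scores) != length(labels))
    .validationError("scores and labels must have equal length")
  if (anyNA(scores) || anyNA(labels))
    .validationError("missing values not supported")
  if (!all(labels %in% c(0, 1)))
    .validationError("labels must be 0/1")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L)
    .validationError("both label classes must be present (got %d/%d)", n1, n0)
  r <- rank(scores)
  aucVal <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  lastOfGroup <- c(s[-length(s)] != s[-1], TRUE)
  tpr <- cumsum(l == 1)[lastOfGroup] / n1
  fpr <- cumsum(l == 0)[lastOfGroup] / n0
  points <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
  new("RocResult", method = method, points = points, auc = aucVal,
      nTrue = as.integer(n1), nFalse = as.integer(n0))
}

.edgeKey <- function(e) paste(pmin(e$gene_a, e$gene_b),
                              pmax(e$gene_a, e$gene_b), e$label)

#' Compare adjustment methods by ROC/AUC on a shared gold standard
#'
#' All results must score the identical edge set (same pairs, same labels).
#' Returns one [RocResult-class] per method, sorted by AUC descending;
#' optionally writes per-method ROC point tables, an AUC summary TSV and a
#' curve plot.
#'
#' @param results named list of [CoexpressionResult-class] objects.
#' @param outDir optional output directory for TSV tables.
#' @param plot also render `roc_curves.png` into `outDir`.
#' @return list of [RocResult-class], AUC-descending.
#' @export
compareMethods <- function(results, outDir = NULL, plot = FALSE) {
  if (length(results) == 0L)
    .validationError("no methods to compare")
  if (is.null(names(results)) || !all(nzchar(names(results))))
    .configError("results must be a named list (method names)")
  keys <- lapply(results, function(r) .edgeKey(coexEdges(r)))
  ref <- keys[[1]]
  for (m in names(results)[-1]) {
    if (!setequal(ref, keys[[m]]) ||
        length(ref) != length(keys[[m]])) {
      diff <- union(setdiff(ref, keys[[m]]), setdiff(keys[[m]], ref))
      .validationError("edge sets differ between '%s' and '%s'; symmetric difference: %s",
                       names(results)[1], m,
                       paste(head(diff, 5), collapse = "; "))
    }
  }
  rocs <- lapply(names(results), function(m) {
    e <- coexEdges(results[[m]])
    rocAuc(e$score, e$label, method = m)
  })
  rocs <- rocs[order(-vapply(rocs, auc, numeric(1)))]
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    for (r in rocs)
      write.table(rocPoints(r),
                  file.path(outDir, paste0("roc_", r@method, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    summary <- data.frame(method = vapply(rocs, slot, character(1), "method"),
                          auc = vapply(rocs, auc, numeric(1)),
                          n_true = vapply(rocs, slot, integer(1), "nTrue"),
                          n_false = vapply(rocs, slot, integer(1), "nFalse"))
    write.table(summary, file.path(outDir, "auc_summary.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (plot)
      plotRocCurves(rocs, file.path(outDir, "roc_curves.png"))
  }
  rocs
}

#' Distribution summary of Spearman estimates per method and label
#'
#' Mean, standard deviation, mean absolute value and a fixed-break histogram
#' of the per-edge `rs` values, split by method and gold-standard label.
#' Shrinkage of the *true*-edge distribution toward zero relative to a
#' gentler method diagnoses overcorrection.
#'
#' @param results named list of [CoexpressionResult-class] objects.
#' @param bins histogram bin count over \[-1, 1\]; default 50.
#' @return A [DensitySummary-class].
#' @export
densitySummary <- function(results, bins = 50L) {
  if (length(results) == 0L)
    .validationError("at least one method is required")
  if (is.null(names(results)) || !all(nzchar(names(results))))
    .configError("results must be a named list (method names)")
  breaks <- seq(-1, 1, length.out = bins + 1L)
  rows <- list()
  hists <- list()
  for (m in names(results)) {
    e <- coexEdges(results[[m]])
    for (lab in c(1, 0)) {
      v <- e$rs[e$label == lab]
      if (length(v) == 0L) next
      rows[[paste(m, lab)]] <- data.frame(
        method = m, label = lab, n = length(v), mean = mean(v),
        sd = if (length(v) > 1) sd(v) else NA_real_, meanAbs = mean(abs(v)))
      hists[[paste0(m, ".", lab)]] <-
        hist(pmin(pmax(v, -1), 1), breaks = breaks, plot = FALSE)$counts
    }
  }
  new("DensitySummary", stats = do.call(rbind, c(rows, make.row.names = FALSE)),
      histograms = hists, breaks = breaks)
}

#' Plot ROC curves for a set of methods
#'
#' Side-effect-only rendering (base graphics); never required by any
#' computation.
#'
#' @param rocs list of [RocResult-class] objects.
#' @param file optional PNG path; when `NULL`, draws on the active device.
#' @return `NULL`, invisibly.
#' @export
plotRocCurves <- function(rocs, file = NULL) {
  if (!is.null(file)) {
    png(file, width = 900, height = 900, res = 150)
    on.exit(dev.off(), add = TRUE)
  }
  cols <- seq_along(rocs)
  plot(c(0, 1), c(0, 1), type = "n", xlab = "False positive rate",
       ylab = "True positive rate", main = "Gold-standard edge recovery")
  abline(0, 1, lty = 3, col = "grey60")
  for (i in seq_along(rocs)) {
    p <- rocPoints(rocs[[i]])
    lines(p$fpr, p$tpr, col = cols[i], lwd = 2)
  }
  legend("bottomright",
         legend = sprintf("%s (AUC %.3f)",
                          vapply(rocs, slot, character(1), "method"),
                          vapply(rocs, auc, numeric(1))),
         col = cols, lwd = 2, bty = "n")
  invisible(NULL)
}
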