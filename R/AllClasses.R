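#' Gold standard of true and false gene-gene associations
#'
#' A calibrated set of gene pairs labeled 1 (*true* association, confidence
#' strictly above `cutoffTrue`) or 0 (*false* association, confidence strictly
#' below `cutoffFalse`). Pairs with confidence in the closed mid-range are not
#' part of the standard. Created by [buildGoldStandard()].
#'
#' @slot edges `data.frame` with columns `gene_a`, `gene_b`, `confidence`,
#'   `label`.
#' @slot cutoffTrue numeric(1), lower bound (exclusive) for *true* edges.
#' @slot cutoffFalse numeric(1), upper bound (exclusive) for *false* edges.
#' @exportClass GoldStandard
setClass("GoldStandard",
  slots = c(edges = "data.frame", cutoffTrue = "numeric",
            cutoffFalse = "numeric"))

setValidity("GoldStandard", function(object) {
  e <- object@edges
  if (!all(c("gene_a", "gene_b", "confidence", "label") %in% names(e)))
    return("edges must have columns gene_a, gene_b, confidence, label")
  if (length(object@cutoffTrue) != 1L || length(object@cutoffFalse) != 1L)
    return("cutoffs must be scalars")
  if (object@cutoffFalse >= object@cutoffTrue)
    return("cutoffFalse must be strictly below cutoffTrue")
  if (!all(e$label %in% c(0, 1)))
    return("labels must be 0 or 1")
  if (any(e$label == 1 & e$confidence <= object@cutoffTrue) ||
      any(e$label == 0 & e$confidence >= object@cutoffFalse))
    return("labels inconsistent with cutoffs")
  TRUE
})

#' Confounder design matrix for residualization
#'
#' Samples-by-confounders design: treatment-coded covariate indicators,
#' continuous covariates, principal-component scores or hidden factors, plus
#' an intercept column. Created by [buildDesign()], [computePCs()] or
#' [designFromMatrix()].
#'
#' @slot design numeric matrix, samples x columns, sample ids as rownames.
#' @slot includesIntercept logical(1).
#' @slot droppedSamples character vector of sample ids excluded because a
#'   requested covariate was missing.
#' @slot info list of construction metadata (dropped columns, explained
#'   variance for PC designs, ...).
#' @exportClass ConfounderDesign
setClass("ConfounderDesign",
  slots = c(design = "matrix", includesIntercept = "logical",
            droppedSamples = "character", info = "list"),
  prototype = prototype(includesIntercept = TRUE,
                        droppedSamples = character(), info = list()))

setValidity("ConfounderDesign", function(object) {
  d <- object@design
  if (!is.numeric(d) || ncol(d) < 1L)
    return("design must be a numeric matrix with at least one column")
  if (is.null(rownames(d)))
    return("design rows must be named by sample identifiers")
  nonInt <- d[, !colnames(d) %in% "(Intercept)", drop = FALSE]
  if (ncol(nonInt) > 0 && nrow(d) > 1) {
    rng <- apply(nonInt, 2, function(v) diff(range(v)))
    if (any(rng == 0))
      return(paste("constant non-intercept column(s):",
                   paste(colnames(nonInt)[rng == 0], collapse = ", ")))
  }
  TRUE
})

#' Per-gene OLS fit of expression on a confounder design
#'
#' Holds the coefficient matrix and the residual matrix of gene-by-gene
#' ordinary least squares of expression on a [ConfounderDesign-class]. The
#' residuals are the adjusted expression. Created by [residualize()].
#'
#' @slot coefficients numeric matrix, genes x design columns.
#' @slot residuals numeric matrix, genes x samples (same dimnames as the
#'   input expression, up to samples dropped by the design).
#' @slot design the [ConfounderDesign-class] used for the fit.
#' @exportClass ResidualFit
setClass("ResidualFit",
  slots = c(coefficients = "matrix", residuals = "matrix",
            design = "ConfounderDesign"))

setValidity("ResidualFit", function(object) {
  if (nrow(object@coefficients) != nrow(object@residuals))
    return("coefficients and residuals must cover the same genes")
  if (ncol(object@residuals) != nrow(object@design@design))
    return("residual columns must match the design's samples")
  TRUE
})

#' Spearman scores of gold-standard edges in one expression matrix
#'
#' One row per gold-standard edge: the Spearman estimate, its t-approximation
#' p-value, the Benjamini-Hochberg adjusted p-value across all scored edges,
#' and the -log10 score (capped at `scoreCap`). Created by [scoreEdges()].
#'
#' @slot edges `data.frame` with columns `gene_a`, `gene_b`, `label`, `rs`,
#'   `p`, `p_adj`, `score`.
#' @slot scoreCap numeric(1), cap applied to the -log10 score (and floor
#'   `10^-scoreCap` applied to adjusted p-values).
#' @slot method character(1), label of the adjustment that produced the
#'   expression matrix.
#' @exportClass CoexpressionResult
setClass("CoexpressionResult",
  slots = c(edges = "data.frame", scoreCap = "numeric", method = "character"))

setValidity("CoexpressionResult", function(object) {
  e <- object@edges
  need <- c("gene_a", "gene_b", "label", "rs", "p", "p_adj", "score")
  if (!all(need %in% names(e)))
    return(paste("edges must have columns", paste(need, collapse = ", ")))
  if (any(abs(e$rs) > 1 + 1e-12)) return("|rs| must be <= 1")
  if (any(e$p_adj < e$p - 1e-15)) return("adjusted p must be >= raw p")
  if (any(e$score < 0) || any(e$score > object@scoreCap + 1e-12))
    return("scores must lie in [0, scoreCap]")
  TRUE
})

#' ROC curve and AUC of edge scores against gold-standard labels
#'
#' The curve runs from (0,0) to (1,1) over descending score thresholds; tied
#' scores enter together, so the trapezoidal area under the curve equals the
#' Mann-Whitney statistic with half-credit for ties, which is how `auc` is
#' computed. Created by [rocAuc()].
#'
#' @slot method character(1).
#' @slot points `data.frame` with columns `fpr`, `tpr`.
#' @slot auc numeric(1) in \[0, 1\].
#' @slot nTrue,nFalse integer(1), label counts.
#' @exportClass RocResult
setClass("RocResult",
  slots = c(method = "character", points = "data.frame", auc = "numeric",
            nTrue = "integer", nFalse = "integer"))

setValidity("RocResult", function(object) {
  p <- object@points
  if (!all(c("fpr", "tpr") %in% names(p)))
    return("points must have columns fpr, tpr")
  if (any(diff(p$fpr) < 0) || any(diff(p$tpr) < 0))
    return("ROC points must be monotone non-decreasing")
  if (abs(p$fpr[1]) > 0 || abs(p$tpr[1]) > 0 ||
      abs(p$fpr[nrow(p)] - 1) > 1e-12 || abs(p$tpr[nrow(p)] - 1) > 1e-12)
    return("ROC curve must run from (0,0) to (1,1)")
  trap <- sum(diff(p$fpr) * (p$tpr[-1] + p$tpr[-nrow(p)]) / 2)
  if (abs(trap - object@auc) > 1e-12)
    return("trapezoidal area of points must equal auc")
  if (object@nTrue < 1L || object@nFalse < 1L)
    return("both label classes must be present")
  TRUE
})

#' Summary of Spearman-estimate distributions per method and label
#'
#' Mean, standard deviation and histogram of the per-edge Spearman estimates,
#' split by adjustment method and gold-standard label; the device for
#' diagnosing overcorrection (true-edge correlations shrunk toward zero).
#' Created by [densitySummary()].
#'
#' @slot stats `data.frame` with columns `method`, `label`, `n`, `mean`,
#'   `sd`, `meanAbs`.
#' @slot histograms named list (method.label) of histogram count vectors on
#'   the shared `breaks`.
#' @slot breaks numeric vector of histogram break points on \[-1, 1\].
#' @exportClass DensitySummary
setClass("DensitySummary",
  slots = c(stats = "data.frame", histograms = "list", breaks = "numeric"))

#' Synthetic benchmark dataset with planted structure
#'
#' Expression with planted co-expression modules, batch artefacts and
#' (optionally) hidden confounders; the matching phenotype table; a
#' confidence-scored edge list GIANT-like in shape; the generative truth
#' labels; and the full generative parameter record. Created by
#' [generateSynthetic()].
#'
#' @slot expr numeric matrix, genes x samples.
#' @slot pheno `data.frame` of per-sample covariates (sample rownames).
#' @slot edges `data.frame` `gene_a`, `gene_b`, `confidence` (descending
#'   confidence order, as confidence-ranked network downloads are shipped).
#' @slot truth `data.frame` `gene_a`, `gene_b`, `label` for the planted true
#'   (1) and false (0) pairs.
#' @slot params list of generative parameters (module assignment, loadings,
#'   batch coefficients, hidden-factor loadings).
#' @slot config the [syntheticConfig()] list that produced the dataset.
#' @exportClass SyntheticDataset
setClass("SyntheticDataset",
  slots = c(expr = "matrix", pheno = "data.frame", edges = "data.frame",
            truth = "data.frame", params = "list", config = "list"))

setValidity("SyntheticDataset", function(object) {
  genes <- rownames(object@expr)
  if (!all(object@edges$gene_a %in% genes) ||
      !all(object@edges$gene_b %in% genes))
    return("every edge gene must exist in the expression matrix")
  if (!all(object@truth$label %in% c(0, 1)))
    return("truth labels must be 0/1")
  TRUE
})
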