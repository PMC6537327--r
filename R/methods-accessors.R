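# Accessor methods and show() methods.

#' @rdname GoldStandard-class
#' @export
setMethod("goldEdges", "GoldStandard", function(object) object@edges)

#' @rdname GoldStandard-class
#' @export
setMethod("cutoffs", "GoldStandard", function(object)
  c(cutoffFalse = object@cutoffFalse, cutoffTrue = object@cutoffTrue))

#' @rdname GoldStandard-class
#' @export
setMethod("nTrueEdges", "GoldStandard", function(object)
  sum(object@edges$label == 1))

#' @rdname GoldStandard-class
#' @export
setMethod("nFalseEdges", "GoldStandard", function(object)
  sum(object@edges$label == 0))

setMethod("show", "GoldStandard", function(object) {
  cat("GoldStandard:", nrow(object@edges), "edges (",
      nTrueEdges(object), "true /", nFalseEdges(object), "false )\n")
  cat("  cutoffs: confidence >", object@cutoffTrue, "=> true;  <",
      object@cutoffFalse, "=> false\n")
})

#' @rdname ConfounderDesign-class
#' @export
setMethod("designMatrix", "ConfounderDesign", function(object) object@design)

setMethod("show", "ConfounderDesign", function(object) {
  cat("ConfounderDesign:", nrow(object@design), "samples x",
      ncol(object@design), "columns",
      if (object@includesIntercept) "(incl. intercept)" else "", "\n")
  cat("  columns:", paste(head(colnames(object@design), 8), collapse = ", "),
      if (ncol(object@design) > 8) "..." else "", "\n")
  if (length(object@droppedSamples))
    cat("  dropped samples (missing covariates):",
        length(object@droppedSamples), "\n")
})

#' @rdname ResidualFit-class
#' @param object a `ResidualFit`.
#' @param ... ignored.
#' @export
setMethod("residuals", "ResidualFit", function(object, ...) object@residuals)

#' @rdname ResidualFit-class
#' @export
setMethod("coef", "ResidualFit", function(object, ...) object@coefficients)

setMethod("show", "ResidualFit", function(object) {
  cat("ResidualFit:", nrow(object@residuals), "genes x",
      ncol(object@residuals), "samples;",
      ncol(object@coefficients), "coefficients per gene\n")
})

#' @rdname CoexpressionResult-class
#' @export
setMethod("coexEdges", "CoexpressionResult", function(object) object@edges)

setMethod("show", "CoexpressionResult", function(object) {
  e <- object@edges
  cat("CoexpressionResult [", object@method, "]: ", nrow(e), " edges (",
      sum(e$label == 1), " true / ", sum(e$label == 0), " false)\n", sep = "")
  cat(sprintf("  mean |rs| true: %.3f  false: %.3f\n",
              mean(abs(e$rs[e$label == 1])), mean(abs(e$rs[e$label == 0]))))
})

#' @rdname RocResult-class
#' @export
setMethod("rocPoints", "RocResult", function(object) object@points)

#' @rdname RocResult-class
#' @export
setMethod("auc", "RocResult", function(object) object@auc)

setMethod("show", "RocResult", function(object) {
  cat(sprintf("RocResult [%s]: AUC = %.4f (%d true / %d false edges)\n",
              object@method, object@auc, object@nTrue, object@nFalse))
})

setMethod("show", "DensitySummary", function(object) {
  cat("DensitySummary over", length(unique(object@stats$method)),
      "method(s):\n")
  print(object@stats, row.names = FALSE)
})

#' @rdname SyntheticDataset-class
#' @export
setMethod("exprMatrix", "SyntheticDataset", function(object) object@expr)

#' @rdname SyntheticDataset-class
#' @export
setMethod("phenoTable", "SyntheticDataset", function(object) object@pheno)

#' @rdname SyntheticDataset-class
#' @export
setMethod("edgeList", "SyntheticDataset", function(object) object@edges)

#' @rdname SyntheticDataset-class
#' @export
setMethod("truthTable", "SyntheticDataset", function(object) object@truth)

#' @rdname SyntheticDataset-class
#' @export
setMethod("genParams", "SyntheticDataset", function(object) object@params)

setMethod("show", "SyntheticDataset", function(object) {
  cat("SyntheticDataset:", nrow(object@expr), "genes x", ncol(object@expr),
      "samples\n")
  cat("  planted pairs:", sum(object@truth$label == 1), "true /",
      sum(object@truth$label == 0), "false;",
      nrow(object@edges), "edges in list\n")
  cat("  covariates:", paste(colnames(object@pheno), collapse = ", "), "\n")
})
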