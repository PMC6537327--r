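# Internal condition constructors and shared validators.
#
# All user-facing failures are classed conditions so callers (and tests) can
# distinguish format, parse, validation, configuration and calibration
# failures without matching message text.

.err <- function(class, msg, ..., data = list()) {
  cond <- structure(
    class = c(class, "coexBenchError", "error", "condition"),
    c(list(message = sprintf(msg, ...), call = sys.call(-1)), data)
  )
  stop(cond)
}

.formatError      <- function(msg, ...) .err("coexBenchFormatError", msg, ...)
.parseError       <- function(msg, ...) .err("coexBenchParseError", msg, ...)
.validationError  <- function(msg, ...) .err("coexBenchValidationError", msg, ...)
.configError      <- function(msg, ...) .err("coexBenchConfigError", msg, ...)

.log <- function(msg, ...) {
  if (!isTRUE(getOption("coexBench.quiet", FALSE)))
    message("coexBench | ", sprintf(msg, ...))
  invisible(NULL)
}

# Expression matrices are plain numeric matrices, genes in rows, samples in
# columns, with unique dimnames and finite values throughout.
.checkExpression <- function(expr, what = "expression matrix",
                             requireFinite = TRUE) {
  if (!is.matrix(expr) || !is.numeric(expr))
    .validationError("%s must be a numeric matrix (genes x samples)", what)
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    .validationError("%s must carry gene rownames and sample colnames", what)
  if (anyDuplicated(rownames(expr)))
    .validationError("duplicate gene identifiers in %s: %s", what,
                     paste(unique(rownames(expr)[duplicated(rownames(expr))]),
                           collapse = ", "))
  if (anyDuplicated(colnames(expr)))
    .validationError("duplicate sample identifiers in %s", what)
  if (requireFinite && !all(is.finite(expr)))
    .validationError("%s contains non-finite values", what)
  invisible(expr)
}

.checkPhenotypes <- function(pheno) {
  if (!is.data.frame(pheno))
    .validationError("phenotype table must be a data.frame")
  if (is.null(rownames(pheno)))
    .validationError("phenotype table must carry sample identifiers as rownames")
  invisible(pheno)
}

.checkEdgeList <- function(edges, what = "edge list") {
  if (!is.data.frame(edges) ||
      !all(c("gene_a", "gene_b", "confidence") %in% names(edges)))
    .validationError("%s must have columns gene_a, gene_b, confidence", what)
  conf <- edges$confidence
  if (!is.numeric(conf) || anyNA(conf))
    .validationError("%s confidences must be numeric and non-missing", what)
  bad <- conf < 0 | conf > 1
  if (any(bad))
    .validationError("%s has %d confidence value(s) outside [0, 1] (first at row %d)",
                     what, sum(bad), which(bad)[1])
  self <- edges$gene_a == edges$gene_b
  if (any(self))
    .validationError("%s contains self-edge(s), e.g. row %d (%s)", what,
                     which(self)[1], edges$gene_a[which(self)[1]])
  key <- paste(pmin(edges$gene_a, edges$gene_b),
               pmax(edges$gene_a, edges$gene_b))
  if (anyDuplicated(key))
    .validationError("%s contains duplicated unordered pair(s), e.g. %s", what,
                     key[duplicated(key)][1])
  invisible(edges)
}

#' Align expression, phenotype and factor tables on shared samples
#'
#' Alignment is by identifier intersection: mismatched order is silently
#' reordered, samples absent from any supplied table are dropped (with a
#' logged count), and an empty intersection is an error.
#'
#' @param expr numeric matrix, genes x samples.
#' @param pheno optional phenotype `data.frame` with sample rownames.
#' @param factors optional hidden-factor matrix, factors x samples.
#' @return A list with elements `expr`, `pheno`, `factors`, all restricted to
#'   the shared samples in the expression matrix's order.
#' @export
alignSamples <- function(expr, pheno = NULL, factors = NULL) {
  ids <- colnames(expr)
  if (!is.null(pheno)) ids <- intersect(ids, rownames(pheno))
  if (!is.null(factors)) ids <- intersect(ids, colnames(factors))
  if (length(ids) == 0)
    .validationError("no samples shared between expression and covariate tables")
  dropped <- length(colnames(expr)) - length(ids)
  if (dropped > 0)
    .log("sample alignment dropped %d of %d expression samples",
         dropped, ncol(expr))
  list(
    expr = expr[, ids, drop = FALSE],
    pheno = if (is.null(pheno)) NULL else pheno[ids, , drop = FALSE],
    factors = if (is.null(factors)) NULL else factors[, ids, drop = FALSE]
  )
}
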