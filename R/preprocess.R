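# Expression pre-processing: low-expression filtering, within-dataset
# quantile normalization, and per-gene mapping to a standard normal.

#' Drop genes with low average expression
#'
#' Keeps genes whose row mean is strictly greater than `minMean` (in the
#' units of the input, conventionally RPKM for raw matrices).
#'
#' @param expr numeric matrix, genes x samples.
#' @param minMean threshold on the row mean; default 0.1.
#' @return The filtered matrix.
#' @export
filterLowExpression <- function(expr, minMean = 0.1) {
  .checkExpression(expr)
  keep <- rowMeans(expr) > minMean
  if (!any(keep))
    .validationError("low-expression filter (> %g) removed every gene", minMean)
  .log("low-expression filter (> %g): removed %d of %d genes",
       minMean, sum(!keep), nrow(expr))
  expr[keep, , drop = FALSE]
}

#' Quantile-normalize sample columns
#'
#' Forces every sample column onto the common reference distribution given by
#' the across-sample mean of order statistics. Ties within a column receive
#' the mean of the reference values their sorted positions span, so tied
#' input values stay tied.
#'
#' @param expr numeric matrix, genes x samples (>= 2 samples).
#' @return Matrix of the same shape; all columns share the same sorted
#'   profile.
#' @export
quantileNormalize <- function(expr) {
  .checkExpression(expr)
  if (ncol(expr) < 2L)
    .validationError("quantile normalization needs >= 2 samples")
  ref <- rowMeans(apply(expr, 2, sort))
  out <- apply(expr, 2, function(v) {
    assigned <- numeric(length(v))
    assigned[order(v)] <- ref
    ave(assigned, v)               # tie groups -> mean of spanned ref values
  })
  dimnames(out) <- dimnames(expr)
  out
}

#' Map each gene row to a standard normal distribution
#'
#' Rank-based inverse normal transform: per gene, values are replaced by
#' `qnorm((r - offset) / (n - 2*offset + 1))` of their average-tied ranks
#' `r`. The default offset 3/8 is the Blom convention.
#'
#' @param expr numeric matrix, genes x samples (>= 3 samples).
#' @param offset rank offset; default `3/8`.
#' @return Matrix of the same shape, each row approximately standard normal.
#' @export
inverseNormalTransform <- function(expr, offset = 3 / 8) {
  .checkExpression(expr)
  n <- ncol(expr)
  if (n < 3L)
    .validationError("inverse normal transform needs >= 3 samples")
  const <- apply(expr, 1, function(v) diff(range(v)) == 0)
  if (any(const))
    .validationError("constant gene row(s), rank transform undefined: %s",
                     paste(rownames(expr)[const], collapse = ", "))
  ranks <- t(apply(expr, 1, rank))   # average ranks on ties
  out <- qnorm((ranks - offset) / (n - 2 * offset + 1))
  dimnames(out) <- dimnames(expr)
  out
}

#' Filter samples by a phenotype predicate
#'
#' Generic sample-quality filter (e.g. keep RIN > 6 when a RIN column is
#' available): the predicate receives the phenotype table and returns a
#' logical keep-vector; samples with `NA` predicate values are dropped.
#'
#' @param expr numeric matrix, genes x samples.
#' @param pheno phenotype `data.frame`, sample rownames.
#' @param predicate `function(pheno) -> logical` of length `nrow(pheno)`.
#' @return list with filtered `expr` and `pheno`.
#' @export
filterSamples <- function(expr, pheno, predicate) {
  .checkPhenotypes(pheno)
  al <- alignSamples(expr, pheno)
  keep <- predicate(al$pheno)
  if (!is.logical(keep) || length(keep) != nrow(al$pheno))
    .configError("predicate must return one logical per sample")
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) .validationError("sample predicate removed every sample")
  .log("sample filter removed %d of %d samples", sum(!keep), length(keep))
  list(expr = al$expr[, keep, drop = FALSE],
       pheno = al$pheno[keep, , drop = FALSE])
}
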