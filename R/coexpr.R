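# Spearman scoring of gold-standard edges: rank correlation with
# t-approximation p-values, BH correction across all scored edges, and the
# -log10 score.

#' Spearman correlation with a t-approximation p-value
#'
#' Ranks use the average-rank convention on ties; the estimate is the Pearson
#' correlation of the rank vectors (the covariance-over-sd form, valid with
#' ties; on tie-free data it coincides with `1 - 6*sum(d^2)/(n(n^2-1))`).
#' The two-sided p-value comes from `t = rs * sqrt((n-2)/(1-rs^2))` on `n-2`
#' degrees of freedom; `|rs| = 1` gives p = 0 (callers flooring p for
#' log-scores must do so themselves, see [scoreEdges()]).
#'
#' @param x,y numeric vectors of equal length `n >= 4`, neither constant.
#' @return list with elements `rs` and `p`.
#' @export
spearmanTest <- function(x, y) {
  if (length(x) != length(y))
    .validationError("x and y must have equal length (%d vs %d)",
                     length(x), length(y))
  n <- length(x)
  if (n < 4L)
    .validationError("Spearman test needs n >= 4 observations")
  if (anyNA(x) || anyNA(y))
    .validationError("missing values not supported")
  if (diff(range(x)) == 0 || diff(range(y)) == 0)
    .validationError("constant vector: Spearman correlation undefined")
  rx <- rank(x)
  ry <- rank(y)
  rs <- cor(rx, ry)
  p <- .spearmanPvalue(rs, n)
  list(rs = rs, p = p)
}

.spearmanPvalue <- function(rs, n) {
  rs <- pmin(1, pmax(-1, rs))
  p <- numeric(length(rs))
  exact1 <- abs(rs) >= 1
  p[exact1] <- 0
  tstat <- rs[!exact1] * sqrt((n - 2) / (1 - rs[!exact1]^2))
  p[!exact1] <- 2 * pt(-abs(tstat), df = n - 2)
  p
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment across the supplied family (delegates to
#' [stats::p.adjust()] after range validation).
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order, elementwise `>=` the input.
#' @export
bhAdjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p > 1))
    .validationError("p-values must be numeric in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Score every gold-standard edge in an expression matrix
#'
#' Computes the Spearman estimate and t-approximation p-value per edge
#' (vectorized: each involved gene row is rank-transformed once), adjusts
#' all p-values together with Benjamini-Hochberg — true and false edges form
#' one family — and scores each edge as `-log10(p_adj)`, with the adjusted
#' p floored at `10^-scoreCap` so scores stay finite at `|rs| = 1`.
#'
#' @param expr numeric matrix, genes x samples (>= 4 samples).
#' @param gs a [GoldStandard-class]; if it covers genes absent from `expr`
#'   it is restricted internally with a warning.
#' @param scoreCap cap on the -log10 score; default 320.
#' @param method label stored in the result (defaults to `"raw"`).
#' @return A [CoexpressionResult-class].
#' @export
scoreEdges <- function(expr, gs, scoreCap = 320, method = "raw") {
  .checkExpression(expr)
  if (!is(gs, "GoldStandard"))
    .validationError("gs must be a GoldStandard")
  if (scoreCap <= 0) .configError("scoreCap must be positive")
  n <- ncol(expr)
  if (n < 4L) .validationError("edge scoring needs >= 4 samples")
  e <- goldEdges(gs)
  if (!all(c(e$gene_a, e$gene_b) %in% rownames(expr))) {
    warning("gold standard covers genes absent from the expression matrix; restricting",
            call. = FALSE)
    gs <- restrictToDataset(gs, expr)
    e <- goldEdges(gs)
  }
  genes <- unique(c(e$gene_a, e$gene_b))
  sub <- expr[genes, , drop = FALSE]
  const <- apply(sub, 1, function(v) diff(range(v)) == 0)
  if (any(const))
    .validationError("constant gene row(s) among edge genes: %s",
                     paste(genes[const], collapse = ", "))
  R <- t(apply(sub, 1, rank))
  R <- R - rowMeans(R)
  norms <- sqrt(rowSums(R^2))
  ia <- match(e$gene_a, genes)
  ib <- match(e$gene_b, genes)
  rs <- rowSums(R[ia, , drop = FALSE] * R[ib, , drop = FALSE]) /
    (norms[ia] * norms[ib])
  p <- .spearmanPvalue(rs, n)
  pAdj <- bhAdjust(p)
  floorP <- 10^(-scoreCap)
  score <- pmin(-log10(pmax(pAdj, floorP)), scoreCap)
  out <- data.frame(gene_a = e$gene_a, gene_b = e$gene_b, label = e$label,
                    rs = rs, p = p, p_adj = pAdj, score = score,
                    row.names = NULL)
  new("CoexpressionResult", edges = out, scoreCap = scoreCap,
      method = method)
}

#' Write a coexpression score table as TSV
#' @param result a [CoexpressionResult-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeScores <- function(result, path) {
  write.table(coexEdges(result), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
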