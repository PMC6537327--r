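# Residualization-based adjustment: confounder designs from known
# covariates, hidden factors or principal components; gene-by-gene OLS with
# the residual matrix as adjusted expression.

.encodeCovariate <- function(values, name) {
  if (is.numeric(values)) {
    m <- matrix(values, ncol = 1, dimnames = list(NULL, name))
    return(m)
  }
  f <- factor(values, levels = sort(unique(as.character(values))))
  if (nlevels(f) < 2L) return(NULL)
  mm <- model.matrix(~f)[, -1L, drop = FALSE]   # treatment coding, first
  colnames(mm) <- paste0(name, levels(f)[-1L])  # sorted level as reference
  mm
}

#' Build a confounder design from known covariates
#'
#' Categorical variables are expanded to treatment-coded indicators (the
#' first level in sorted order is the dropped reference); continuous
#' variables enter as-is; an intercept column is appended. Samples missing
#' any requested covariate are dropped (recorded in the object). A covariate
#' left with a single level after the drops is excluded with a warning;
#' constant continuous columns are likewise excluded.
#'
#' @param pheno phenotype `data.frame`, sample rownames, typed columns.
#' @param covariates character vector of variable names to include.
#' @return A [ConfounderDesign-class].
#' @export
buildDesign <- function(pheno, covariates) {
  .checkPhenotypes(pheno)
  absent <- setdiff(covariates, colnames(pheno))
  if (length(absent))
    .configError("covariate(s) not in phenotype table: %s",
                 paste(absent, collapse = ", "))
  if (length(covariates) == 0L)
    .configError("at least one covariate is required")
  sub <- pheno[, covariates, drop = FALSE]
  complete <- !Reduce(`|`, lapply(sub, is.na))
  dropped <- rownames(pheno)[!complete]
  if (length(dropped))
    .log("design construction dropped %d sample(s) with missing covariates",
         length(dropped))
  sub <- sub[complete, , drop = FALSE]
  if (nrow(sub) == 0L)
    .validationError("no samples left after dropping missing covariates")
  cols <- list()
  for (v in covariates) {
    enc <- .encodeCovariate(sub[[v]], v)
    if (is.null(enc) ||
        any(constant <- apply(enc, 2, function(x) diff(range(x)) == 0))) {
      if (!is.null(enc) && !all(constant)) {
        enc <- enc[, !constant, drop = FALSE]
      } else {
        warning(sprintf("covariate '%s' has a single level/value after sample drops; excluded",
                        v), call. = FALSE)
        next
      }
    }
    cols[[v]] <- enc
  }
  if (length(cols) == 0L)
    .validationError("empty design: every requested covariate degenerated")
  design <- cbind(`(Intercept)` = 1, do.call(cbind, cols))
  rownames(design) <- rownames(sub)
  new("ConfounderDesign", design = design, includesIntercept = TRUE,
      droppedSamples = dropped)
}

#' Wrap an arbitrary numeric matrix as a confounder design
#'
#' For hidden-factor (PEER-style) columns or any externally supplied
#' samples-by-confounders matrix. Constant columns are dropped with a
#' warning (they carry no adjustable signal); additional known covariates
#' can be appended treatment-coded.
#'
#' @param mat numeric matrix, samples x confounders, sample ids as rownames.
#' @param pheno optional phenotype table supplying `covariates`.
#' @param covariates optional covariate names to append (e.g. `"GENDER"`).
#' @param addIntercept append an intercept column (default `TRUE`).
#' @return A [ConfounderDesign-class].
#' @export
designFromMatrix <- function(mat, pheno = NULL, covariates = NULL,
                             addIntercept = TRUE) {
  if (!is.matrix(mat) || !is.numeric(mat) || is.null(rownames(mat)))
    .validationError("design matrix must be numeric with sample rownames")
  if (is.null(colnames(mat)))
    colnames(mat) <- paste0("C", seq_len(ncol(mat)))
  dropped <- character()
  if (length(covariates)) {
    if (is.null(pheno))
      .configError("covariates requested but no phenotype table supplied")
    cd <- buildDesign(pheno, covariates)
    ids <- intersect(rownames(mat), rownames(cd@design))
    if (length(ids) == 0L)
      .validationError("no shared samples between matrix and phenotypes")
    dropped <- setdiff(rownames(mat), ids)
    mat <- cbind(mat[ids, , drop = FALSE],
                 cd@design[ids, colnames(cd@design) != "(Intercept)",
                           drop = FALSE])
  }
  const <- apply(mat, 2, function(v) diff(range(v)) == 0)
  if (any(const)) {
    warning(sprintf("dropping constant design column(s): %s",
                    paste(colnames(mat)[const], collapse = ", ")),
            call. = FALSE)
    mat <- mat[, !const, drop = FALSE]
  }
  design <- if (addIntercept) cbind(`(Intercept)` = 1, mat) else mat
  if (ncol(design) == 0L) .validationError("empty design")
  new("ConfounderDesign", design = design, includesIntercept = addIntercept,
      droppedSamples = dropped)
}

#' Regress each gene on a confounder design and keep the residuals
#'
#' Ordinary least squares per gene (QR factorization, shared across genes).
#' The residual matrix is the adjusted expression. A rank-deficient design
#' has its collinear columns dropped with a warning; if that leaves only the
#' intercept the fit is refused.
#'
#' @param expr numeric matrix, genes x samples.
#' @param design a [ConfounderDesign-class] (samples must be a subset of the
#'   expression's; expression columns are aligned and, where necessary,
#'   dropped to match).
#' @return A [ResidualFit-class]; `residuals()` gives the adjusted matrix.
#' @export
residualize <- function(expr, design) {
  .checkExpression(expr)
  X <- design@design
  ids <- intersect(colnames(expr), rownames(X))
  if (length(ids) == 0L)
    .validationError("no shared samples between expression and design")
  if (length(ids) < ncol(expr))
    .log("residualize: %d expression sample(s) not covered by the design; dropped",
         ncol(expr) - length(ids))
  expr <- expr[, ids, drop = FALSE]
  X <- X[ids, , drop = FALSE]
  if (ncol(X) >= nrow(X))
    .validationError("more confounders (%d) than samples (%d)",
                     ncol(X) - design@includesIntercept, nrow(X))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    warning(sprintf("rank-deficient design; dropping collinear column(s): %s",
                    paste(aliased, collapse = ", ")), call. = FALSE)
    X <- X[, setdiff(colnames(X), aliased), drop = FALSE]
    if (identical(colnames(X), "(Intercept)"))
      .validationError("design collapsed to intercept-only after dropping collinear columns")
  }
  fit <- lm.fit(X, t(expr))
  coefs <- t(fit$coefficients)
  resid <- t(fit$residuals)
  dimnames(resid) <- dimnames(expr)
  rownames(coefs) <- rownames(expr)
  newDesign <- new("ConfounderDesign", design = X,
                   includesIntercept = design@includesIntercept,
                   droppedSamples = design@droppedSamples,
                   info = design@info)
  new("ResidualFit", coefficients = coefs, residuals = resid,
      design = newDesign)
}

.standardizeGenes <- function(expr) {
  s <- apply(expr, 1, sd)
  keep <- s > 0
  if (!all(keep)) {
    warning(sprintf("dropping %d constant gene(s) before PCA", sum(!keep)),
            call. = FALSE)
    expr <- expr[keep, , drop = FALSE]
    s <- s[keep]
  }
  (expr - rowMeans(expr)) / s
}

.pcaScores <- function(expr) {
  Z <- .standardizeGenes(expr)
  pc <- prcomp(t(Z), center = FALSE, scale. = FALSE)
  # resolve sign indeterminacy: largest-magnitude loading positive
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  pc
}

#' Principal-component scores of the samples as a confounder design
#'
#' PCs are computed on the gene-standardized matrix (each gene centered and
#' scaled to unit variance), so high-variance genes do not dominate; signs
#' are fixed by making each component's largest-magnitude gene loading
#' positive. Explained-variance fractions are logged and stored in the
#' design's `info`.
#'
#' @param expr numeric matrix, genes x samples.
#' @param k number of leading components, `k < min(genes, samples)`.
#' @return A [ConfounderDesign-class] with columns `PC1..PCk` plus intercept.
#' @export
computePCs <- function(expr, k) {
  .checkExpression(expr)
  if (length(k) != 1L || k < 1 || k >= min(dim(expr)))
    .configError("k must satisfy 1 <= k < min(genes, samples); got %s",
                 format(k))
  pc <- .pcaScores(expr)
  k <- as.integer(k)
  if (k > ncol(pc$x))
    .configError("k = %d exceeds the %d available components", k, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  .log("top %d PCs explain %.1f%% of variance", k, 100 * sum(expl[1:k]))
  design <- cbind(`(Intercept)` = 1, scores)
  rownames(design) <- colnames(expr)
  new("ConfounderDesign", design = design, includesIntercept = TRUE,
      droppedSamples = character(),
      info = list(explainedVariance = expl[seq_len(k)],
                  cumulativeVariance = cumsum(expl)))
}

#' Smallest number of PCs reaching a cumulative explained-variance fraction
#'
#' @param expr numeric matrix, genes x samples.
#' @param cumVarThreshold target fraction in (0, 1).
#' @return Integer `k`.
#' @export
chooseNumPCs <- function(expr, cumVarThreshold) {
  .checkExpression(expr)
  if (cumVarThreshold <= 0 || cumVarThreshold >= 1)
    .configError("cumVarThreshold must lie strictly in (0, 1)")
  pc <- .pcaScores(expr)
  cumVar <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  kMax <- min(dim(expr)) - 1L
  hit <- which(cumVar >= cumVarThreshold - 1e-12)
  if (length(hit) == 0L || hit[1] > kMax)
    .validationError("threshold %.3f unreachable with %d components",
                     cumVarThreshold, kMax)
  hit[1]
}

#' Adjust an expression matrix with one of the benchmarked methods
#'
#' * `"raw"`: no adjustment (returned unchanged; the benchmark baseline).
#' * `"LR"`: residualize on a design of known covariates from `pheno`.
#' * `"PEER"`: residualize on supplied hidden-factor columns (factors x
#'   samples, see [readFactors()]), plus any `covariates` (conventionally
#'   gender).
#' * `"PCA"`: residualize on the top `numPCs` principal components (or the
#'   count chosen by `cumVarThreshold`), plus any `covariates`.
#' * `"PCA_opt"`: as `"PCA"` but `numPCs` must be given explicitly (an
#'   externally optimized count).
#' * `"ComBat"`: iterative empirical-Bayes location/scale batch adjustment,
#'   see [combatIterative()]; configure via `combatConfig`.
#'
#' @param expr numeric matrix, genes x samples.
#' @param method one of `"raw"`, `"LR"`, `"PEER"`, `"PCA"`, `"PCA_opt"`,
#'   `"ComBat"`.
#' @param pheno phenotype `data.frame` (required for `"LR"`, `"ComBat"`, and
#'   whenever `covariates` are requested).
#' @param covariates covariate names: the design for `"LR"`, appended
#'   columns for `"PEER"`/`"PCA"`/`"PCA_opt"`.
#' @param factors hidden-factor matrix (factors x samples) for `"PEER"`.
#' @param numPCs explicit PC count for `"PCA"`/`"PCA_opt"`.
#' @param cumVarThreshold alternative to `numPCs` for `"PCA"`: pick the
#'   smallest count reaching this cumulative explained-variance fraction.
#' @param combatConfig a [combatConfig()] list for `"ComBat"`.
#' @return The adjusted genes x samples matrix.
#' @export
adjustExpression <- function(expr,
                             method = c("raw", "LR", "PEER", "PCA",
                                        "PCA_opt", "ComBat"),
                             pheno = NULL, covariates = NULL, factors = NULL,
                             numPCs = NULL, cumVarThreshold = NULL,
                             combatConfig = NULL) {
  method <- match.arg(method)
  .checkExpression(expr)
  if (method == "raw") return(expr)
  if (method == "LR") {
    if (is.null(pheno) || is.null(covariates))
      .configError("LR adjustment needs pheno and covariates")
    al <- alignSamples(expr, pheno)
    design <- buildDesign(al$pheno, covariates)
    return(residuals(residualize(al$expr, design)))
  }
  if (method == "PEER") {
    if (is.null(factors))
      .configError("PEER adjustment needs a hidden-factor matrix")
    al <- alignSamples(expr, pheno, factors)
    design <- designFromMatrix(t(al$factors), pheno = al$pheno,
                               covariates = covariates)
    return(residuals(residualize(al$expr, design)))
  }
  if (method %in% c("PCA", "PCA_opt")) {
    if (method == "PCA_opt" && is.null(numPCs))
      .configError("PCA_opt needs an explicit numPCs")
    al <- if (is.null(pheno)) list(expr = expr, pheno = NULL)
          else alignSamples(expr, pheno)
    k <- if (!is.null(numPCs)) numPCs
         else if (!is.null(cumVarThreshold)) chooseNumPCs(al$expr, cumVarThreshold)
         else .configError("PCA needs numPCs or cumVarThreshold")
    pcs <- computePCs(al$expr, k)
    scores <- pcs@design[, colnames(pcs@design) != "(Intercept)", drop = FALSE]
    design <- designFromMatrix(scores, pheno = al$pheno,
                               covariates = covariates)
    return(residuals(residualize(al$expr, design)))
  }
  # ComBat
  if (is.null(pheno) || is.null(combatConfig))
    .configError("ComBat adjustment needs pheno and a combatConfig")
  combatIterative(expr, pheno, combatConfig)
}
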