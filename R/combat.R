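# Empirical-Bayes location/scale batch adjustment with an iterative
# multi-batch scheme.
#
# Per-gene model in standardized space: Z_gj = gamma_gb + delta_gb * e_gj for
# sample j in batch b. Batch effects are shrunk with parametric EB priors
# (normal on gamma, inverse-gamma on delta^2, hyperparameters by method of
# moments, joint fixed-point iteration) and removed. Variance estimators use
# ML (1/n) denominators throughout so that a single-batch input, where there
# is nothing to estimate, is returned exactly unchanged.

#' Discretize continuous ischemic time into ComBat-ready bins
#'
#' Half-open bins `[k*binWidth, (k+1)*binWidth)` labeled `1..nBins`, with the
#' top bin absorbing everything beyond its start. Negative values clamp to
#' bin 1 with a warning; missing values propagate.
#'
#' @param values numeric vector (minutes between death and collection, for
#'   the canonical use).
#' @param binWidth bin width in the same units; default 300 minutes.
#' @param nBins number of bins; default 5.
#' @return Factor with levels `1..nBins`.
#' @export
discretizeIschemic <- function(values, binWidth = 300, nBins = 5L) {
  if (binWidth <= 0) .configError("binWidth must be positive")
  if (nBins < 2L) .configError("nBins must be >= 2")
  if (!is.numeric(values)) .validationError("values must be numeric")
  if (any(values < 0, na.rm = TRUE)) {
    warning("negative time value(s) clamped to bin 1", call. = FALSE)
    values <- pmax(values, 0)
  }
  lab <- pmin(nBins, floor(values / binWidth) + 1)
  factor(lab, levels = seq_len(nBins))
}

#' Pre-filter an expression matrix and batch vector for ComBat
#'
#' Drops samples that are alone in their batch (singleton batches cannot
#' support a scale estimate), then genes with zero variance inside any
#' remaining batch (they would standardize to NaN).
#'
#' @param expr numeric matrix, genes x samples.
#' @param batch factor-like vector aligned with the columns of `expr`.
#' @return list with filtered `expr` and `batch` (factor, unused levels
#'   dropped).
#' @export
combatPrefilter <- function(expr, batch) {
  .checkExpression(expr)
  if (length(batch) != ncol(expr))
    .validationError("batch vector must align with the expression samples")
  batch <- factor(batch)
  if (anyNA(batch))
    .validationError("batch vector contains missing values")
  sizes <- table(batch)
  single <- names(sizes)[sizes == 1L]
  if (length(single)) {
    keep <- !(batch %in% single)
    .log("ComBat prefilter removed %d singleton-batch sample(s)", sum(!keep))
    expr <- expr[, keep, drop = FALSE]
    batch <- droplevels(batch[keep])
  }
  if (nlevels(batch) < 2L)
    .validationError("fewer than 2 batches remain after singleton removal")
  zeroVar <- rep(FALSE, nrow(expr))
  for (b in levels(batch)) {
    sub <- expr[, batch == b, drop = FALSE]
    zeroVar <- zeroVar | apply(sub, 1, function(v) diff(range(v)) == 0)
  }
  if (all(zeroVar))
    .validationError("every gene has zero variance within some batch")
  if (any(zeroVar))
    .log("ComBat prefilter removed %d gene(s) with zero within-batch variance",
         sum(zeroVar))
  list(expr = expr[!zeroVar, , drop = FALSE], batch = batch)
}

# Parametric EB hyperparameters (method of moments) and the joint
# fixed-point solver for one batch, following the standard location/scale
# formulation.
.ebFixedPoint <- function(Zb, gammaHat, deltaHat, gammaBar, tau2,
                          aPrior, bPrior, conv, maxIter) {
  nb <- ncol(Zb)
  gOld <- gammaHat
  dOld <- deltaHat
  for (i in seq_len(maxIter)) {
    gNew <- (tau2 * nb * gammaHat + dOld * gammaBar) / (tau2 * nb + dOld)
    sum2 <- rowSums((Zb - gNew)^2)
    dNew <- (0.5 * sum2 + bPrior) / (nb / 2 + aPrior - 1)
    change <- max(abs(gNew - gOld) / pmax(abs(gOld), 1e-12),
                  abs(dNew - dOld) / pmax(abs(dOld), 1e-12))
    gOld <- gNew
    dOld <- dNew
    if (change < conv)
      return(list(gammaStar = gNew, deltaStar = dNew, iterations = i))
  }
  .err("coexBenchConvergenceError",
       "EB fixed point did not converge within %d iterations (last change %g)",
       maxIter, change)
}

#' Empirical-Bayes location/scale adjustment for one batch variable
#'
#' Standardizes each gene against the batch + covariate model, estimates
#' per-batch per-gene additive (gamma) and multiplicative (delta^2) effects,
#' shrinks them with parametric empirical-Bayes priors (normal /
#' inverse-gamma, moment-matched hyperparameters, fixed-point iteration to
#' `conv`), removes the shrunken effects and restores the original scale.
#'
#' When the moment estimate of a prior's spread degenerates (all per-gene
#' estimates identical, e.g. a single batch), shrinkage for the affected
#' parameter is skipped — there is no information to shrink with. Together
#' with the ML variance estimators this makes a single-batch input (reachable
#' with `allowSingleBatch = TRUE`) an exact no-op.
#'
#' @param expr numeric matrix, genes x samples (pre-filtered, see
#'   [combatPrefilter()]).
#' @param batch factor-like, aligned with samples; every batch needs >= 2
#'   samples.
#' @param covDesign optional [ConfounderDesign-class] (or samples x columns
#'   matrix) of model covariates to protect during standardization; the
#'   intercept column, if present, is ignored (batch indicators span it).
#' @param shrink set `FALSE` to skip EB shrinkage and remove the raw batch
#'   estimates (test hook; exactly equalizes within-batch gene moments in
#'   standardized space).
#' @param conv fixed-point convergence tolerance; default `1e-4`.
#' @param maxIter fixed-point iteration cap; default 10000.
#' @param allowSingleBatch bypass the >= 2 batches guard.
#' @return Adjusted genes x samples matrix (same dimnames).
#' @export
combatAdjust <- function(expr, batch, covDesign = NULL, shrink = TRUE,
                         conv = 1e-4, maxIter = 10000L,
                         allowSingleBatch = FALSE) {
  .checkExpression(expr)
  batch <- factor(batch)
  if (length(batch) != ncol(expr))
    .validationError("batch vector must align with the expression samples")
  if (nlevels(batch) < 2L && !allowSingleBatch)
    .validationError("need >= 2 batches (or allowSingleBatch = TRUE)")
  if (any(table(batch) < 2L))
    .validationError("every batch needs >= 2 samples; run combatPrefilter()")
  n <- ncol(expr)
  batchDesign <- vapply(levels(batch), function(l) as.numeric(batch == l),
                        numeric(n))   # one indicator per batch, no reference
  dim(batchDesign) <- c(n, nlevels(batch))
  colnames(batchDesign) <- levels(batch)
  X <- batchDesign
  if (!is.null(covDesign)) {
    M <- if (is(covDesign, "ConfounderDesign")) covDesign@design else covDesign
    M <- M[, colnames(M) != "(Intercept)", drop = FALSE]
    if (nrow(M) != n) {
      if (is.null(rownames(M)) || !all(colnames(expr) %in% rownames(M)))
        .validationError("covariate design must cover every expression sample")
      M <- M[colnames(expr), , drop = FALSE]
    }
    X <- cbind(batchDesign, M)
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      aliased <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
      keepCov <- setdiff(colnames(M), aliased)
      warning(sprintf("covariate column(s) confounded with batch dropped: %s",
                      paste(intersect(colnames(M), aliased), collapse = ", ")),
              call. = FALSE)
      X <- cbind(batchDesign, M[, keepCov, drop = FALSE])
    }
  }
  nBatch <- nlevels(batch)
  fit <- lm.fit(X, t(expr))
  BHat <- fit$coefficients                       # columns of X  x  genes
  batchSizes <- as.numeric(table(batch))
  grand <- crossprod(matrix(batchSizes / n, ncol = 1),
                     BHat[seq_len(nBatch), , drop = FALSE])  # 1 x genes
  varPooled <- rowMeans((expr - t(X %*% BHat))^2)            # ML, 1/n
  if (any(varPooled == 0))
    .validationError("gene(s) with zero pooled residual variance; prefilter first")
  standMean <- matrix(grand, nrow(expr), n)   # each column = grand mean
  if (ncol(X) > nBatch) {
    covPart <- X[, -seq_len(nBatch), drop = FALSE] %*%
      BHat[-seq_len(nBatch), , drop = FALSE]
    standMean <- standMean + t(covPart)
  }
  Z <- (expr - standMean) / sqrt(varPooled)

  gammaStar <- matrix(0, nBatch, nrow(expr))
  deltaStar <- matrix(1, nBatch, nrow(expr))
  for (bi in seq_len(nBatch)) {
    sel <- batch == levels(batch)[bi]
    Zb <- Z[, sel, drop = FALSE]
    nb <- sum(sel)
    gammaHat <- rowMeans(Zb)
    deltaHat <- rowMeans((Zb - gammaHat)^2)      # ML, 1/n_b
    if (!shrink) {
      gammaStar[bi, ] <- gammaHat
      deltaStar[bi, ] <- deltaHat
      next
    }
    gammaBar <- mean(gammaHat)
    tau2 <- var(gammaHat)
    m <- mean(deltaHat)
    s2 <- var(deltaHat)
    degenerateGamma <- !is.finite(tau2) || tau2 < 1e-12
    degenerateDelta <- !is.finite(s2) || s2 < 1e-12
    if (degenerateGamma || degenerateDelta) {
      # no across-gene spread to moment-match that prior; leave unshrunk
      gammaStar[bi, ] <- if (degenerateGamma) gammaHat
        else (tau2 * nb * gammaHat + deltaHat * gammaBar) /
             (tau2 * nb + deltaHat)
      deltaStar[bi, ] <- deltaHat
      next
    }
    aPrior <- (2 * s2 + m^2) / s2
    bPrior <- (m * s2 + m^3) / s2
    sol <- .ebFixedPoint(Zb, gammaHat, deltaHat, gammaBar, tau2,
                         aPrior, bPrior, conv, maxIter)
    gammaStar[bi, ] <- sol$gammaStar
    deltaStar[bi, ] <- sol$deltaStar
  }
  out <- Z
  for (bi in seq_len(nBatch)) {
    sel <- batch == levels(batch)[bi]
    out[, sel] <- (Z[, sel, drop = FALSE] - gammaStar[bi, ]) /
      sqrt(deltaStar[bi, ])
  }
  out <- out * sqrt(varPooled) + standMean
  dimnames(out) <- dimnames(expr)
  if (!all(is.finite(out)))
    .validationError("ComBat produced non-finite values; check input filtering")
  out
}

#' Configuration for iterative multi-batch adjustment
#'
#' @param batchVariables ordered character vector of phenotype variables to
#'   adjust, one per round; default follows the canonical listing (death
#'   type, experimental batch, ischemic time, age, gender).
#' @param binWidth,nBins discretization of continuous batch variables (see
#'   [discretizeIschemic()]); defaults 300 and 5.
#' @param parametric parametric EB priors; the only implemented option.
#' @param shrink EB shrinkage on/off (test hook, see [combatAdjust()]).
#' @return Validated configuration list.
#' @export
combatConfig <- function(batchVariables = c("DTHHRDY", "SMGEBTCH",
                                            "SMTSISCH", "AGE", "GENDER"),
                         binWidth = 300, nBins = 5L, parametric = TRUE,
                         shrink = TRUE) {
  if (length(batchVariables) < 1L)
    .configError("at least one batch variable is required")
  if (!isTRUE(parametric))
    .configError("only parametric EB priors are implemented")
  if (nBins < 2L || binWidth <= 0)
    .configError("need nBins >= 2 and binWidth > 0")
  list(batchVariables = batchVariables, binWidth = binWidth,
       nBins = as.integer(nBins), parametric = parametric, shrink = shrink)
}

#' Iteratively adjust several batch variables
#'
#' One [combatAdjust()] round per variable in `config$batchVariables` order.
#' Each round uses the current variable as batch and supplies the *not yet
#' adjusted* batch variables as model covariates, so later batches are
#' protected from absorption while still pending; the adjusted matrix feeds
#' the next round. Continuous batch variables are discretized with
#' [discretizeIschemic()]. Samples missing any batch variable are excluded
#' up front (logged); genes removed by any round's prefilter stay removed.
#'
#' @param expr numeric matrix, genes x samples.
#' @param pheno phenotype `data.frame`, sample rownames.
#' @param config a [combatConfig()] list.
#' @return Adjusted genes x samples matrix.
#' @export
combatIterative <- function(expr, pheno, config = combatConfig()) {
  .checkExpression(expr)
  .checkPhenotypes(pheno)
  vars <- config$batchVariables
  absent <- setdiff(vars, colnames(pheno))
  if (length(absent))
    .configError("batch variable(s) not in phenotype table: %s",
                 paste(absent, collapse = ", "))
  al <- alignSamples(expr, pheno)
  expr <- al$expr
  pheno <- al$pheno
  complete <- !Reduce(`|`, lapply(pheno[, vars, drop = FALSE], is.na))
  if (!all(complete)) {
    .log("ComBat: excluded %d sample(s) with missing batch variables",
         sum(!complete))
    expr <- expr[, complete, drop = FALSE]
    pheno <- pheno[complete, , drop = FALSE]
  }
  batches <- lapply(setNames(vars, vars), function(v) {
    val <- pheno[[v]]
    if (is.numeric(val))
      discretizeIschemic(val, config$binWidth, config$nBins)
    else factor(val)
  })
  current <- expr
  for (round in seq_along(vars)) {
    v <- vars[round]
    res <- tryCatch({
      batch <- droplevels(batches[[v]][match(colnames(current),
                                             rownames(pheno))])
      pf <- combatPrefilter(current, batch)
      remaining <- vars[-seq_len(round)]
      covDesign <- NULL
      if (length(remaining)) {
        remDf <- data.frame(lapply(setNames(remaining, remaining), function(r)
          batches[[r]][match(colnames(pf$expr), rownames(pheno))]),
          row.names = colnames(pf$expr))
        covDesign <- tryCatch(buildDesign(remDf, remaining),
                              error = function(e) NULL)
      }
      combatAdjust(pf$expr, pf$batch, covDesign = covDesign,
                   shrink = isTRUE(config$shrink))
    }, coexBenchError = function(e) {
      .err(class(e)[1],
           "ComBat round %d (batch variable '%s') failed: %s",
           round, v, conditionMessage(e))
    })
    .log("ComBat round %d ('%s'): %d genes x %d samples", round, v,
         nrow(res), ncol(res))
    current <- res
  }
  current
}
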