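test_that("design construction encodes covariates with treatment coding", {
  ph <- data.frame(
    GENDER = factor(rep(c("F", "M"), 5)),
    SMTSISCH = seq(10, 100, 10),
    row.names = sprintf("S%02d", 1:10))
  d <- buildDesign(ph, c("GENDER", "SMTSISCH"))
  X <- designMatrix(d)
  expect_identical(ncol(X), 3L)               # intercept + indicator + slope
  expect_identical(colnames(X), c("(Intercept)", "GENDERM", "SMTSISCH"))
  expect_equal(unname(X[, "GENDERM"]), rep(c(0, 1), 5))

  ph$AGE <- factor(rep(c("20-29", "30-39", "40-49", "50-59"), length.out = 10))
  d4 <- buildDesign(ph, "AGE")
  expect_identical(ncol(designMatrix(d4)), 4L)  # 3 indicators + intercept

  expect_error(buildDesign(ph, "NOPE"), class = "coexBenchConfigError")
})

test_that("design construction drops incomplete samples and degenerate covariates", {
  ph <- makePheno(10, seed = 3)
  ph$SMTSISCH[c(2, 5)] <- NA
  d <- buildDesign(ph, c("GENDER", "SMTSISCH"))
  expect_identical(nrow(designMatrix(d)), 8L)
  expect_identical(d@droppedSamples, rownames(ph)[c(2, 5)])

  ph$ONELEVEL <- factor(rep("x", 10))
  expect_warning(d2 <- buildDesign(ph, c("ONELEVEL", "GENDER")),
                 "single level")
  expect_false(any(grepl("ONELEVEL", colnames(designMatrix(d2)))))
  expect_error(suppressWarnings(buildDesign(ph, "ONELEVEL")),
               class = "coexBenchValidationError")
})

test_that("residualization removes exactly the fitted linear structure", {
  withr::with_seed(7, {
    n <- 30
    X <- cbind(rnorm(n), rnorm(n), rnorm(n))
    colnames(X) <- paste0("C", 1:3)
    rownames(X) <- sprintf("S%03d", 1:n)
    design <- designFromMatrix(X)
    expr <- matrix(rnorm(50 * n), 50, n,
                   dimnames = list(sprintf("G%03d", 1:50), rownames(X)))
    # a row that is an exact linear function of the design
    expr[1, ] <- 2 * X[, 1] + 5
    fit <- residualize(expr, design)
    expect_lt(max(abs(residuals(fit)[1, ])), 1e-10)
    expect_equal(unname(coef(fit)[1, c("(Intercept)", "C1")]), c(5, 2),
                 tolerance = 1e-10)

    # brute-force normal-equations oracle
    Xf <- designMatrix(design)
    beta <- solve(t(Xf) %*% Xf) %*% t(Xf) %*% t(expr)
    oracle <- expr - t(Xf %*% beta)
    expect_lt(max(abs(residuals(fit) - oracle)), 1e-8)

    # a row orthogonal to all non-intercept columns: residual = row - mean
    Q <- qr.Q(qr(cbind(1, X)))
    v <- rnorm(n)
    v <- v - Q %*% crossprod(Q, v)
    v <- as.numeric(v) + 3
    expr[2, ] <- v
    fit2 <- residualize(expr, design)
    expect_equal(unname(residuals(fit2)[2, ]), v - mean(v), tolerance = 1e-8)
  })
})

test_that("residual adjustment is idempotent and reparameterization-invariant", {
  withr::with_seed(8, {
    expr <- makeExpr(40, 25, seed = 8)
    X <- matrix(rnorm(25 * 3), 25, 3,
                dimnames = list(colnames(expr), paste0("C", 1:3)))
    d1 <- designFromMatrix(X)
    r1 <- residuals(residualize(expr, d1))
    # regressing the residuals on the same design returns ~0 coefficients
    refit <- coef(residualize(r1, d1))
    expect_lt(max(abs(refit)), 1e-8)
    # invertible linear reparameterization of the columns
    A <- matrix(c(2, 0.5, 0, -1, 1, 3, 0.2, 0, 1), 3, 3)
    d2 <- designFromMatrix(X %*% A)
    r2 <- residuals(residualize(expr, d2))
    expect_equal(r1, r2, tolerance = 1e-8)
  })
})

test_that("residualization guards dimensions and rank", {
  expr <- makeExpr(10, 5)
  X <- matrix(rnorm(5 * 6), 5, 6, dimnames = list(colnames(expr), NULL))
  expect_error(residualize(expr, designFromMatrix(X)),
               class = "coexBenchValidationError")
  # duplicated column -> collinear drop with warning
  Z <- matrix(rnorm(5), 5, 1, dimnames = list(colnames(expr), "C1"))
  d <- designFromMatrix(cbind(Z, C2 = Z[, 1]))
  expect_warning(fit <- residualize(expr, d), "collinear")
  expect_identical(ncol(coef(fit)), 2L)
})

test_that("principal components recover planted structure", {
  withr::with_seed(10, {
    n <- 40
    f <- rnorm(n)
    load <- rnorm(60)
    expr <- outer(load, f) + matrix(rnorm(60 * n, sd = 1e-3), 60, n)
    dimnames(expr) <- list(sprintf("G%02d", 1:60), sprintf("S%02d", 1:n))
    d <- computePCs(expr, 1)
    expect_gt(d@info$explainedVariance[1], 0.999)
    expect_gt(abs(cor(designMatrix(d)[, "PC1"], f)), 0.999)

    # two orthogonal planted factors on disjoint gene blocks of different
    # size (distinct eigenvalues, so the components cannot mix)
    f2 <- rnorm(n)
    f2 <- f2 - f * sum(f * f2) / sum(f^2)
    expr2 <- rbind(outer(rnorm(40), f), outer(rnorm(20), f2)) +
      matrix(rnorm(60 * n, sd = 0.05), 60, n)
    dimnames(expr2) <- dimnames(expr)
    d2 <- computePCs(expr2, 2)
    S <- designMatrix(d2)[, c("PC1", "PC2")]
    cors <- abs(cor(S, cbind(f, f2)))
    expect_gt(max(cors[1, ]), 0.99)
    expect_gt(max(cors[2, ]), 0.99)
    expect_lt(abs(sum(S[, 1] * S[, 2])), 1e-8)   # orthogonal scores
  })
  expect_error(computePCs(makeExpr(10, 5), 5), class = "coexBenchConfigError")
})

test_that("PC count selection follows the cumulative-variance spectrum", {
  withr::with_seed(12, {
    n <- 30
    expr <- outer(rnorm(50), rnorm(n)) + matrix(rnorm(50 * n, sd = 1e-3), 50, n)
    dimnames(expr) <- list(sprintf("G%02d", 1:50), sprintf("S%02d", 1:n))
    expect_identical(chooseNumPCs(expr, 0.9), 1L)

    noise <- makeExpr(60, 20, seed = 13)
    Z <- (noise - rowMeans(noise)) / apply(noise, 1, sd)
    ev <- eigen(crossprod(t(Z) - colMeans(t(Z))), only.values = TRUE)$values
    ev <- eigen(cov(t(Z)) * (ncol(Z) - 1), only.values = TRUE)$values
    oracleK <- which(cumsum(ev) / sum(ev) >= 0.5)[1]
    expect_lte(abs(chooseNumPCs(noise, 0.5) - oracleK), 2)

    full <- makeExpr(5, 5, seed = 14)
    expect_lte(chooseNumPCs(full, 0.999), 4L)
  })
})

test_that("adjustment methods dispatch and degenerate designs pass through", {
  ds <- smallSynthetic(seed = 4)
  expr <- exprMatrix(ds); ph <- phenoTable(ds)
  # PEER with a zero factor matrix and no covariates: identity up to centering
  zeroFac <- matrix(0, 3, ncol(expr),
                    dimnames = list(paste0("F", 1:3), colnames(expr)))
  out <- suppressWarnings(
    adjustExpression(expr, "PEER", pheno = ph, factors = zeroFac))
  expect_equal(out, expr - rowMeans(expr), tolerance = 1e-10)

  expect_error(adjustExpression(expr, "PEER", pheno = ph),
               class = "coexBenchConfigError")
  expect_error(adjustExpression(expr, "PCA_opt", pheno = ph),
               class = "coexBenchConfigError")
  expect_identical(adjustExpression(expr, "raw"), expr)

  # PCA with large k shrinks per-gene variance and true-pair correlation
  # (k well above the planted structure's dimension, but leaving enough
  # residual rank for correlations to stay estimable)
  dsm <- generateSynthetic(syntheticConfig(
    nGenes = 300, nSamples = 60, nTrueEdges = 40, nFalseEdges = 40,
    nFillerEdges = 0, nModules = 4, seed = 5))
  exprM <- exprMatrix(dsm)
  adj <- adjustExpression(exprM, "PCA", pheno = phenoTable(dsm),
                          numPCs = 30, covariates = "GENDER")
  expect_true(all(apply(adj, 1, var) < apply(exprM, 1, var)))
  gs <- goldStandardFromTruth(dsm)
  rsRaw <- coexEdges(scoreEdges(exprM, gs))
  rsAdj <- coexEdges(scoreEdges(adj, gs))
  expect_lt(mean(abs(rsAdj$rs[rsAdj$label == 1])),
            mean(abs(rsRaw$rs[rsRaw$label == 1])))
})
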