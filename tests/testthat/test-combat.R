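test_that("ischemic-time discretization uses half-open 300-minute bins", {
  expect_identical(as.integer(discretizeIschemic(c(150, 450))), c(1L, 2L))
  expect_identical(as.integer(discretizeIschemic(300)), 2L)   # boundary up
  expect_identical(as.integer(discretizeIschemic(1500)), 5L)  # top clamp
  expect_identical(as.integer(discretizeIschemic(0)), 1L)
  expect_warning(lab <- discretizeIschemic(-10), "clamped")
  expect_identical(as.integer(lab), 1L)
  expect_true(is.na(discretizeIschemic(c(NA, 100))[1]))
})

test_that("prefilter removes singleton batches then zero-variance genes", {
  expr <- makeExpr(6, 7, seed = 2)
  batch <- factor(c("a", "a", "a", "b", "b", "b", "c"))
  expr[3, batch == "b"] <- 5         # constant inside batch b only
  pf <- combatPrefilter(expr, batch)
  expect_identical(ncol(pf$expr), 6L)               # singleton "c" removed
  expect_identical(levels(pf$batch), c("a", "b"))
  expect_false("G003" %in% rownames(pf$expr))       # zero-variance gene gone

  clean <- combatPrefilter(expr[-3, 1:6], batch[1:6])
  expect_identical(clean$expr, expr[-3, 1:6])

  expect_error(combatPrefilter(expr[, 1:4],
                               factor(c("a", "a", "a", "b"))),
               class = "coexBenchValidationError")
})

test_that("single-batch input is returned unchanged", {
  expr <- makeExpr(30, 12, seed = 3)
  batch <- factor(rep("one", 12))
  out <- combatAdjust(expr, batch, allowSingleBatch = TRUE)
  expect_lt(max(abs(out - expr)), 1e-8)
  expect_error(combatAdjust(expr, batch), class = "coexBenchValidationError")
})

test_that("a pure between-batch mean shift is removed", {
  withr::with_seed(21, {
    G <- 200; n <- 60
    batch <- factor(rep(c("b1", "b2"), each = n / 2))
    delta <- 2
    expr <- matrix(rnorm(G * n), G, n,
                   dimnames = list(sprintf("G%03d", 1:G),
                                   sprintf("S%03d", 1:n)))
    expr[, batch == "b2"] <- expr[, batch == "b2"] + delta
    out <- combatAdjust(expr, batch)
    gaps <- rowMeans(out[, batch == "b1"]) - rowMeans(out[, batch == "b2"])
    # the planted global shift is removed ...
    expect_lt(abs(mean(gaps)), 0.05 * delta)
    # ... and per-gene residuals sit at the EB-shrinkage noise floor, far
    # below the planted effect
    expect_lt(mean(abs(gaps)), 0.15 * delta)
    expect_true(all(is.finite(out)))
    expect_identical(dimnames(out), dimnames(expr))
  })
})

test_that("between-batch variance ratios are equalized", {
  withr::with_seed(22, {
    G <- 200; n <- 60
    batch <- factor(rep(c("b1", "b2"), each = n / 2))
    expr <- cbind(matrix(rnorm(G * n / 2, sd = 2), G, n / 2),
                  matrix(rnorm(G * n / 2, sd = 1), G, n / 2))
    dimnames(expr) <- list(sprintf("G%03d", 1:G), sprintf("S%03d", 1:n))
    out <- combatAdjust(expr, batch)
    v1 <- apply(out[, batch == "b1"], 1, var)
    v2 <- apply(out[, batch == "b2"], 1, var)
    ratio <- mean(v1) / mean(v2)
    expect_gt(ratio, 0.8)
    expect_lt(ratio, 1.25)
  })
})

test_that("with shrinkage disabled batch moments are exactly equalized", {
  withr::with_seed(23, {
    G <- 50; n <- 40
    batch <- factor(rep(c("b1", "b2"), each = n / 2))
    expr <- makeExpr(G, n, seed = 23)
    expr[, batch == "b2"] <- expr[, batch == "b2"] * 1.6 + 1
    out <- combatAdjust(expr, batch, shrink = FALSE)
    m1 <- rowMeans(out[, batch == "b1"])
    m2 <- rowMeans(out[, batch == "b2"])
    expect_lt(max(abs(m1 - m2)), 1e-8)
    v1 <- apply(out[, batch == "b1"], 1, function(v) mean((v - mean(v))^2))
    v2 <- apply(out[, batch == "b2"], 1, function(v) mean((v - mean(v))^2))
    expect_lt(max(abs(v1 - v2)), 1e-8)
  })
})

test_that("adjustment agrees with the sva reference on large batches", {
  withr::with_seed(24, {
    G <- 80; n <- 200
    batch <- factor(rep(c("b1", "b2"), each = n / 2))
    expr <- matrix(rnorm(G * n), G, n,
                   dimnames = list(sprintf("G%03d", 1:G),
                                   sprintf("S%03d", 1:n)))
    expr[, batch == "b2"] <- expr[, batch == "b2"] * 1.3 + 0.8
    ours <- combatAdjust(expr, batch)
    ref <- suppressMessages(sva::ComBat(expr, batch))
    expect_gt(cor(as.numeric(ours), as.numeric(ref)), 0.999)
    expect_lt(mean(abs(ours - ref)), 0.02)
  })
})

test_that("iterative adjustment handles multiple batch variables in order", {
  withr::with_seed(25, {
    G <- 120; n <- 80
    genes <- sprintf("G%03d", 1:G); samples <- sprintf("S%03d", 1:n)
    ph <- data.frame(
      V1 = factor(sample(c("a", "b"), n, replace = TRUE)),
      V2 = factor(sample(c("x", "y", "z"), n, replace = TRUE)),
      row.names = samples)
    base <- matrix(rnorm(G * n), G, n, dimnames = list(genes, samples))
    shift1 <- matrix(rnorm(G * 2, sd = 1.5), G, 2)
    shift2 <- matrix(rnorm(G * 3, sd = 1.5), G, 3)
    expr <- base + shift1[, as.integer(ph$V1)] + shift2[, as.integer(ph$V2)]

    gap <- function(mat, f) {
      centers <- sapply(levels(f), function(l)
        rowMeans(mat[, f == l, drop = FALSE]))
      mean(apply(centers, 1, function(v) max(v) - min(v)))
    }
    out <- combatIterative(expr, ph,
                           combatConfig(batchVariables = c("V1", "V2")))
    f1 <- ph$V1[match(colnames(out), rownames(ph))]
    f2 <- ph$V2[match(colnames(out), rownames(ph))]
    expect_lt(gap(out, f1), 0.2 * gap(expr, ph$V1))
    expect_lt(gap(out, f2), 0.2 * gap(expr, ph$V2))

    # a single variable equals one combatAdjust round
    single <- combatIterative(expr, ph, combatConfig(batchVariables = "V1"))
    direct <- combatAdjust(expr, ph$V1)
    expect_equal(single, direct, tolerance = 1e-10)

    # order sensitivity is real and documented
    rev <- combatIterative(expr, ph,
                           combatConfig(batchVariables = c("V2", "V1")))
    expect_gt(max(abs(rev - out)), 1e-8)
  })
})
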