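test_that("candidate selection takes a prefix in file order and clamps", {
  edges <- data.frame(gene_a = paste0("A", 1:10), gene_b = paste0("B", 1:10),
                      confidence = seq(0.05, 0.95, length.out = 10))
  expect_identical(takeCandidateEdges(edges, 3)$gene_a, paste0("A", 1:3))
  expect_warning(all10 <- takeCandidateEdges(edges, 50), "only 10")
  expect_identical(nrow(all10), 10L)
  expect_error(takeCandidateEdges(edges, 0), class = "coexBenchConfigError")
  byConf <- takeCandidateEdges(edges, 3, order = "confidence")
  expect_identical(byConf$gene_a, paste0("A", 10:8))
})

test_that("default candidate count keeps the first 100,000 of a larger list", {
  n <- 150000L
  edges <- data.frame(gene_a = sprintf("A%06d", 1:n),
                      gene_b = sprintf("B%06d", 1:n),
                      confidence = rep(0.5, n))
  out <- takeCandidateEdges(edges)
  expect_identical(nrow(out), 100000L)
  expect_identical(out$gene_a[100000], "A100000")
})

test_that("calibration stops immediately on already balanced counts", {
  conf <- c(runif(100, 0.8, 1), runif(100, 0, 0.005))
  cal <- calibrateCutoffs(conf)
  expect_identical(cal$iterations, 0L)
  expect_equal(cal$cutoffFalse, 0.01)
  expect_equal(cal$cutoffTrue, 0.7)
})

test_that("calibration matches a step-by-step oracle on balanceable input", {
  # skewed mixture the loop can balance by lowering the high cutoff
  conf <- withr::with_seed(2, c(rbeta(3000, 8, 2), rbeta(4000, 1, 40)))
  oracle <- calibrationOracle(conf)
  expect_identical(oracle$status, "balanced")
  cal <- calibrateCutoffs(conf)
  expect_equal(cal$cutoffFalse, oracle$cutoffFalse)
  expect_equal(cal$cutoffTrue, oracle$cutoffTrue)
  expect_identical(cal$iterations, as.integer(oracle$iterations))
  expect_identical(cal$nTrue, oracle$nTrue)
  expect_identical(cal$nFalse, oracle$nFalse)
  expect_lte(max(cal$nTrue, cal$nFalse) / min(cal$nTrue, cal$nFalse), 1.25)
  # deterministic: rerun gives identical cutoffs
  expect_identical(calibrateCutoffs(conf), cal)
})

test_that("calibration failure carries the oracle's last state", {
  conf <- withr::with_seed(1, c(rbeta(2000, 8, 2), rbeta(50000, 1, 50)))
  oracle <- calibrationOracle(conf)
  expect_identical(oracle$status, "failed")
  err <- tryCatch(calibrateCutoffs(conf), error = identity)
  expect_s3_class(err, "coexBenchCalibrationError")
  expect_match(conditionMessage(err), "last counts")
  expect_equal(err$cutoffFalse, oracle$cutoffFalse)
  expect_equal(err$cutoffTrue, oracle$cutoffTrue)
  expect_identical(err$nTrue, oracle$nTrue)
  expect_identical(err$nFalse, oracle$nFalse)
})

test_that("widening the balance tolerance never takes more iterations", {
  conf <- withr::with_seed(3, c(rbeta(3000, 8, 2), rbeta(4000, 1, 40)))
  tols <- c(1.1, 1.25, 1.5, 2, 3)
  iters <- vapply(tols, function(tol) {
    res <- tryCatch(calibrateCutoffs(conf, balanceTol = tol),
                    error = function(e) NULL)
    if (is.null(res)) NA_integer_ else res$iterations
  }, integer(1))
  ok <- !is.na(iters)
  expect_true(all(diff(iters[ok]) <= 0))
})

test_that("gold-standard labeling applies strict thresholds and drops mid-range", {
  edges <- data.frame(gene_a = paste0("A", 1:4), gene_b = paste0("B", 1:4),
                      confidence = c(0.9, 0.6, 0.3, 0.01))
  gs <- buildGoldStandard(edges, cutoffTrue = 0.5, cutoffFalse = 0.025)
  e <- goldEdges(gs)
  expect_identical(nrow(e), 3L)
  expect_identical(e$label, c(1L, 1L, 0L))
  expect_false("A3" %in% e$gene_a)

  mid <- data.frame(gene_a = paste0("A", 1:3), gene_b = paste0("B", 1:3),
                    confidence = c(0.1, 0.2, 0.3))
  expect_error(buildGoldStandard(mid, 0.5, 0.025),
               class = "coexBenchValidationError")
})

test_that("label counts equal brute-force threshold counts on random lists", {
  withr::with_seed(11, {
    for (rep in 1:5) {
      n <- sample(200:600, 1)
      conf <- c(runif(n), runif(30, 0.9, 1), runif(30, 0, 0.01))
      edges <- data.frame(gene_a = sprintf("A%03d", seq_along(conf)),
                          gene_b = sprintf("B%03d", seq_along(conf)),
                          confidence = conf)
      cutT <- runif(1, 0.5, 0.8); cutF <- runif(1, 0.02, 0.2)
      gs <- buildGoldStandard(edges, cutT, cutF)
      expect_identical(nTrueEdges(gs), sum(conf > cutT))
      expect_identical(nFalseEdges(gs), sum(conf < cutF))
    }
  })
})

test_that("dataset restriction keeps only fully measured pairs", {
  edges <- data.frame(gene_a = c("G1", "G3", "G5", "G7"),
                      gene_b = c("G2", "G4", "G6", "G8"),
                      confidence = c(0.9, 0.8, 0.01, 0.005))
  gs <- buildGoldStandard(edges, 0.5, 0.025)
  expr <- makeExpr(6, 5)
  rownames(expr) <- c("G1", "G2", "G3", "G5", "G6", "G8")
  r <- restrictToDataset(gs, expr)
  expect_identical(goldEdges(r)$gene_a, c("G1", "G5"))   # G3/G4, G7/G8 lost
  expect_identical(cutoffs(r), cutoffs(gs))

  exprAll <- makeExpr(8, 5)
  rownames(exprAll) <- paste0("G", 1:8)
  expect_identical(goldEdges(restrictToDataset(gs, exprAll)), goldEdges(gs))

  exprNone <- makeExpr(3, 5)
  rownames(exprNone) <- c("G1", "G2", "G3")
  expect_error(restrictToDataset(gs, exprNone),
               class = "coexBenchValidationError")
})
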