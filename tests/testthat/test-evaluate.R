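test_that("ROC/AUC handles separation, ties and the pairwise oracle", {
  expect_equal(auc(rocAuc(c(3, 2, 1), c(1, 1, 0))), 1)
  expect_equal(auc(rocAuc(rep(2, 6), c(1, 0, 1, 0, 1, 0))), 0.5)
  expect_equal(auc(rocAuc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0))), 0.75)
  expect_error(rocAuc(1:4, rep(1, 4)), class = "coexBenchValidationError")

  withr::with_seed(41, {
    for (i in 1:50) {
      m <- sample(8:60, 1)
      s <- sample(round(rnorm(m), sample(0:2, 1)))
      l <- rbinom(m, 1, 0.5)
      if (length(unique(l)) < 2) next
      r <- rocAuc(s, l)
      expect_equal(auc(r), aucOracle(s, l), tolerance = 1e-12)
      # trapezoid of the emitted curve equals the AUC
      p <- rocPoints(r)
      trap <- sum(diff(p$fpr) * (p$tpr[-1] + p$tpr[-nrow(p)]) / 2)
      expect_equal(trap, auc(r), tolerance = 1e-12)
    }
  })
})

test_that("AUC respects the complement and strictly monotone transforms", {
  withr::with_seed(42, {
    s <- rnorm(40)                            # tie-free
    l <- rbinom(40, 1, 0.5)
    expect_equal(auc(rocAuc(s, l)), 1 - auc(rocAuc(-s, l)), tolerance = 1e-12)
    expect_equal(auc(rocAuc(s, l)), auc(rocAuc(exp(s), l)), tolerance = 1e-12)
    p <- runif(40)
    expect_equal(auc(rocAuc(-p, l)), auc(rocAuc(-log10(p), l)),
                 tolerance = 1e-12)
  })
})

test_that("AUC agrees with the pROC reference", {
  withr::with_seed(43, {
    s <- c(rnorm(60, 1), rnorm(60))
    l <- rep(c(1, 0), each = 60)
    expect_equal(auc(rocAuc(s, l)),
                 as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                                direction = "<"))),
                 tolerance = 1e-12)
  })
})

test_that("method comparison enforces a shared edge set and sorts by AUC", {
  ds <- smallSynthetic(seed = 7)
  gs <- goldStandardFromTruth(ds)
  expr <- exprMatrix(ds)
  raw <- scoreEdges(expr, gs, method = "raw")
  lr <- scoreEdges(adjustExpression(expr, "LR", pheno = phenoTable(ds),
                                    covariates = colnames(phenoTable(ds))),
                   gs, method = "LR")
  rocs <- compareMethods(list(raw = raw, LR = lr))
  aucs <- vapply(rocs, auc, numeric(1))
  expect_true(all(diff(aucs) <= 0))           # sorted descending
  # identical scores under two names give identical AUC
  same <- compareMethods(list(a = raw, b = raw))
  expect_equal(auc(same[[1]]), auc(same[[2]]))

  e <- coexEdges(raw)
  clipped <- new("CoexpressionResult", edges = e[-1, , drop = FALSE],
                 scoreCap = 320, method = "clipped")
  err <- tryCatch(compareMethods(list(raw = raw, clipped = clipped)),
                  error = identity)
  expect_s3_class(err, "coexBenchValidationError")
  expect_match(conditionMessage(err), "symmetric difference")
  expect_error(compareMethods(list()), class = "coexBenchValidationError")
  expect_error(compareMethods(setNames(list(raw), "")),
               class = "coexBenchConfigError")
})

test_that("comparison writes ROC tables, an AUC summary and a curve plot", {
  ds <- smallSynthetic(seed = 8)
  gs <- goldStandardFromTruth(ds)
  raw <- scoreEdges(exprMatrix(ds), gs, method = "raw")
  out <- tempfile()
  plotOk <- tryCatch({ compareMethods(list(raw = raw), outDir = out,
                                      plot = TRUE); TRUE },
                     error = function(e) FALSE)
  if (!plotOk)   # headless devices without png support still must write TSVs
    compareMethods(list(raw = raw), outDir = out, plot = FALSE)
  expect_true(file.exists(file.path(out, "roc_raw.tsv")))
  summary <- read.delim(file.path(out, "auc_summary.tsv"))
  expect_identical(summary$method, "raw")
  expect_equal(summary$auc, auc(rocAuc(coexEdges(raw)$score,
                                       coexEdges(raw)$label)))
})

test_that("density summaries expose overcorrection and determinism", {
  dsm <- generateSynthetic(syntheticConfig(
    nGenes = 300, nSamples = 120, nTrueEdges = 40, nFalseEdges = 40,
    nFillerEdges = 0, batchSpec = list(), seed = 9))
  gs <- goldStandardFromTruth(dsm)
  expr <- exprMatrix(dsm)
  raw <- scoreEdges(expr, gs, method = "raw")
  # destroying all structure pulls true-edge mean toward 0
  shuffled <- withr::with_seed(99, t(apply(expr, 1, sample)))
  dimnames(shuffled) <- dimnames(expr)
  null <- scoreEdges(shuffled, gs, method = "null")
  d <- densitySummary(list(raw = raw, null = null))
  st <- d@stats
  expect_gt(st$mean[st$method == "raw" & st$label == 1], 0.3)
  expect_lt(abs(st$mean[st$method == "null" & st$label == 1]),
            2 * 2 / sqrt(sum(st$n[st$method == "null" & st$label == 1])))
  expect_true(all(vapply(d@histograms, sum, numeric(1)) ==
                    st$n[match(names(d@histograms),
                               paste0(st$method, ".", st$label))]))
  d2 <- densitySummary(list(x = raw, y = raw))
  expect_equal(d2@stats$mean[d2@stats$method == "x"],
               d2@stats$mean[d2@stats$method == "y"])
})
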