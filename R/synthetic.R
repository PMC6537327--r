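# Download-free synthetic benchmark data: planted co-expression modules,
# known-covariate batch artefacts, optional hidden confounders, and a
# GIANT-like confidence-scored edge list.

#' Configuration for the synthetic benchmark generator
#'
#' Defaults describe the desk-scale study conditions used throughout the
#' package's own benchmarks: 2,000 genes x 200 samples, 300 planted true and
#' 300 planted false pairs, 20,000 filler edges; batch-free pair correlation
#' 0.5; one 4-level experimental batch with per-gene/per-level additive
#' shifts of sd 1.0, a binary sex covariate (shift sd 0.5) and a continuous
#' ischemic-time-like confounder (per-gene slope sd 0.5 on the standardized
#' covariate); unit-sd idiosyncratic noise.
#'
#' The loading of each pair's shared latent factor is
#' `lambda = noiseSd * sqrt(rhoTrue / (1 - rhoTrue))`, so `rhoTrue` is the
#' population correlation of the batch-free *observed* expression (shared
#' factor plus noise) of a planted pair — the quantity the downstream
#' Spearman scoring sees when no batch structure interferes.
#'
#' @param nGenes,nSamples matrix dimensions.
#' @param nTrueEdges,nFalseEdges planted pair counts; pairs are disjoint, so
#'   `2*(nTrueEdges + nFalseEdges) <= nGenes` is required.
#' @param nFillerEdges unlabeled background edges (mid-range confidences)
#'   giving cutoff calibration material to work on.
#' @param rhoTrue target batch-free correlation of a planted true pair.
#' @param nModules number of shared latent module factors the true pairs are
#'   grouped into; `NULL` (default) gives every pair its own factor. Small
#'   values concentrate the biology into few dominant variance components —
#'   the regime in which component-removal methods overcorrect.
#' @param batchSpec list of batch-variable descriptors, each a list with
#'   `name`, `type` (`"categorical"`/`"continuous"`), `nLevels` (categorical
#'   only) and `effectSd`.
#' @param hiddenFactors number of hidden (unrecorded) confounders.
#' @param hiddenLoadingSd per-gene loading sd of hidden confounders.
#' @param noiseSd idiosyncratic noise sd.
#' @param confTrue,confFalse,confFiller `c(shape1, shape2)` of the Beta
#'   confidence distributions for true, false and filler edges.
#' @param seed integer seed; generation is bit-reproducible given the config.
#' @return Validated configuration list of class `syntheticConfig`.
#' @export
syntheticConfig <- function(nGenes = 2000L, nSamples = 200L,
                            nTrueEdges = 300L, nFalseEdges = 300L,
                            nFillerEdges = 20000L, rhoTrue = 0.5,
                            nModules = NULL,
                            batchSpec = list(
                              list(name = "SMGEBTCH", type = "categorical",
                                   nLevels = 4L, effectSd = 1.0),
                              list(name = "GENDER", type = "categorical",
                                   nLevels = 2L, effectSd = 0.5),
                              list(name = "SMTSISCH", type = "continuous",
                                   effectSd = 0.5)),
                            hiddenFactors = 0L, hiddenLoadingSd = 0.5,
                            noiseSd = 1, confTrue = c(8, 2),
                            confFalse = c(1, 40), confFiller = c(2, 10),
                            seed = 1L) {
  cfg <- list(nGenes = as.integer(nGenes), nSamples = as.integer(nSamples),
              nTrueEdges = as.integer(nTrueEdges),
              nFalseEdges = as.integer(nFalseEdges),
              nFillerEdges = as.integer(nFillerEdges), rhoTrue = rhoTrue,
              nModules = if (is.null(nModules)) NULL else as.integer(nModules),
              batchSpec = batchSpec, hiddenFactors = as.integer(hiddenFactors),
              hiddenLoadingSd = hiddenLoadingSd, noiseSd = noiseSd,
              confTrue = confTrue, confFalse = confFalse,
              confFiller = confFiller, seed = as.integer(seed))
  if (2L * (cfg$nTrueEdges + cfg$nFalseEdges) > cfg$nGenes)
    .configError("planted pairs need 2*(nTrueEdges + nFalseEdges) <= nGenes")
  if (cfg$rhoTrue <= 0 || cfg$rhoTrue >= 1)
    .configError("rhoTrue must lie strictly in (0, 1)")
  if (cfg$noiseSd <= 0) .configError("noiseSd must be positive")
  if (!is.null(cfg$nModules) && cfg$nModules < 1L)
    .configError("nModules must be >= 1")
  for (b in cfg$batchSpec) {
    if (!all(c("name", "type", "effectSd") %in% names(b)) ||
        !b$type %in% c("categorical", "continuous"))
      .configError("each batchSpec entry needs name, type (categorical/continuous), effectSd")
    if (b$type == "categorical" && (is.null(b$nLevels) || b$nLevels < 2L))
      .configError("categorical batch variable '%s' needs nLevels >= 2", b$name)
    if (b$effectSd < 0)
      .configError("effectSd must be >= 0 for '%s'", b$name)
  }
  nBackground <- cfg$nGenes - 2L * (cfg$nTrueEdges + cfg$nFalseEdges)
  if (cfg$nFillerEdges > 0 &&
      cfg$nFillerEdges > nBackground * (nBackground - 1) / 2)
    .configError("nFillerEdges exceeds the available background gene pairs")
  structure(cfg, class = "syntheticConfig")
}

#' Generate a synthetic benchmark dataset
#'
#' Each planted true pair shares a standard-normal latent module factor; with
#' loading `lambda` and noise sd `sigma` the batch-free pair correlation is
#' `lambda^2 / (lambda^2 + sigma^2) = rhoTrue`. False pairs and background
#' genes are independent, scaled to the same total batch-free variance.
#' Categorical batch variables add per-gene, per-level shifts drawn with the
#' configured sd; continuous variables add per-gene linear slopes on the
#' standardized covariate (the phenotype table stores the raw minutes-like
#' values); hidden factors add per-gene loadings that are *not* recorded in
#' the phenotype table. Confidences come from the configured Beta
#' distributions and the edge list is written in descending-confidence order,
#' the shape confidence-ranked network downloads have.
#'
#' @param config a [syntheticConfig()] (or plain list of its fields).
#' @return A [SyntheticDataset-class].
#' @export
generateSynthetic <- function(config = syntheticConfig()) {
  if (!inherits(config, "syntheticConfig"))
    config <- do.call(syntheticConfig, config)
  withr::with_seed(config$seed, .generateSynthetic(config))
}

.generateSynthetic <- function(cfg) {
  G <- cfg$nGenes; n <- cfg$nSamples
  genes <- sprintf("G%05d", seq_len(G))
  samples <- sprintf("S%04d", seq_len(n))
  nT <- cfg$nTrueEdges; nF <- cfg$nFalseEdges
  trueA <- seq_len(nT) * 2L - 1L
  trueB <- trueA + 1L
  falseA <- 2L * nT + seq_len(nF) * 2L - 1L
  falseB <- falseA + 1L
  background <- setdiff(seq_len(G), c(trueA, trueB, falseA, falseB))

  sigma <- cfg$noiseSd
  lambda <- sigma * sqrt(cfg$rhoTrue / (1 - cfg$rhoTrue))
  totalSd <- sqrt(lambda^2 + sigma^2)
  m <- if (is.null(cfg$nModules)) nT else min(cfg$nModules, nT)
  moduleOf <- ((seq_len(nT) - 1L) %% m) + 1L
  factors <- matrix(rnorm(m * n), m, n)

  expr <- matrix(rnorm(G * n, sd = totalSd), G, n,
                 dimnames = list(genes, samples))
  for (i in seq_len(nT)) {
    f <- factors[moduleOf[i], ]
    expr[trueA[i], ] <- lambda * f + rnorm(n, sd = sigma)
    expr[trueB[i], ] <- lambda * f + rnorm(n, sd = sigma)
  }

  pheno <- data.frame(row.names = samples)
  batchCoefs <- list()
  for (b in cfg$batchSpec) {
    if (b$type == "categorical") {
      lev <- paste0(substr(b$name, 1, 1), seq_len(b$nLevels))
      assign <- factor(sample(lev, n, replace = TRUE), levels = lev)
      pheno[[b$name]] <- assign
      coefs <- matrix(rnorm(G * b$nLevels, sd = b$effectSd), G, b$nLevels,
                      dimnames = list(genes, lev))
      expr <- expr + coefs[, as.integer(assign)]
      batchCoefs[[b$name]] <- coefs
    } else {
      minutes <- runif(n, 0, 1500)
      pheno[[b$name]] <- minutes
      z <- as.numeric(scale(minutes))
      slopes <- rnorm(G, sd = b$effectSd)
      expr <- expr + outer(slopes, z)
      batchCoefs[[b$name]] <- slopes
    }
  }

  hiddenLoadings <- NULL
  if (cfg$hiddenFactors > 0L) {
    H <- matrix(rnorm(cfg$hiddenFactors * n), cfg$hiddenFactors, n)
    hiddenLoadings <- matrix(rnorm(G * cfg$hiddenFactors,
                                   sd = cfg$hiddenLoadingSd),
                             G, cfg$hiddenFactors)
    expr <- expr + hiddenLoadings %*% H
  }

  confT <- rbeta(nT, cfg$confTrue[1], cfg$confTrue[2])
  confF <- rbeta(nF, cfg$confFalse[1], cfg$confFalse[2])
  edges <- data.frame(
    gene_a = c(genes[trueA], genes[falseA]),
    gene_b = c(genes[trueB], genes[falseB]),
    confidence = c(confT, confF),
    label = c(rep(1L, nT), rep(0L, nF)))
  if (cfg$nFillerEdges > 0L) {
    filler <- .sampleDistinctPairs(background, cfg$nFillerEdges)
    edges <- rbind(edges, data.frame(
      gene_a = genes[filler[, 1]], gene_b = genes[filler[, 2]],
      confidence = rbeta(cfg$nFillerEdges, cfg$confFiller[1],
                         cfg$confFiller[2]),
      label = NA_integer_))
  }
  ord <- order(-edges$confidence)
  edges <- edges[ord, , drop = FALSE]
  rownames(edges) <- NULL
  truth <- edges[!is.na(edges$label), c("gene_a", "gene_b", "label")]
  rownames(truth) <- NULL
  edges$label <- NULL

  new("SyntheticDataset", expr = expr, pheno = pheno, edges = edges,
      truth = truth,
      params = list(lambda = lambda, sigma = sigma, totalSd = totalSd,
                    moduleOf = moduleOf, modules = m,
                    batchCoefs = batchCoefs,
                    hiddenLoadings = hiddenLoadings),
      config = unclass(cfg))
}

# Sample k distinct unordered pairs from a gene-index pool without
# enumerating all pairs.
.sampleDistinctPairs <- function(pool, k) {
  seen <- character(0)
  out <- matrix(0L, k, 2L)
  got <- 0L
  while (got < k) {
    need <- k - got
    a <- sample(pool, 2L * need, replace = TRUE)
    b <- sample(pool, 2L * need, replace = TRUE)
    ok <- a != b
    lo <- pmin(a, b)[ok]; hi <- pmax(a, b)[ok]
    key <- paste(lo, hi)
    fresh <- !duplicated(key) & !(key %in% seen)
    lo <- lo[fresh]; hi <- hi[fresh]
    take <- min(length(lo), need)
    if (take > 0) {
      idx <- seq_len(take)
      out[got + idx, 1] <- lo[idx]
      out[got + idx, 2] <- hi[idx]
      seen <- c(seen, paste(lo[idx], hi[idx]))
      got <- got + take
    }
  }
  out
}

#' Gold standard from a synthetic dataset's planted truth
#'
#' Builds a [GoldStandard-class] directly from the generative labels,
#' bypassing confidence calibration — the reference evaluation when the
#' planted truth is available. Nominal confidences consistent with the
#' default cutoffs (0.5 / 0.025) are attached.
#'
#' @param dataset a [SyntheticDataset-class].
#' @return A [GoldStandard-class] over the planted true/false pairs.
#' @export
goldStandardFromTruth <- function(dataset) {
  tr <- truthTable(dataset)
  edges <- data.frame(gene_a = tr$gene_a, gene_b = tr$gene_b,
                      confidence = ifelse(tr$label == 1, 0.9, 0.001),
                      label = as.integer(tr$label))
  new("GoldStandard", edges = edges, cutoffTrue = 0.5, cutoffFalse = 0.025)
}

#' Write a synthetic dataset's tables to a directory
#'
#' Writes `expr.tsv`, `pheno.tsv`, `edges.tsv`, `truth.tsv` and
#' `config.yaml` — the four framework inputs plus the generative record, all
#' plain text.
#'
#' @param dataset a [SyntheticDataset-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSyntheticDataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeExpression(exprMatrix(dataset), file.path(dir, "expr.tsv"))
  writePhenotypes(phenoTable(dataset), file.path(dir, "pheno.tsv"))
  writeEdgeList(edgeList(dataset), file.path(dir, "edges.tsv"))
  write.table(truthTable(dataset), file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cfg <- dataset@config
  cfg$nModules <- if (is.null(cfg$nModules)) "default" else cfg$nModules
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}
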