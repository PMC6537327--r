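# End-to-end orchestration: gold standard -> per-method adjustment ->
# edge scoring -> ROC/AUC comparison, from a single configuration.

.pipelineMethods <- c("raw", "LR", "PEER", "PCA", "PCA_opt", "ComBat")

.normalizeMethodSpec <- function(methods) {
  if (length(methods) == 0L)
    .configError("config must request at least one method")
  out <- lapply(methods, function(m) {
    if (is.character(m)) m <- list(name = m)
    if (is.null(m$name))
      .configError("every method entry needs a 'name'")
    if (!m$name %in% .pipelineMethods)
      .configError("unknown method '%s'; available: %s", m$name,
                   paste(.pipelineMethods, collapse = ", "))
    m
  })
  names(out) <- vapply(out, function(m) m$name, character(1))
  if (anyDuplicated(names(out)))
    .configError("duplicate method entries: %s",
                 paste(unique(names(out)[duplicated(names(out))]),
                       collapse = ", "))
  out
}

#' Run the full benchmark pipeline from one configuration
#'
#' Stages: load (or synthesize) the inputs; build the calibrated gold
#' standard and restrict it to the dataset; adjust the expression matrix with
#' every requested method — the unadjusted `"raw"` baseline is always
#' evaluated, since the framework's question is whether adjustment helps
#' relative to it — score all gold-standard edges per method; compare by
#' ROC/AUC and summarize the Spearman distributions. Writes one score table
#' and ROC table per method, an AUC summary, and a JSON manifest (package
#' version, seed, config hash, per-stage counts) sufficient to reproduce the
#' run.
#'
#' @param config a configuration list, or path to a YAML file holding one.
#'   Fields: `seed`; `outDir`; `data` (either paths `expr`/`pheno`/
#'   `factors`/`edges` with an optional `phenoTypes` type map, or
#'   `synthetic = list(...)` passed to [syntheticConfig()]); `goldStandard`
#'   (`nCandidates`, and either `calibrate = TRUE` with optional calibration
#'   parameters, or explicit `cutoffTrue`/`cutoffFalse`); `preprocess`
#'   (optional `minMean`, `quantile`, `inverseNormal`); `methods`, a list of
#'   method entries (name plus method-specific parameters such as
#'   `covariates`, `numPCs`, `batchVariables`); `plots`.
#' @return Invisibly, a list with `aucSummary` (data.frame), `rocs`,
#'   `scores`, `goldStandard`, `density` and `outDir`.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) .configError("config must be a list or YAML path")
  methods <- .normalizeMethodSpec(config$methods)   # fail fast
  if (!"raw" %in% names(methods))
    methods <- c(list(raw = list(name = "raw")), methods)
  outDir <- config$outDir
  if (is.null(outDir)) .configError("config needs an outDir")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  set.seed(seed)

  counts <- list()
  # ---- inputs -------------------------------------------------------------
  factors <- NULL
  if (!is.null(config$data$synthetic)) {
    synCfg <- config$data$synthetic
    if (is.null(synCfg$seed)) synCfg$seed <- seed
    dataset <- generateSynthetic(do.call(syntheticConfig, synCfg))
    expr <- exprMatrix(dataset)
    pheno <- phenoTable(dataset)
    edges <- edgeList(dataset)
  } else {
    d <- config$data
    if (is.null(d$expr) || is.null(d$edges))
      .configError("config$data needs expr and edges paths (or synthetic)")
    expr <- readExpression(d$expr,
                           dialect = if (is.null(d$dialect)) "tsv" else d$dialect)
    pheno <- if (is.null(d$pheno)) NULL
             else readPhenotypes(d$pheno, typeSpec = d$phenoTypes)
    factors <- if (is.null(d$factors)) NULL else readFactors(d$factors)
    edges <- readEdgeList(d$edges)
  }
  counts$genes <- nrow(expr); counts$samples <- ncol(expr)
  counts$networkEdges <- nrow(edges)

  # ---- optional preprocessing --------------------------------------------
  pp <- config$preprocess
  if (!is.null(pp$minMean)) expr <- filterLowExpression(expr, pp$minMean)
  if (isTRUE(pp$quantile)) expr <- quantileNormalize(expr)
  if (isTRUE(pp$inverseNormal)) expr <- inverseNormalTransform(expr)
  counts$genesAfterPreprocess <- nrow(expr)

  # ---- gold standard ------------------------------------------------------
  gsCfg <- if (is.null(config$goldStandard)) list() else config$goldStandard
  nCand <- if (is.null(gsCfg$nCandidates)) 100000L else gsCfg$nCandidates
  cand <- takeCandidateEdges(edges, n = min(nCand, nrow(edges)))
  if (isTRUE(gsCfg$calibrate)) {
    cal <- calibrateCutoffs(
      cand,
      low0 = if (is.null(gsCfg$low0)) 0.01 else gsCfg$low0,
      high0 = if (is.null(gsCfg$high0)) 0.7 else gsCfg$high0,
      stepLow = if (is.null(gsCfg$stepLow)) 0.005 else gsCfg$stepLow,
      stepHigh = if (is.null(gsCfg$stepHigh)) 0.05 else gsCfg$stepHigh,
      balanceTol = if (is.null(gsCfg$balanceTol)) 1.25 else gsCfg$balanceTol)
    cutTrue <- cal$cutoffTrue; cutFalse <- cal$cutoffFalse
  } else {
    cutTrue <- if (is.null(gsCfg$cutoffTrue)) 0.5 else gsCfg$cutoffTrue
    cutFalse <- if (is.null(gsCfg$cutoffFalse)) 0.025 else gsCfg$cutoffFalse
  }
  gs <- buildGoldStandard(cand, cutoffTrue = cutTrue, cutoffFalse = cutFalse)
  gs <- restrictToDataset(gs, expr)
  counts$goldTrue <- nTrueEdges(gs); counts$goldFalse <- nFalseEdges(gs)
  writeEdgeList(gs, file.path(outDir, "gold_standard.tsv"))

  # ---- adjust + score -----------------------------------------------------
  scores <- list()
  for (m in names(methods)) {
    spec <- methods[[m]]
    adjusted <- adjustExpression(
      expr, method = spec$name, pheno = pheno,
      covariates = if (is.null(spec$covariates)) NULL
                   else unlist(spec$covariates),
      factors = factors,
      numPCs = spec$numPCs, cumVarThreshold = spec$cumVarThreshold,
      combatConfig = if (spec$name == "ComBat")
        combatConfig(batchVariables = if (is.null(spec$batchVariables))
          colnames(pheno) else unlist(spec$batchVariables)) else NULL)
    gsm <- if (identical(dim(adjusted), dim(expr))) gs
           else restrictToDataset(gs, adjusted)
    scores[[m]] <- scoreEdges(adjusted, gsm, method = m)
    writeScores(scores[[m]], file.path(outDir, paste0("scores_", m, ".tsv")))
  }
  shared <- Reduce(intersect, lapply(scores, function(s) .edgeKey(coexEdges(s))))
  scores <- lapply(scores, function(s) {
    e <- coexEdges(s)
    keep <- .edgeKey(e) %in% shared
    initialize(s, edges = e[keep, , drop = FALSE])
  })

  # ---- evaluate -----------------------------------------------------------
  rocs <- compareMethods(scores, outDir = outDir,
                         plot = isTRUE(config$plots))
  dens <- densitySummary(scores)
  write.table(dens@stats, file.path(outDir, "rs_density_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  aucSummary <- data.frame(
    method = vapply(rocs, slot, character(1), "method"),
    auc = vapply(rocs, auc, numeric(1)))

  manifest <- list(
    package = "coexBench",
    version = as.character(packageVersion("coexBench")),
    seed = seed,
    configHash = .hashConfig(config),
    config = config,
    counts = counts,
    auc = setNames(as.list(aucSummary$auc), aucSummary$method))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  .log("pipeline done: %d methods, gold standard %d true / %d false",
       length(scores), counts$goldTrue, counts$goldFalse)
  invisible(list(aucSummary = aucSummary, rocs = rocs, scores = scores,
                 goldStandard = gs, density = dens, outDir = outDir))
}

.hashConfig <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              null = "null", force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}
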