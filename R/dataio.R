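# Readers and writers for the four input formats plus result tables.
# Expression travels as plain numeric matrices (genes x samples), phenotypes
# as typed data.frames with sample rownames, factor matrices as numeric
# matrices (factors x samples), edge lists as data.frames in file order.

.readTable <- function(path) {
  if (!file.exists(path)) .formatError("file not found: %s", path)
  path
}

.numericOrParseError <- function(df, what) {
  for (j in seq_along(df)) {
    v <- df[[j]]
    if (is.character(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v) & v != "NA" & v != "")
      if (length(bad))
        .parseError("non-numeric value '%s' in %s (row %d, column '%s')",
                    v[bad[1]], what, bad[1], names(df)[j])
      df[[j]] <- num
    }
  }
  df
}

#' Read a gene-expression matrix
#'
#' Reads a genes-by-samples expression table from plain TSV (first column =
#' gene identifiers, header = sample identifiers) or GCT v1.2 (two-line
#' preamble `#1.2` / dimensions, then `Name`, `Description` and sample
#' columns; the `Description` column is ignored).
#'
#' @param path path to the file.
#' @param dialect `"tsv"` or `"gct"`.
#' @return Numeric matrix, genes x samples, with unique dimnames.
#' @seealso [writeExpression()]
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeExpression(matrix(1:6, 3, 2,
#'   dimnames = list(paste0("G", 1:3), c("S1", "S2"))), tf)
#' readExpression(tf)
#' @export
readExpression <- function(path, dialect = c("tsv", "gct")) {
  dialect <- match.arg(dialect)
  .readTable(path)
  skip <- 0L
  if (dialect == "gct") {
    preamble <- readLines(path, n = 2L)
    if (length(preamble) < 2L || !startsWith(preamble[1], "#1.2"))
      .formatError("GCT file must start with a '#1.2' preamble: %s", path)
    skip <- 2L
  }
  df <- tryCatch(
    read.delim(path, skip = skip, check.names = FALSE,
               colClasses = "character"),
    error = function(e) .formatError("malformed expression header in %s: %s",
                                     path, conditionMessage(e)))
  if (ncol(df) < 2L)
    .formatError("expression table needs a gene column plus >=1 sample: %s",
                 path)
  genes <- df[[1L]]
  df <- df[-1L]
  if (dialect == "gct" && tolower(names(df)[1]) == "description")
    df <- df[-1L]
  if (anyDuplicated(genes))
    .validationError("duplicate gene identifier(s) in %s: %s", path,
                     paste(unique(genes[duplicated(genes)]), collapse = ", "))
  if (anyDuplicated(names(df)))
    .validationError("duplicate sample identifier(s) in %s", path)
  df <- .numericOrParseError(df, basename(path))
  expr <- as.matrix(df)
  rownames(expr) <- genes
  .checkExpression(expr)
  .log("read expression: %d genes x %d samples from %s",
       nrow(expr), ncol(expr), basename(path))
  expr
}

#' Write a gene-expression matrix as TSV
#'
#' Values are written with 17 significant digits so that a write-then-read
#' round trip reproduces finite doubles bit-identically.
#'
#' @param expr numeric matrix, genes x samples.
#' @param path output path.
#' @param geneColumn header for the gene-identifier column.
#' @return `path`, invisibly.
#' @export
writeExpression <- function(expr, path, geneColumn = "gene_id") {
  .checkExpression(expr, requireFinite = FALSE)
  chr <- matrix(sprintf("%.17g", expr), nrow(expr), ncol(expr))
  out <- cbind(rownames(expr), chr)
  colnames(out) <- c(geneColumn, colnames(expr))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-sample phenotype table
#'
#' The first column must hold sample identifiers. Every requested variable is
#' coerced according to `typeSpec`: `"categorical"` variables become factors
#' with sorted levels, `"continuous"` variables become numerics. Missing
#' cells (`NA` or empty) are kept as `NA`; samples are never dropped here.
#'
#' @param path path to a TSV file.
#' @param typeSpec named character vector / list mapping variable name to
#'   `"categorical"` or `"continuous"`.
#' @param variables variables to keep; defaults to `names(typeSpec)`. A
#'   requested variable absent from `typeSpec` is a configuration error.
#' @return `data.frame` with sample identifiers as rownames and one typed
#'   column per variable.
#' @export
readPhenotypes <- function(path, typeSpec, variables = names(typeSpec)) {
  .readTable(path)
  typeSpec <- unlist(typeSpec)
  if (is.null(names(typeSpec)) || !all(nzchar(names(typeSpec))))
    .configError("typeSpec must be a named mapping to categorical/continuous")
  if (!all(typeSpec %in% c("categorical", "continuous")))
    .configError("typeSpec values must be 'categorical' or 'continuous'")
  missingSpec <- setdiff(variables, names(typeSpec))
  if (length(missingSpec))
    .configError("typeSpec omits requested variable(s): %s",
                 paste(missingSpec, collapse = ", "))
  df <- read.delim(path, check.names = FALSE, colClasses = "character",
                   na.strings = c("NA", ""))
  if (ncol(df) < 1L || anyDuplicated(df[[1L]]) || anyNA(df[[1L]]))
    .formatError("phenotype table needs a leading sample-ID column with unique ids: %s",
                 path)
  ids <- df[[1L]]
  absent <- setdiff(variables, names(df)[-1L])
  if (length(absent))
    .formatError("phenotype table %s lacks column(s): %s", path,
                 paste(absent, collapse = ", "))
  out <- data.frame(row.names = ids)
  for (v in variables) {
    col <- df[[v]]
    if (typeSpec[[v]] == "continuous") {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad))
        .parseError("non-numeric value '%s' in continuous phenotype '%s' (row %d)",
                    col[bad[1]], v, bad[1])
      out[[v]] <- num
    } else {
      out[[v]] <- factor(col, levels = sort(unique(col[!is.na(col)])))
    }
  }
  .log("read phenotypes: %d samples, %d variables from %s",
       nrow(out), ncol(out), basename(path))
  out
}

#' Write a phenotype table as TSV
#' @param pheno `data.frame` with sample rownames.
#' @param path output path.
#' @param idColumn header for the sample-ID column.
#' @return `path`, invisibly.
#' @export
writePhenotypes <- function(pheno, path, idColumn = "sample_id") {
  .checkPhenotypes(pheno)
  asChr <- function(v) {
    if (is.numeric(v)) ifelse(is.na(v), NA_character_, sprintf("%.17g", v))
    else as.character(v)
  }
  out <- cbind(setNames(data.frame(rownames(pheno)), idColumn),
               as.data.frame(lapply(pheno, asChr)))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read a confidence-scored gene-gene edge list
#'
#' Rows are `gene_a gene_b confidence`, whitespace- or tab-delimited, with or
#' without a header line. File order is preserved exactly; candidate-edge
#' selection ([takeCandidateEdges()]) depends on it. Self-edges, duplicated
#' unordered pairs and confidences outside \[0, 1\] are validation errors.
#'
#' @param path path to the file.
#' @return `data.frame` with columns `gene_a`, `gene_b`, `confidence`, in
#'   file order.
#' @export
readEdgeList <- function(path) {
  .readTable(path)
  df <- tryCatch(read.table(path, header = FALSE, colClasses = "character"),
                 error = function(e)
                   .formatError("malformed edge list %s: %s", path,
                                conditionMessage(e)))
  if (ncol(df) != 3L)
    .formatError("edge list must have exactly 3 columns, found %d: %s",
                 ncol(df), path)
  # tolerate a header line: its third field will not parse as a number
  suppressWarnings(firstConf <- as.numeric(df[[3L]][1L]))
  if (is.na(firstConf)) df <- df[-1L, , drop = FALSE]
  suppressWarnings(conf <- as.numeric(df[[3L]]))
  bad <- which(is.na(conf))
  if (length(bad))
    .parseError("non-numeric confidence '%s' at edge-list row %d",
                df[[3L]][bad[1]], bad[1])
  edges <- data.frame(gene_a = df[[1L]], gene_b = df[[2L]],
                      confidence = conf, row.names = NULL)
  .checkEdgeList(edges)
  .log("read edge list: %d edges from %s", nrow(edges), basename(path))
  edges
}

#' Write an edge list (or labeled gold standard) as TSV
#' @param edges `data.frame` with `gene_a`, `gene_b`, `confidence` (and
#'   optionally `label`); or a [GoldStandard-class].
#' @param path output path.
#' @param header write a header line?
#' @return `path`, invisibly.
#' @export
writeEdgeList <- function(edges, path, header = FALSE) {
  if (is(edges, "GoldStandard")) {
    edges <- goldEdges(edges)
    header <- TRUE
  }
  out <- edges
  out$confidence <- sprintf("%.17g", edges$confidence)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = header)
  invisible(path)
}

#' Read a hidden-factor matrix (factors x samples)
#'
#' PEER-style covariate files: first column factor identifiers, remaining
#' columns one per sample, all cells numeric. A factor row that is constant
#' (e.g. all zeros) is accepted with a logged warning since it carries no
#' adjustable signal.
#'
#' @param path path to a TSV file.
#' @return Numeric matrix, factors x samples.
#' @export
readFactors <- function(path) {
  .readTable(path)
  if (length(readLines(path, n = 1L)) == 0L)
    .formatError("empty factor file: %s", path)
  df <- read.delim(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L)
    .formatError("factor file needs an ID column plus >=1 sample: %s", path)
  ids <- df[[1L]]
  df <- .numericOrParseError(df[-1L], basename(path))
  fac <- as.matrix(df)
  rownames(fac) <- ids
  if (anyNA(fac))
    .parseError("missing value(s) in factor file %s", path)
  if (nrow(fac) > 0 && ncol(fac) > 1) {
    const <- apply(fac, 1, function(v) diff(range(v)) == 0)
    if (any(const)) {
      warning(sprintf("constant factor row(s) in %s: %s", basename(path),
                      paste(ids[const], collapse = ", ")), call. = FALSE)
      .log("factor file has %d constant row(s)", sum(const))
    }
  }
  .log("read factors: %d factors x %d samples from %s",
       nrow(fac), ncol(fac), basename(path))
  fac
}

#' Write a factor matrix as TSV
#' @param factors numeric matrix, factors x samples.
#' @param path output path.
#' @param idColumn header for the factor-ID column.
#' @return `path`, invisibly.
#' @export
writeFactors <- function(factors, path, idColumn = "factor_id") {
  chr <- matrix(sprintf("%.17g", factors), nrow(factors), ncol(factors))
  out <- cbind(rownames(factors), chr)
  colnames(out) <- c(idColumn, colnames(factors))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
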