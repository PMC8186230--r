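#' Read an expression matrix from TSV
#'
#' Expects a tab-separated file whose first column holds gene identifiers and
#' whose header row holds sample identifiers (first header field is a label
#' such as `gene_id`). An optional leading directive line `# scale: log2`
#' (written by [writeExpressionMatrix()]) switches the scale flag; without it
#' the matrix is taken as linear-scale intensities.
#'
#' @param path path to the TSV file.
#' @return A validated [ExprMatrix-class].
#' @seealso [writeExpressionMatrix()], [readLabels()]
#' @export
readExpressionMatrix <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  first <- readLines(path, n = 1L)
  scale <- "linear"
  skip <- 0L
  if (startsWith(first, "#")) {
    skip <- 1L
    m <- regmatches(first, regexec("scale:\\s*(linear|log2)", first))[[1L]]
    if (length(m) == 2L) scale <- m[2L]
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t", skip = skip,
                          check.names = FALSE, colClasses = "character",
                          comment.char = "")
  if (ncol(df) < 2L)
    stop("expression matrix needs a gene column and at least one sample",
         call. = FALSE)
  gid <- df[[1L]]
  sid <- colnames(df)[-1L]
  if (anyDuplicated(gid))
    stop(sprintf("duplicated gene identifier: '%s'", gid[duplicated(gid)][1L]),
         call. = FALSE)
  if (anyDuplicated(sid))
    stop(sprintf("duplicated sample identifier: '%s'", sid[duplicated(sid)][1L]),
         call. = FALSE)
  vals <- suppressWarnings(
    vapply(df[-1L], as.numeric, numeric(nrow(df))))
  vals <- matrix(vals, nrow = nrow(df),
                 dimnames = list(gid, sid))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric value at gene '%s', sample '%s'",
                 gid[bad[1L]], sid[bad[2L]]), call. = FALSE)
  }
  ExprMatrix(vals, scale = scale)
}

#' Write an expression matrix to TSV
#'
#' Writes a `# scale:` directive line, a header `gene_id<TAB>samples...`, and
#' one gene per row. Values are written at full precision (15 significant
#' digits) so that a write/read round trip reproduces the matrix.
#'
#' @param x an [ExprMatrix-class].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
writeExpressionMatrix <- function(x, path) {
  stopifnot(is(x, "ExprMatrix"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# scale: %s", exprScale(x)), con)
  writeLines(paste(c("gene_id", sampleIds(x)), collapse = "\t"), con)
  vals <- format(exprValues(x), digits = 15, trim = TRUE, scientific = FALSE)
  writeLines(paste(geneIds(x), apply(vals, 1L, paste, collapse = "\t"),
                   sep = "\t"), con)
  invisible(path)
}

#' Read a sample label table and attach it to a matrix
#'
#' Expects a two-column TSV `sample_id<TAB>class` with class names `PA`
#' (phlegmonous) or `GA` (gangrenous). Every labeled sample must exist in the
#' companion matrix, every matrix sample must be labeled, and each class
#' needs at least 2 samples (the Welch test and the logistic fit both require
#' within-group variance).
#'
#' @param path path to the label TSV.
#' @param x the companion [ExprMatrix-class].
#' @return `x` with labels attached (`colData(x)$class`).
#' @export
readLabels <- function(path, x) {
  stopifnot(is(x, "ExprMatrix"))
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  if (ncol(df) < 2L)
    stop("label table needs columns sample_id and class", call. = FALSE)
  labels <- stats::setNames(df[[2L]], df[[1L]])
  classLabels(x) <- labels
  x
}

#' Write a sample label table
#'
#' @param x an [ExprMatrix-class] with labels attached.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
writeLabels <- function(x, path) {
  cls <- classLabels(x)
  if (is.null(cls)) stop("no labels attached", call. = FALSE)
  writeResultTable(
    data.frame(sample_id = sampleIds(x), class = as.character(cls)), path)
}

#' Write a result table to TSV
#'
#' Tab-separated output with a header row; numeric columns are rounded to 6
#' significant digits. Refuses to write an empty table.
#'
#' @param records a non-empty data.frame.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
writeResultTable <- function(records, path) {
  records <- as.data.frame(records)
  if (nrow(records) == 0L)
    stop("refusing to write an empty result table", call. = FALSE)
  num <- vapply(records, is.numeric, logical(1L)) &
    !vapply(records, is.integer, logical(1L))
  records[num] <- lapply(records[num], signif, digits = 6L)
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a result table written by [writeResultTable()]
#'
#' @param path path to the TSV file.
#' @return A data.frame.
#' @export
readResultTable <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
}
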