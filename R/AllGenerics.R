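#' @rdname ExprMatrix-accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname ExprMatrix-accessors
#' @export
setGeneric("exprScale", function(x) standardGeneric("exprScale"))

#' @rdname ExprMatrix-accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname ExprMatrix-accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname ExprMatrix-accessors
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname ExprMatrix-accessors
#' @export
setGeneric("classLabels<-", function(x, value) standardGeneric("classLabels<-"))

#' @rdname ExprMatrix-accessors
#' @export
setGeneric("modelView", function(x) standardGeneric("modelView"))

#' Accessors for ExprMatrix
#'
#' `exprValues()` returns the gene x sample intensity matrix, `exprScale()`
#' the `"linear"`/`"log2"` flag, `geneIds()`/`sampleIds()` the identifiers,
#' and `classLabels()` the attached PA/GA factor (or `NULL`). `modelView()`
#' returns the transposed, model-facing n-samples x p-genes matrix that the
#' classifier consumes. `classLabels<-` attaches labels given as a PA/GA
#' factor or character vector, or as 0/1 codes (0 = PA, 1 = GA), optionally
#' named by sample identifier.
#'
#' @param x an [ExprMatrix-class].
#' @param value class labels (see description).
#' @return See description; `classLabels<-` returns the updated object.
#' @name ExprMatrix-accessors
NULL

#' @rdname ExprMatrix-accessors
#' @export
setMethod("exprValues", "ExprMatrix", function(x)
  SummarizedExperiment::assay(x, "exprs"))

#' @rdname ExprMatrix-accessors
#' @export
setMethod("exprScale", "ExprMatrix", function(x) x@scaleFlag)

#' @rdname ExprMatrix-accessors
#' @export
setMethod("geneIds", "ExprMatrix", function(x) rownames(x))

#' @rdname ExprMatrix-accessors
#' @export
setMethod("sampleIds", "ExprMatrix", function(x) colnames(x))

#' @rdname ExprMatrix-accessors
#' @export
setMethod("classLabels", "ExprMatrix", function(x) {
  cls <- SummarizedExperiment::colData(x)$class
  if (is.null(cls)) return(NULL)
  stats::setNames(cls, colnames(x))
})

#' @rdname ExprMatrix-accessors
#' @export
setMethod("classLabels<-", "ExprMatrix", function(x, value) {
  value <- normalizeLabels(value, sampleIds(x))
  SummarizedExperiment::colData(x)$class <- value
  validObject(x)
  x
})

#' @rdname ExprMatrix-accessors
#' @export
setMethod("modelView", "ExprMatrix", function(x) t(exprValues(x)))

# Coerce user-supplied labels to a PA/GA factor in matrix sample order.
normalizeLabels <- function(value, sids) {
  if (is.numeric(value)) {
    if (!all(value %in% c(0, 1)))
      stop("numeric labels must be 0 (PA) or 1 (GA)", call. = FALSE)
    lab <- c("PA", "GA")[value + 1L]
    names(lab) <- names(value)
    value <- lab
  }
  if (is.factor(value)) {
    nm <- names(value)
    value <- stats::setNames(as.character(value), nm)
  }
  if (!is.null(names(value))) {
    missing <- setdiff(names(value), sids)
    if (length(missing))
      stop(sprintf("labeled sample '%s' is not in the matrix", missing[1L]),
           call. = FALSE)
    if (!setequal(names(value), sids))
      stop("labels must cover every sample in the matrix", call. = FALSE)
    value <- value[sids]
  } else if (length(value) != length(sids)) {
    stop("unnamed labels must have one entry per sample", call. = FALSE)
  }
  bad <- setdiff(unique(value), c("PA", "GA"))
  if (length(bad))
    stop(sprintf("unknown class name '%s' (expected PA or GA)", bad[1L]),
         call. = FALSE)
  factor(value, levels = c("PA", "GA"))
}

# Binary 0/1 codes (PA = 0, GA = 1) for an ExprMatrix with labels attached.
labelCodes <- function(x) {
  cls <- classLabels(x)
  if (is.null(cls))
    stop("no class labels attached to the matrix", call. = FALSE)
  as.integer(cls) - 1L
}
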