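#' Quantile-normalize sample columns
#'
#' Classic across-sample quantile normalization: the k-th smallest value of
#' every sample column is replaced by the mean of the k-th smallest values
#' across all columns, so that every column shares one empirical
#' distribution. Ties within a column receive the mean of the reference
#' values over their tied rank span. Delegates to
#' [limma::normalizeQuantiles()] (ties = TRUE), the canonical microarray
#' implementation of exactly this convention.
#'
#' Applied once to the full matrix before any resampling; see
#' [runDiscoveryValidation()]'s `renormalize` flag for the per-bootstrap
#' alternative used in leakage-sensitivity analyses.
#'
#' @param x an [ExprMatrix-class] with at least 2 samples.
#' @return An [ExprMatrix-class] on the same scale, labels preserved.
#' @export
quantileNormalize <- function(x) {
  stopifnot(is(x, "ExprMatrix"))
  if (ncol(x) < 2L)
    stop("quantile normalization needs at least 2 samples", call. = FALSE)
  vals <- limma::normalizeQuantiles(exprValues(x), ties = TRUE)
  dimnames(vals) <- dimnames(exprValues(x))
  out <- ExprMatrix(vals, scale = exprScale(x))
  cls <- classLabels(x)
  if (!is.null(cls)) classLabels(out) <- cls
  out
}

#' Log2-transform a linear-scale matrix
#'
#' Element-wise log2 with no pseudo-count: strict positivity is an invariant
#' of linear-scale matrices, so zeros never reach this point silently.
#'
#' @param x a linear-scale [ExprMatrix-class].
#' @return An [ExprMatrix-class] with `scaleFlag = "log2"`.
#' @export
log2Transform <- function(x) {
  stopifnot(is(x, "ExprMatrix"))
  if (exprScale(x) != "linear")
    stop("matrix is already on the log2 scale", call. = FALSE)
  vals <- exprValues(x)
  if (any(vals <= 0)) {
    bad <- which(vals <= 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-positive intensity at gene '%s', sample '%s'",
                 geneIds(x)[bad[1L]], sampleIds(x)[bad[2L]]), call. = FALSE)
  }
  out <- ExprMatrix(log2(vals), scale = "log2")
  cls <- classLabels(x)
  if (!is.null(cls)) classLabels(out) <- cls
  out
}

#' Preprocess a linear matrix for analysis
#'
#' Quantile normalization on the linear scale followed by log2
#' transformation, the order used throughout this package.
#'
#' @param x a linear-scale [ExprMatrix-class].
#' @param normalize set `FALSE` to skip quantile normalization.
#' @return A log2-scale [ExprMatrix-class].
#' @export
preprocessMatrix <- function(x, normalize = TRUE) {
  if (normalize) x <- quantileNormalize(x)
  log2Transform(x)
}
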