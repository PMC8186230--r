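#' @import methods
#' @importFrom stats pt sd quantile rnorm runif var setNames aggregate
#' @importFrom utils read.delim write.table packageVersion
NULL

#' ExprMatrix: a two-class expression intensity matrix
#'
#' Thin extension of [SummarizedExperiment::SummarizedExperiment] that carries
#' a gene x sample intensity matrix in the `"exprs"` assay together with an
#' explicit scale flag (`"linear"` or `"log2"`). Class labels, when attached,
#' live in `colData()$class` as a factor with levels `PA` (phlegmonous,
#' code 0) and `GA` (gangrenous, code 1).
#'
#' Validity requires unique, non-empty gene and sample identifiers, no
#' missing or non-finite values, and strictly positive intensities on the
#' linear scale.
#'
#' @slot scaleFlag character, `"linear"` or `"log2"`.
#' @export
setClass("ExprMatrix",
  contains = "SummarizedExperiment",
  representation(scaleFlag = "character"),
  prototype(scaleFlag = "linear")
)

setValidity("ExprMatrix", function(object) {
  msg <- character()
  if (!identical(length(object@scaleFlag), 1L) ||
      !object@scaleFlag %in% c("linear", "log2"))
    msg <- c(msg, "scaleFlag must be one of 'linear', 'log2'")
  if (!"exprs" %in% SummarizedExperiment::assayNames(object))
    return(c(msg, "assay 'exprs' is required"))
  x <- SummarizedExperiment::assay(object, "exprs")
  gid <- rownames(object)
  sid <- colnames(object)
  if (is.null(gid) || anyNA(gid) || any(gid == ""))
    msg <- c(msg, "gene identifiers (rownames) must be non-empty")
  if (is.null(sid) || anyNA(sid) || any(sid == ""))
    msg <- c(msg, "sample identifiers (colnames) must be non-empty")
  if (!is.null(gid) && anyDuplicated(gid))
    msg <- c(msg, sprintf("duplicated gene identifier: '%s'",
                          gid[duplicated(gid)][1L]))
  if (!is.null(sid) && anyDuplicated(sid))
    msg <- c(msg, sprintf("duplicated sample identifier: '%s'",
                          sid[duplicated(sid)][1L]))
  if (!is.numeric(x) || any(!is.finite(x)))
    msg <- c(msg, "expression values must be finite numbers (no NA)")
  if (identical(object@scaleFlag, "linear") && is.numeric(x) &&
      all(is.finite(x)) && any(x <= 0)) {
    bad <- which(x <= 0, arr.ind = TRUE)[1L, ]
    msg <- c(msg, sprintf(
      "linear-scale intensities must be > 0 (gene '%s', sample '%s')",
      gid[bad[1L]], sid[bad[2L]]))
  }
  cls <- SummarizedExperiment::colData(object)$class
  if (!is.null(cls)) {
    if (!is.factor(cls) || !identical(levels(cls), c("PA", "GA")) || anyNA(cls))
      msg <- c(msg, "colData$class must be a complete factor with levels PA, GA")
    else if (any(table(cls) < 2L))
      msg <- c(msg, "both classes need at least 2 samples")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an ExprMatrix
#'
#' @param values numeric matrix, genes in rows, samples in columns. Row and
#'   column names are used as gene and sample identifiers unless `geneIds` /
#'   `sampleIds` are given.
#' @param geneIds,sampleIds optional character vectors of identifiers.
#' @param scale `"linear"` (default) or `"log2"`.
#' @param labels optional class labels (factor or character with values
#'   `"PA"`/`"GA"`, or 0/1 codes), named by sample or in column order.
#' @return A validated [ExprMatrix-class] object.
#' @examples
#' m <- matrix(2^rnorm(12, 8), 4, 3,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
#' ExprMatrix(m)
#' @export
ExprMatrix <- function(values, geneIds = rownames(values),
                       sampleIds = colnames(values),
                       scale = c("linear", "log2"), labels = NULL) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  dimnames(values) <- list(geneIds, sampleIds)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values))
  obj <- new("ExprMatrix", se, scaleFlag = scale)
  if (!is.null(labels)) classLabels(obj) <- labels
  obj
}

#' RidgeLogistic: a fitted ridge-penalized logistic model
#'
#' Maximizer of the penalized log-likelihood
#' \eqn{\ell(\beta) - (\lambda/2)\,\lVert w \rVert^2} (intercept unpenalized)
#' on internally z-scored features, fitted by iteratively reweighted least
#' squares. Standardization parameters from the fitting data are stored so
#' validation-set prediction uses the discovery-set location and scale.
#'
#' @slot intercept numeric(1).
#' @slot weights named numeric, one coefficient per signature gene, on the
#'   standardized scale.
#' @slot lambda ridge penalty (>= 0).
#' @slot center,scale named numeric, per-gene mean and sd of the fitting data.
#' @slot converged logical(1); whether IRLS met the 1e-8 tolerance.
#' @slot iterations integer(1), IRLS iterations used.
#' @export
setClass("RidgeLogistic", representation(
  intercept  = "numeric",
  weights    = "numeric",
  lambda     = "numeric",
  center     = "numeric",
  scale      = "numeric",
  converged  = "logical",
  iterations = "integer"
))

setValidity("RidgeLogistic", function(object) {
  msg <- character()
  if (length(object@intercept) != 1L || !is.finite(object@intercept))
    msg <- c(msg, "intercept must be a finite scalar")
  if (object@lambda < 0) msg <- c(msg, "lambda must be >= 0")
  nm <- names(object@weights)
  if (length(object@weights) && (is.null(nm) || anyDuplicated(nm)))
    msg <- c(msg, "weights must be uniquely named by gene")
  if (!identical(names(object@center), nm) ||
      !identical(names(object@scale), nm))
    msg <- c(msg, "center/scale names must match weight names")
  if (any(object@scale <= 0))
    msg <- c(msg, "standardization sds must be > 0")
  if (length(msg)) msg else TRUE
})

#' BootstrapRun: per-iteration records of the discovery/validation search
#'
#' One row of `records` per (iteration, candidate-signature) pair holding the
#' discovery-set AUC of the fitted model, its out-of-bag validation AUC, the
#' candidate's genes, and the validation probabilities/labels needed for
#' threshold-swept ROC aggregation. Failed fits are kept as `NA` metrics.
#'
#' @slot records data.frame with columns `iteration`, `size`,
#'   `discovery_auc`, `validation_auc` and list columns `genes`,
#'   `validation_probs`, `validation_labels`.
#' @slot B,kMax,seed integers echoing the run configuration.
#' @slot lambda ridge penalty used for every fit.
#' @slot rankingMode `"per-iteration"` or `"global"`.
#' @slot geneIds gene universe of the input matrix.
#' @export
setClass("BootstrapRun", representation(
  records     = "data.frame",
  B           = "integer",
  kMax        = "integer",
  lambda      = "numeric",
  rankingMode = "character",
  seed        = "integer",
  geneIds     = "character"
))

#' SignatureSelection: the winning signature and its evidence
#'
#' @slot genes character vector of gene identifiers, length = winning size.
#' @slot size integer, winning signature size (mean validation AUC argmax,
#'   smaller size on ties).
#' @slot perSize data.frame: per candidate size, mean/SE of the validation
#'   AUC and number of contributing iterations.
#' @slot geneFrequency named numeric: per-gene selection frequency among the
#'   winning-size candidates across iterations.
#' @export
setClass("SignatureSelection", representation(
  genes         = "character",
  size          = "integer",
  perSize       = "data.frame",
  geneFrequency = "numeric"
))

setMethod("show", "ExprMatrix", function(object) {
  cat(sprintf("ExprMatrix: %d genes x %d samples (%s scale)\n",
              nrow(object), ncol(object), object@scaleFlag))
  cls <- SummarizedExperiment::colData(object)$class
  if (!is.null(cls)) {
    tab <- table(cls)
    cat(sprintf("  labels: %d PA, %d GA\n", tab[["PA"]], tab[["GA"]]))
  } else cat("  labels: none attached\n")
})

setMethod("show", "RidgeLogistic", function(object) {
  cat(sprintf(
    "RidgeLogistic: %d gene(s), lambda = %g, %s in %d iteration(s)\n",
    length(object@weights), object@lambda,
    if (object@converged) "converged" else "NOT converged",
    object@iterations))
  cat(sprintf("  intercept %.4f\n", object@intercept))
  if (length(object@weights)) {
    w <- format(round(object@weights, 4))
    cat(paste0("  ", names(w), " ", w, "\n"), sep = "")
  }
})

setMethod("show", "BootstrapRun", function(object) {
  ok <- sum(!is.na(object@records$validation_auc))
  cat(sprintf(
    "BootstrapRun: B = %d, k_max = %d, lambda = %g, %s ranking, seed %d\n",
    object@B, object@kMax, object@lambda, object@rankingMode, object@seed))
  cat(sprintf("  %d candidate records (%d with validation AUC)\n",
              nrow(object@records), ok))
})

setMethod("show", "SignatureSelection", function(object) {
  cat(sprintf("SignatureSelection: %d-gene signature\n", object@size))
  cat("  genes:", paste(object@genes, collapse = ", "), "\n")
  i <- match(object@size, object@perSize$size)
  cat(sprintf("  mean validation AUC %.3f (SE %.3f, n = %d iterations)\n",
              object@perSize$mean_validation_auc[i],
              object@perSize$se_validation_auc[i],
              object@perSize$n_iterations[i]))
})
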