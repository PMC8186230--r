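# Penalized log-likelihood l(beta) - (lambda/2) * ||weights||^2 on the
# standardized design D = [1, Z]; the intercept is never penalized.
penalizedLogLik <- function(beta, D, y, lambda) {
  eta <- drop(D %*% beta)
  sum(y * eta - log1p(exp(eta))) - (lambda / 2) * sum(beta[-1L]^2)
}

#' Fit a ridge-penalized logistic regression by IRLS
#'
#' Maximizes the penalized log-likelihood
#' \eqn{\ell(\beta) - (\lambda/2)\lVert w\rVert^2} (intercept unpenalized)
#' with Newton/IRLS steps and step-halving, on internally z-scored columns.
#' Convergence when the largest absolute coefficient change drops below
#' 1e-8, capped at 100 iterations; the `converged` slot records which.
#' With \eqn{\lambda > 0} coefficients stay finite even on perfectly
#' separable data, the expected regime at 29 samples and several genes.
#'
#' Zero-variance columns cannot be standardized; their weight is fixed at 0
#' with a warning and the remaining columns are fitted as usual.
#'
#' @param X numeric matrix, samples x signature genes (column names = gene
#'   identifiers), log2 expression values.
#' @param y binary labels, 0 = PA, 1 = GA (or a PA/GA factor).
#' @param lambda ridge penalty on the standardized scale (default 1).
#' @return A [RidgeLogistic-class] model.
#' @examples
#' X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("gA", "gB")))
#' y <- rep(0:1, each = 10)
#' fitLogistic(X, y)
#' @export
fitLogistic <- function(X, y, lambda = 1.0) {
  X <- as.matrix(X)
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.numeric(y)
  if (length(y) != nrow(X))
    stop("length(y) must equal nrow(X)", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("y must contain both classes", call. = FALSE)
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  genes <- colnames(X)
  if (is.null(genes)) genes <- paste0("x", seq_len(ncol(X)))
  colnames(X) <- genes

  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  dead <- scl == 0
  if (any(dead)) {
    warning(sprintf("zero-variance column(s) %s: weight fixed at 0",
                    paste(genes[dead], collapse = ", ")), call. = FALSE)
    scl[dead] <- 1
  }
  live <- which(!dead)
  Z <- sweep(sweep(X[, live, drop = FALSE], 2L, ctr[live]), 2L,
             scl[live], "/")
  D <- cbind(1, Z)
  pz <- length(live)
  pen <- c(0, rep(lambda, pz))

  beta <- numeric(pz + 1L)
  ll <- penalizedLogLik(beta, D, y, lambda)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(100L)) {
    eta <- drop(D %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    grad <- drop(crossprod(D, y - mu)) - pen * beta
    H <- crossprod(D, D * w) + diag(pen, nrow = pz + 1L)
    step <- tryCatch(solve(H, grad), error = function(e)
      stop("IRLS system is singular; increase lambda", call. = FALSE))
    # step-halve until the penalized likelihood does not decrease
    for (h in 0:30) {
      cand <- beta + step / 2^h
      llc <- penalizedLogLik(cand, D, y, lambda)
      if (is.finite(llc) && llc >= ll - 1e-12) break
    }
    delta <- max(abs(cand - beta))
    beta <- unname(cand)
    ll <- llc
    if (delta < 1e-8) { converged <- TRUE; break }
  }

  weights <- stats::setNames(numeric(length(genes)), genes)
  weights[live] <- beta[-1L]
  new("RidgeLogistic",
      intercept = beta[1L], weights = weights, lambda = lambda,
      center = stats::setNames(ctr, genes),
      scale = stats::setNames(scl, genes),
      converged = converged, iterations = it)
}

#' Predict GA class probabilities
#'
#' Applies the model's stored fitting-data standardization to `X` and
#' returns \eqn{p(\mathrm{GA}) = 1/(1 + e^{-(b_0 + \sum_g w_g z_g)})}.
#'
#' @param model a [RidgeLogistic-class].
#' @param X numeric matrix, samples x genes; must contain a column for every
#'   signature gene of the model.
#' @return Numeric vector of probabilities in (0, 1), one per row of `X`.
#' @export
predictProba <- function(model, X) {
  stopifnot(is(model, "RidgeLogistic"))
  X <- as.matrix(X)
  genes <- names(model@weights)
  missing <- setdiff(genes, colnames(X))
  if (length(missing))
    stop(sprintf("signature gene '%s' missing from X", missing[1L]),
         call. = FALSE)
  Z <- sweep(sweep(X[, genes, drop = FALSE], 2L, model@center), 2L,
             model@scale, "/")
  stats::plogis(model@intercept + drop(Z %*% model@weights))
}

#' Serialize a fitted model to a plain-text key:value file
#'
#' @param model a [RidgeLogistic-class].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
writeLogisticModel <- function(model, path) {
  stopifnot(is(model, "RidgeLogistic"))
  fmt <- function(x) format(x, digits = 17, scientific = TRUE, trim = TRUE)
  lines <- c(
    sprintf("lambda: %s", fmt(model@lambda)),
    sprintf("intercept: %s", fmt(model@intercept)),
    sprintf("converged: %s", model@converged),
    sprintf("iterations: %d", model@iterations),
    sprintf("gene: %s %s %s %s", names(model@weights), fmt(model@weights),
            fmt(model@center), fmt(model@scale)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a model written by [writeLogisticModel()]
#'
#' @param path path to the key:value model file.
#' @return A [RidgeLogistic-class].
#' @export
readLogisticModel <- function(path) {
  lines <- readLines(path)
  kv <- function(key) sub(paste0("^", key, ": "), "",
                          grep(paste0("^", key, ": "), lines, value = TRUE))
  gl <- strsplit(kv("gene"), " ", fixed = TRUE)
  genes <- vapply(gl, `[`, "", 1L)
  new("RidgeLogistic",
      intercept = as.numeric(kv("intercept")),
      weights = stats::setNames(as.numeric(vapply(gl, `[`, "", 2L)), genes),
      lambda = as.numeric(kv("lambda")),
      center = stats::setNames(as.numeric(vapply(gl, `[`, "", 3L)), genes),
      scale = stats::setNames(as.numeric(vapply(gl, `[`, "", 4L)), genes),
      converged = as.logical(kv("converged")),
      iterations = as.integer(kv("iterations")))
}
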