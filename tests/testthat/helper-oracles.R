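# Fixtures and independent oracle implementations used across test files.

# Small labeled ExprMatrix built directly (not via the generator).
tinyLabeled <- function(nGenes = 20L, n0 = 5L, n1 = 6L, seed = 42L,
                        scale = "log2") {
  set.seed(seed)
  vals <- matrix(rnorm(nGenes * (n0 + n1), mean = 8), nGenes, n0 + n1,
                 dimnames = list(sprintf("g%03d", seq_len(nGenes)),
                                 c(sprintf("PA%02d", seq_len(n0)),
                                   sprintf("GA%02d", seq_len(n1)))))
  if (scale == "linear") vals <- 2^(vals / 4)
  ExprMatrix(vals, scale = scale, labels = rep(c("PA", "GA"), c(n0, n1)))
}

# Trapezoidal ROC integration over all distinct score cutoffs; ties produce
# diagonal segments. Independent of the rank-based implementation.
trapezoidAUC <- function(scores, labels) {
  cuts <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(cuts, function(c) mean(scores[labels == 1] >= c), 0)
  fpr <- vapply(cuts, function(c) mean(scores[labels == 0] >= c), 0)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# Generic numeric maximizer of the same penalized logistic objective that
# fitLogistic targets, on the same internally standardized design.
optimLogistic <- function(X, y, lambda) {
  Z <- scale(X)
  Z[, attr(Z, "scaled:scale") == 0] <- 0
  D <- cbind(1, Z)
  negll <- function(b) {
    eta <- drop(D %*% b)
    -(sum(y * eta - log1p(exp(eta))) - (lambda / 2) * sum(b[-1L]^2))
  }
  grad <- function(b) {
    p <- plogis(drop(D %*% b))
    -(drop(crossprod(D, y - p)) - lambda * c(0, b[-1L]))
  }
  fit <- optim(numeric(ncol(D)), negll, grad, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-15))
  list(intercept = fit$par[1L], weights = fit$par[-1L],
       value = -fit$value)
}
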