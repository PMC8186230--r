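test_that("IRLS matches a generic optimizer of the same objective", {
  set.seed(321)
  for (i in 1:100) {
    n <- sample(6:10, 1); p <- sample(1:2, 1)
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("g", seq_len(p))))
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    lambda <- sample(c(0.5, 1, 2), 1)
    fit <- fitLogistic(X, y, lambda)
    orc <- optimLogistic(X, y, lambda)
    expect_lt(abs(fit@intercept - orc$intercept), 1e-6)
    expect_lt(max(abs(unname(fit@weights) - orc$weights)), 1e-6)
    # no worse an optimum than the oracle's
    Z <- scale(X); D <- cbind(1, Z)
    llFit <- appsig:::penalizedLogLik(c(fit@intercept, fit@weights), D, y,
                                      lambda)
    expect_gte(llFit, orc$value - 1e-8)
  }
})

test_that("uninformative features shrink to the class-ratio intercept", {
  set.seed(99)
  X <- matrix(rnorm(29 * 3), 29, 3,
              dimnames = list(NULL, c("gA", "gB", "gC")))
  y <- rep(c(0, 1), c(13, 16))
  fit <- fitLogistic(X, y, lambda = 1)
  orc <- optimLogistic(X, y, 1)
  expect_lt(abs(fit@intercept - orc$intercept), 1e-6)
  # intercept near log(16/13), weights small relative to informative fits
  expect_lt(abs(fit@intercept - log(16 / 13)), 0.5)
  expect_lt(max(abs(fit@weights)), 1)
})

test_that("degenerate inputs follow the stated conventions", {
  Xflat <- matrix(5, 10, 2, dimnames = list(NULL, c("g1", "g2")))
  y <- rep(0:1, each = 5)
  expect_warning(fit <- fitLogistic(Xflat, y, 1), "zero-variance")
  expect_identical(unname(fit@weights), c(0, 0))
  expect_equal(fit@intercept, 0, tolerance = 1e-8)
  expect_true(all(fit@scale > 0))

  expect_error(fitLogistic(Xflat, rep(1, 10), 1), "both classes")
})

test_that("ridge keeps coefficients finite on separable data", {
  X <- matrix(c(1:5, 11:15), 10, 1, dimnames = list(NULL, "g1"))
  y <- rep(0:1, each = 5)
  fit <- fitLogistic(X, y, lambda = 1)
  expect_true(all(is.finite(c(fit@intercept, fit@weights))))
  expect_true(fit@converged)
})

test_that("fitted probabilities average to the class rate as lambda -> 0", {
  set.seed(7)
  X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("g1", "g2")))
  y <- rep(c(0, 1), c(8, 12))
  fit <- fitLogistic(X, y, lambda = 1e-6)
  expect_equal(mean(predictProba(fit, X)), mean(y), tolerance = 1e-4)
})

test_that("predictProba applies the closed forms and schema checks", {
  m <- new("RidgeLogistic", intercept = 0,
           weights = c(g1 = 0), lambda = 1, center = c(g1 = 0),
           scale = c(g1 = 1), converged = TRUE, iterations = 1L)
  X <- matrix(rnorm(5), 5, 1, dimnames = list(NULL, "g1"))
  expect_equal(predictProba(m, X), rep(0.5, 5))

  m@intercept <- log(3)
  expect_equal(predictProba(m, X), rep(0.75, 5))

  # strictly increasing in the linear score
  m@weights <- c(g1 = 2)
  sorted <- X[order(X[, 1]), , drop = FALSE]
  expect_true(all(diff(predictProba(m, sorted)) > 0))

  colnames(X) <- "other"
  expect_error(predictProba(m, X), "g1")
})

test_that("model serialization round trips exactly", {
  set.seed(8)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("gX", "gY", "gZ")))
  y <- rep(0:1, 10)
  fit <- fitLogistic(X, y, 0.7)
  path <- withr::local_tempfile(fileext = ".txt")
  writeLogisticModel(fit, path)
  back <- readLogisticModel(path)
  expect_equal(back@intercept, fit@intercept, tolerance = 1e-15)
  expect_equal(back@weights, fit@weights, tolerance = 1e-15)
  expect_equal(back@center, fit@center, tolerance = 1e-15)
  expect_identical(back@iterations, fit@iterations)
  expect_equal(predictProba(back, X), predictProba(fit, X),
               tolerance = 1e-12)
})
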