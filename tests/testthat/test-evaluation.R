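test_that("confusion at a threshold uses strict > with GA positive", {
  probs <- c(0.9, 0.8, 0.1, 0.2)
  labs <- c(1, 1, 0, 0)
  expect_equal(unname(confusionAtThreshold(probs, labs, 0.5)), c(1, 1))
  # threshold 0: everything above 0 is called GA
  expect_equal(unname(confusionAtThreshold(probs, labs, 0)), c(1, 0))
  # threshold 1: nothing exceeds 1 strictly
  expect_equal(unname(confusionAtThreshold(probs, labs, 1)), c(0, 1))
  expect_error(confusionAtThreshold(probs, c(1, 1, 1, 1), 0.5),
               "both classes")
})

test_that("concordance AUC matches brute force and trapezoid on random data", {
  expect_equal(aucConcordance(c(0.8, 0.3, 0.6, 0.1), c(1, 1, 0, 0)), 0.75)
  expect_equal(aucConcordance(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(aucConcordance(rep(0.4, 6), rep(0:1, 3)), 0.5)

  set.seed(456)
  for (i in 1:500) {
    n1 <- sample(2:12, 1); n0 <- sample(2:12, 1)
    # discrete support makes ties frequent
    s <- sample(seq(0, 1, 0.1), n0 + n1, replace = TRUE)
    y <- rep(c(0, 1), c(n0, n1))
    mine <- aucConcordance(s, y)
    # brute-force pairwise concordance
    pairs <- outer(s[y == 1], s[y == 0], function(a, b)
      (a > b) + 0.5 * (a == b))
    expect_equal(mine, mean(pairs), tolerance = 1e-12)
    expect_equal(mine, trapezoidAUC(s, y), tolerance = 1e-12)
  }
})

test_that("concordance AUC agrees with an external ROC implementation", {
  set.seed(31)
  for (i in 1:20) {
    s <- runif(20); y <- rep(0:1, each = 10)
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, levels = c(0, 1),
                                          direction = "<", quiet = TRUE)))
    expect_equal(aucConcordance(s, y), ref, tolerance = 1e-12)
  }
})

test_that("random labels give chance-level AUC on average", {
  set.seed(88)
  aucs <- replicate(1000, {
    s <- runif(12)
    aucConcordance(s, sample(rep(0:1, 6)))
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.02)
})

test_that("aggregated ROC reports bootstrap means and SDs per threshold", {
  d <- generateDataset(syntheticConfig(nGenes = 120L, seed = 14L))
  em <- preprocessMatrix(d$matrix)
  run <- runDiscoveryValidation(em, B = 12L, kMax = 3L, seed = 7L)
  roc <- aggregateROC(run, size = 3L)
  expect_identical(nrow(roc), 19L)   # default 0.05..0.95 grid
  expect_true(all(roc$sensitivity_mean >= 0 & roc$sensitivity_mean <= 1))
  expect_true(all(roc$sensitivity_se >= 0 & roc$specificity_se >= 0))
  # monotone in the threshold
  expect_true(all(diff(roc$sensitivity_mean) <= 1e-12))
  expect_true(all(diff(roc$specificity_mean) >= -1e-12))

  # hand-checked aggregation of two iterations
  rec <- run@records[run@records$size == 3L, ][1:2, ]
  rec$validation_probs <- list(c(0.9, 0.2), c(0.9, 0.9))
  rec$validation_labels <- list(c(1L, 0L), c(1L, 0L))
  fake <- run; fake@records <- rec
  out <- aggregateROC(fake, 3L, thresholds = 0.5)
  expect_equal(out$sensitivity_mean, 1)
  expect_equal(out$specificity_mean, 0.5)
  expect_equal(out$specificity_se, sd(c(1, 0)))
})

test_that("AUC summary uses the bootstrap SE and both lower limits", {
  run <- new("BootstrapRun",
             records = data.frame(iteration = 1:3, size = 1L,
                                  discovery_auc = 1,
                                  validation_auc = c(0.8, 0.9, 1.0)),
             B = 3L, kMax = 1L, lambda = 1, rankingMode = "per-iteration",
             seed = 1L, geneIds = "g1")
  s <- summarizeAUC(run, 1L)
  expect_equal(s$mean_auc, 0.9)
  expect_equal(s$se_auc, 0.1)              # SD across iterations, ddof = 1
  expect_equal(s$cl_lower_normal, 0.9 - 1.96 * 0.1)
  expect_lte(s$cl_lower_percentile, s$mean_auc)
  expect_identical(s$n_iterations, 3L)

  # constant AUCs: SE 0, limits collapse onto the mean
  run@records$validation_auc <- rep(0.84, 3)
  s2 <- summarizeAUC(run, 1L)
  expect_equal(s2$se_auc, 0)
  expect_equal(s2$cl_lower_normal, 0.84)
  expect_equal(s2$cl_lower_percentile, 0.84)

  # invariant to iteration order
  run@records$validation_auc <- c(1.0, 0.8, 0.9)
  expect_equal(summarizeAUC(run, 1L), s)

  run@records <- run@records[1, ]
  expect_error(summarizeAUC(run, 1L), "at least 2")
})
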