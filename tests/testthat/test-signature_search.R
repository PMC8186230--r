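test_that("bootstrap splits have the expected out-of-bag structure", {
  y <- rep(c(0L, 1L), c(13L, 16L))
  set.seed(123)
  sizes <- replicate(10000, {
    sp <- bootstrapSplit(29L, y)
    expect_length(sp$discovery, 29L)  # multiset of size n
    length(sp$validation)
  })
  expect_lt(abs(mean(sizes) - 29 * (1 - 1 / 29)^29), 0.2)

  # validation is exactly the out-of-bag complement
  set.seed(5)
  sp <- bootstrapSplit(29L, y)
  expect_identical(sp$validation,
                   sort(setdiff(1:29, unique(sp$discovery))))
  expect_length(intersect(sp$validation, sp$discovery), 0L)
})

test_that("tiny cohorts always yield two-class validation sets", {
  y4 <- c(0L, 0L, 1L, 1L)
  set.seed(9)
  for (i in 1:200) {
    sp <- bootstrapSplit(4L, y4)
    expect_identical(sort(unique(y4[sp$validation])), c(0L, 1L))
  }
  expect_error(bootstrapSplit(3L, c(0L, 0L, 1L)), "at least 4")
})

test_that("a fixed RNG state reproduces the split sequence", {
  y <- rep(0:1, each = 10)
  set.seed(77); a <- replicate(20, bootstrapSplit(20L, y), simplify = FALSE)
  set.seed(77); b <- replicate(20, bootstrapSplit(20L, y), simplify = FALSE)
  expect_identical(a, b)
})

test_that("candidate signatures are nested top-k prefixes", {
  cands <- buildCandidateSignatures(c("g7", "g2", "g9", "g1"), 3L)
  expect_identical(cands,
                   list("g7", c("g7", "g2"), c("g7", "g2", "g9")))
  expect_identical(buildCandidateSignatures(c("a", "b"), 1L), list("a"))
  expect_error(buildCandidateSignatures(character(0), 1L), "non-empty")
  expect_error(buildCandidateSignatures(c("a"), 0L), "kMax")
  expect_error(buildCandidateSignatures(c("a"), 2L), "exceed")
  # pairwise distinct by construction
  expect_identical(anyDuplicated(vapply(cands, paste, "", collapse = ",")),
                   0L)
})

test_that("discovery ranking ignores validation samples entirely", {
  em <- tinyLabeled(nGenes = 50L, seed = 3L)
  vals <- exprValues(em)
  y <- as.integer(classLabels(em)) - 1L
  disc <- c(1:3, 3L, 6:9)   # a multiset leaving samples 4, 5, 10, 11 out
  r1 <- appsig:::rankGenesByWelch(vals, y, disc)
  vals2 <- vals
  vals2[, c(4L, 5L, 10L, 11L)] <- vals2[, c(4L, 5L, 10L, 11L)] + 100
  r2 <- appsig:::rankGenesByWelch(vals2, y, disc)
  expect_identical(r1, r2)
})

test_that("the search is deterministic and leakage-free", {
  d <- generateDataset(syntheticConfig(nGenes = 150L, seed = 4L))
  em <- preprocessMatrix(d$matrix)
  a <- runDiscoveryValidation(em, B = 15L, kMax = 5L, seed = 21L)
  b <- runDiscoveryValidation(em, B = 15L, kMax = 5L, seed = 21L)
  expect_identical(a@records, b@records)
  expect_identical(selectBestSignature(a)@genes, selectBestSignature(b)@genes)
  # AUCs live in [0, 1]; one record per (iteration, size) pair
  expect_true(all(a@records$validation_auc >= 0 &
                    a@records$validation_auc <= 1, na.rm = TRUE))
  expect_identical(nrow(a@records), 15L * 5L)
})

test_that("informative genes outrank noise in the selected signature", {
  d <- generateDataset(syntheticConfig(nGenes = 300L, seed = 12L))
  em <- preprocessMatrix(d$matrix)
  run <- runDiscoveryValidation(em, B = 40L, kMax = 6L, seed = 12L)
  sel <- selectBestSignature(run)
  expect_s4_class(sel, "SignatureSelection")
  expect_true(all(sel@genes %in% geneIds(em)))
  expect_identical(length(sel@genes), as.integer(sel@size))
  # the most frequently top-ranked gene is a true informative gene
  expect_true(names(sel@geneFrequency)[1L] %in% d$truth$gene_id)
  # mean validation AUC argmax defines the winner; ties go to smaller size
  ps <- sel@perSize
  expect_identical(ps$size[which.max(ps$mean_validation_auc)], sel@size)
})

test_that("global ranking mode ranks once on all samples", {
  d <- generateDataset(syntheticConfig(nGenes = 100L, seed = 6L))
  em <- preprocessMatrix(d$matrix)
  run <- runDiscoveryValidation(em, B = 8L, kMax = 4L, seed = 2L,
                                rankingMode = "global")
  g4 <- run@records$genes[run@records$size == 4L]
  expect_true(all(vapply(g4, identical, TRUE, g4[[1L]])))
})

test_that("per-iteration renormalization accepts only linear input", {
  d <- generateDataset(syntheticConfig(nGenes = 80L, seed = 13L))
  expect_error(runDiscoveryValidation(preprocessMatrix(d$matrix),
                                      B = 2L, renormalize = TRUE),
               "linear")
  run <- runDiscoveryValidation(d$matrix, B = 5L, kMax = 3L, seed = 3L,
                                renormalize = TRUE)
  expect_identical(nrow(run@records), 15L)
  expect_true(any(!is.na(run@records$validation_auc)))
})
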