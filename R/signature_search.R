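#' Draw one bootstrap discovery/validation split
#'
#' Discovery set: n samples drawn with replacement (a multiset; repeated
#' samples keep their multiplicity in the fit). Validation set: the
#' out-of-bag samples, i.e. every sample absent from the discovery draw,
#' each once. Draws are repeated (up to `maxAttempts`) until the validation
#' set contains both classes, without which sensitivity and specificity are
#' undefined.
#'
#' @param n number of samples (>= 4).
#' @param y binary labels (0 = PA, 1 = GA) of length `n`.
#' @param maxAttempts redraw budget for the two-class validation constraint.
#' @return list(discovery = integer(n) with replacement, validation =
#'   sorted out-of-bag indices). Consumes the current RNG stream.
#' @export
bootstrapSplit <- function(n, y, maxAttempts = 1000L) {
  if (n < 4L) stop("need at least 4 samples to split", call. = FALSE)
  if (length(y) != n) stop("length(y) must equal n", call. = FALSE)
  for (a in seq_len(maxAttempts)) {
    disc <- sample.int(n, n, replace = TRUE)
    oob <- setdiff(seq_len(n), disc)
    if (length(unique(y[oob])) == 2L)
      return(list(discovery = disc, validation = sort(oob)))
  }
  stop(sprintf(
    "could not draw a validation set holding both classes in %d attempts",
    maxAttempts), call. = FALSE)
}

#' Nested top-k candidate signatures from a gene ranking
#'
#' Candidate j is the top-j genes of the ranking, j = 1..`kMax`, giving
#' `kMax` distinct nested signatures.
#'
#' @param ranking character vector of gene identifiers, best first.
#' @param kMax largest signature size (1 <= kMax <= length(ranking)).
#' @return List of character vectors of lengths 1..kMax.
#' @examples
#' buildCandidateSignatures(c("g7", "g2", "g9", "g1"), 3)
#' @export
buildCandidateSignatures <- function(ranking, kMax) {
  if (kMax < 1L) stop("kMax must be >= 1", call. = FALSE)
  if (!length(ranking)) stop("ranking must be non-empty", call. = FALSE)
  if (kMax > length(ranking))
    stop("kMax cannot exceed the ranking length", call. = FALSE)
  lapply(seq_len(kMax), function(k) ranking[seq_len(k)])
}

# Rank gene ids by decreasing |Welch t| computed on the given sample
# columns only. Ties in |t| resolve to the smaller gene index (stable
# order()). Values outside sampleIdx never influence the result.
rankGenesByWelch <- function(vals, y, sampleIdx) {
  ys <- y[sampleIdx]
  if (sum(ys == 0L) < 2L || sum(ys == 1L) < 2L)
    stop("discovery set needs at least 2 samples per class", call. = FALSE)
  sub <- vals[, sampleIdx, drop = FALSE]
  r <- rowWelch(sub, which(ys == 0L), which(ys == 1L))
  rownames(vals)[order(-abs(r$t))]
}

# Map each validation column onto the reference distribution of the
# discovery columns (mean of sorted discovery columns), used when quantile
# normalization is redone inside the bootstrap loop.
projectOntoReference <- function(cols, ref) {
  p <- length(ref)
  apply(cols, 2L, function(v)
    stats::approx(seq_len(p), ref, xout = rank(v, ties.method = "average"),
                  rule = 2L)$y)
}

#' Bootstrap alternation of discovery and validation
#'
#' The core resampling procedure: for each of `B` iterations, draw a
#' bootstrap discovery multiset with its out-of-bag validation set; rank
#' genes by |Welch t| on the discovery samples only; form the nested top-k
#' candidate signatures (k = 1..`kMax`); fit a ridge-logistic model per
#' candidate on the discovery rows and record its discovery-set AUC, its
#' validation probabilities and its validation AUC. Iterations whose fit or
#' ranking fails (e.g. a tiny discovery set with one class) are recorded
#' with `NA` metrics, never dropped. The whole run is a deterministic
#' function of `(x, B, kMax, lambda, rankingMode, seed)`.
#'
#' `rankingMode = "global"` instead ranks genes once on all samples before
#' the loop — a literal one-off reading of the discovery step, kept for
#' comparison; it leaks label information into validation performance and is
#' not the default.
#'
#' @param x a log2-scale [ExprMatrix-class] with PA/GA labels (or, with
#'   `renormalize = TRUE`, a linear-scale matrix).
#' @param B bootstrap iterations (default 1000, the study's resampling
#'   depth).
#' @param kMax largest candidate signature size (default 10).
#' @param lambda ridge penalty for every logistic fit (default 1).
#' @param seed integer seed.
#' @param rankingMode `"per-iteration"` (default) or `"global"`.
#' @param renormalize redo quantile normalization inside each iteration:
#'   discovery samples are normalized among themselves and validation
#'   samples are projected onto the discovery reference distribution, then
#'   both are log2-transformed. For leakage-sensitivity analyses.
#' @return A [BootstrapRun-class].
#' @export
runDiscoveryValidation <- function(x, B = 1000L, kMax = 10L, lambda = 1.0,
                                   seed = 1L,
                                   rankingMode = c("per-iteration", "global"),
                                   renormalize = FALSE) {
  stopifnot(is(x, "ExprMatrix"))
  rankingMode <- match.arg(rankingMode)
  B <- as.integer(B); kMax <- as.integer(kMax); seed <- as.integer(seed)
  if (B < 1L) stop("B must be >= 1", call. = FALSE)
  if (kMax < 1L || kMax > nrow(x))
    stop("kMax must be between 1 and the number of genes", call. = FALSE)
  if (renormalize) {
    if (exprScale(x) != "linear")
      stop("renormalize = TRUE expects a linear-scale matrix", call. = FALSE)
    if (rankingMode == "global")
      stop("global ranking is not available with per-iteration renormalization",
           call. = FALSE)
  } else if (exprScale(x) != "log2")
    stop("expected a preprocessed log2-scale matrix", call. = FALSE)
  y <- labelCodes(x)
  n <- ncol(x)
  vals <- exprValues(x)

  set.seed(seed)
  globalRanking <- if (rankingMode == "global" && !renormalize)
    rankGenesByWelch(vals, y, seq_len(n)) else NULL

  recs <- vector("list", B)
  for (b in seq_len(B)) {
    split <- bootstrapSplit(n, y)
    stopifnot(length(intersect(split$validation, split$discovery)) == 0L)
    it <- iterationRecords(vals, y, split, kMax, lambda, rankingMode,
                           globalRanking, renormalize)
    it$iteration <- b
    recs[[b]] <- it
  }
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  new("BootstrapRun", records = records, B = B, kMax = kMax,
      lambda = lambda, rankingMode = rankingMode, seed = seed,
      geneIds = rownames(vals))
}

# One iteration's records across all candidate sizes; failures become NA
# rows so every (iteration, size) pair is accounted for.
iterationRecords <- function(vals, y, split, kMax, lambda, rankingMode,
                             globalRanking, renormalize) {
  empty <- data.frame(size = seq_len(kMax), discovery_auc = NA_real_,
                      validation_auc = NA_real_)
  empty$genes <- replicate(kMax, character(0), simplify = FALSE)
  empty$validation_probs <- replicate(kMax, numeric(0), simplify = FALSE)
  empty$validation_labels <- replicate(kMax, integer(0), simplify = FALSE)

  disc <- split$discovery; oob <- split$validation
  if (renormalize) {
    udisc <- sort(unique(disc))
    dsub <- limma::normalizeQuantiles(vals[, udisc, drop = FALSE], ties = TRUE)
    ref <- rowMeans(apply(vals[, udisc, drop = FALSE], 2L, sort))
    vsub <- projectOntoReference(vals[, oob, drop = FALSE], ref)
    norm <- vals
    norm[, udisc] <- dsub
    norm[, oob] <- vsub
    vals <- log2(norm)
  }
  ranking <- if (rankingMode == "global" && !is.null(globalRanking))
    globalRanking
  else tryCatch(rankGenesByWelch(vals, y, disc), error = function(e) NULL)
  if (is.null(ranking)) return(empty)

  candidates <- buildCandidateSignatures(ranking[seq_len(kMax)], kMax)
  Xall <- t(vals)
  out <- empty
  for (k in seq_len(kMax)) {
    genes <- candidates[[k]]
    out$genes[[k]] <- genes
    fit <- tryCatch(
      suppressWarnings(
        fitLogistic(Xall[disc, genes, drop = FALSE], y[disc], lambda)),
      error = function(e) NULL)
    if (is.null(fit)) next
    pd <- predictProba(fit, Xall[disc, genes, drop = FALSE])
    pv <- predictProba(fit, Xall[oob, genes, drop = FALSE])
    out$discovery_auc[k] <- aucConcordance(pd, y[disc])
    out$validation_auc[k] <- aucConcordance(pv, y[oob])
    out$validation_probs[[k]] <- unname(pv)
    out$validation_labels[[k]] <- y[oob]
  }
  out
}

#' Select the best-performing signature from a bootstrap run
#'
#' For each candidate size k, the mean out-of-bag validation AUC across
#' iterations is computed; the winning size k* maximizes it (ties go to the
#' smaller size — parsimony). The reported signature consists of the k*
#' genes most frequently appearing in the size-k* candidate across
#' iterations (frequency ties resolve lexicographically by gene id).
#'
#' @param run a [BootstrapRun-class].
#' @return A [SignatureSelection-class].
#' @export
selectBestSignature <- function(run) {
  stopifnot(is(run, "BootstrapRun"))
  rec <- run@records
  if (all(is.na(rec$validation_auc)))
    stop("no iteration produced a validation AUC", call. = FALSE)
  sizes <- sort(unique(rec$size))
  perSize <- do.call(rbind, lapply(sizes, function(k) {
    a <- rec$validation_auc[rec$size == k]
    a <- a[!is.na(a)]
    data.frame(size = k,
               mean_validation_auc = if (length(a)) mean(a) else NA_real_,
               se_validation_auc = if (length(a) > 1L) stats::sd(a) else NA_real_,
               n_iterations = length(a))
  }))
  best <- sizes[which.max(perSize$mean_validation_auc)]
  kRec <- rec[rec$size == best & !is.na(rec$validation_auc), , drop = FALSE]
  freq <- table(unlist(kRec$genes)) / nrow(kRec)
  ord <- order(-freq, names(freq))
  genes <- names(freq)[ord][seq_len(min(best, length(freq)))]
  new("SignatureSelection", genes = genes, size = as.integer(best),
      perSize = perSize,
      geneFrequency = stats::setNames(as.numeric(freq)[ord],
                                      names(freq)[ord]))
}
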