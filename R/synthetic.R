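#' Configuration for the two-class synthetic expression generator
#'
#' Defaults mirror the study design this package targets: 13 phlegmonous
#' (PA) vs 16 gangrenous (GA) samples and a handful of strongly informative
#' genes, at a test-friendly gene count of 2,000 (use
#' [emulateStudyScale()] for the full 56,666-gene layout).
#'
#' Intensities follow a log-normal model: on the log2 scale each gene g has
#' a baseline mean m_g drawn uniformly from `baselineLog2Range` and Gaussian
#' noise with sd `sigmaLog2`; informative genes have their GA-class mean
#' shifted by `deltaLog2`, so the true log2 fold change equals `deltaLog2`
#' by construction. Genes are independent unless `rho > 0`, which adds an
#' equicorrelated per-sample component.
#'
#' @param nClass0,nClass1 samples per class (PA, GA); each >= 2.
#' @param nGenes total genes (>= 2).
#' @param nInformative number of shifted genes (<= `nGenes`).
#' @param deltaLog2 mean shift of informative genes on the log2 scale (>= 0).
#' @param sigmaLog2 within-group sd on the log2 scale (> 0).
#' @param baselineLog2Range length-2 interval for per-gene baseline means.
#' @param rho equicorrelation of the noise across genes (0 = independent).
#' @param seed integer seed; generation is a pure function of it.
#' @return A validated `syntheticConfig` list.
#' @export
syntheticConfig <- function(nClass0 = 13L, nClass1 = 16L, nGenes = 2000L,
                            nInformative = 4L, deltaLog2 = 2.0,
                            sigmaLog2 = 1.0, baselineLog2Range = c(4, 14),
                            rho = 0, seed = 1L) {
  cfg <- list(nClass0 = as.integer(nClass0), nClass1 = as.integer(nClass1),
              nGenes = as.integer(nGenes),
              nInformative = as.integer(nInformative),
              deltaLog2 = deltaLog2, sigmaLog2 = sigmaLog2,
              baselineLog2Range = baselineLog2Range, rho = rho,
              seed = as.integer(seed))
  if (cfg$nClass0 < 2L || cfg$nClass1 < 2L)
    stop("each class needs at least 2 samples", call. = FALSE)
  if (cfg$nGenes < 2L) stop("nGenes must be >= 2", call. = FALSE)
  if (cfg$nInformative < 0L || cfg$nInformative > cfg$nGenes)
    stop("nInformative must be between 0 and nGenes", call. = FALSE)
  if (cfg$deltaLog2 < 0) stop("deltaLog2 must be >= 0", call. = FALSE)
  if (cfg$sigmaLog2 <= 0) stop("sigmaLog2 must be > 0", call. = FALSE)
  if (length(cfg$baselineLog2Range) != 2L ||
      diff(cfg$baselineLog2Range) < 0)
    stop("baselineLog2Range must be an increasing length-2 interval",
         call. = FALSE)
  if (cfg$rho < 0 || cfg$rho >= 1) stop("rho must be in [0, 1)", call. = FALSE)
  if (is.na(cfg$seed)) stop("seed must be an integer", call. = FALSE)
  class(cfg) <- "syntheticConfig"
  cfg
}

# Core sampler shared by generateDataset() and emulateStudyScale().
# deltas: per-gene log2 mean shift applied to class-1 (GA) samples.
simulateLog2 <- function(n0, n1, baselines, deltas, sigma, rho) {
  p <- length(baselines)
  n <- n0 + n1
  noise <- matrix(rnorm(p * n, sd = sigma), p, n)
  if (rho > 0) {
    shared <- rnorm(n, sd = sigma)
    noise <- sqrt(1 - rho) * noise +
      sqrt(rho) * matrix(shared, p, n, byrow = TRUE)
  }
  log2m <- baselines + noise
  if (n1 > 0L && any(deltas != 0))
    log2m[, (n0 + 1L):n] <- log2m[, (n0 + 1L):n] + deltas
  log2m
}

#' Generate a seeded two-class synthetic dataset with known ground truth
#'
#' @param config a [syntheticConfig()].
#' @return A list with components
#'   \describe{
#'     \item{matrix}{linear-scale [ExprMatrix-class] with PA/GA labels
#'       attached (PA samples first).}
#'     \item{truth}{data.frame `gene_id`, `delta_log2` for the informative
#'       genes (the recoverable signature).}
#'   }
#' @examples
#' d <- generateDataset(syntheticConfig(nGenes = 50, seed = 7))
#' d$truth
#' @export
generateDataset <- function(config) {
  if (!inherits(config, "syntheticConfig"))
    config <- do.call(syntheticConfig, config)
  set.seed(config$seed)
  p <- config$nGenes
  gid <- sprintf("g%05d", seq_len(p))
  sid <- c(sprintf("PA%02d", seq_len(config$nClass0)),
           sprintf("GA%02d", seq_len(config$nClass1)))
  baselines <- runif(p, config$baselineLog2Range[1L],
                     config$baselineLog2Range[2L])
  informative <- sort(sample.int(p, config$nInformative))
  deltas <- numeric(p)
  deltas[informative] <- config$deltaLog2
  log2m <- simulateLog2(config$nClass0, config$nClass1, baselines, deltas,
                        config$sigmaLog2, config$rho)
  dimnames(log2m) <- list(gid, sid)
  em <- ExprMatrix(2^log2m, scale = "linear",
                   labels = rep(c("PA", "GA"),
                                c(config$nClass0, config$nClass1)))
  truth <- data.frame(gene_id = gid[informative],
                      delta_log2 = deltas[informative])
  list(matrix = em, truth = truth)
}

#' Generate a dataset at the full study scale
#'
#' Convenience preset emulating the study layout: 56,666 genes, 13 PA vs 16
#' GA samples. About 6% of genes are differentially expressed downstream:
#' 3,400 genes receive small-to-moderate shifts with delta_log2 drawn
#' uniformly from \[0.2, 1\] (calibrated a priori so that expected Welch
#' power at alpha = 0.05, n = 13 vs 16, plus the 5% false-positive floor
#' yields a DE fraction near the mid-single digits), plus 4 strongly
#' informative genes at delta_log2 = 2.5 that the signature search can
#' recover.
#'
#' @param seed integer seed.
#' @return As [generateDataset()]; `truth` lists the 4 strong genes, and its
#'   attribute `"moderate"` holds the moderately shifted background genes.
#' @export
emulateStudyScale <- function(seed = 1L) {
  set.seed(as.integer(seed))
  p <- 56666L
  n0 <- 13L; n1 <- 16L
  nModerate <- 3400L
  gid <- sprintf("g%05d", seq_len(p))
  sid <- c(sprintf("PA%02d", seq_len(n0)), sprintf("GA%02d", seq_len(n1)))
  baselines <- runif(p, 4, 14)
  shifted <- sample.int(p, nModerate + 4L)
  strong <- sort(shifted[seq_len(4L)])
  moderate <- sort(shifted[-seq_len(4L)])
  deltas <- numeric(p)
  deltas[moderate] <- runif(nModerate, 0.2, 1.0)
  deltas[strong] <- 2.5
  log2m <- simulateLog2(n0, n1, baselines, deltas, sigma = 1, rho = 0)
  dimnames(log2m) <- list(gid, sid)
  em <- ExprMatrix(2^log2m, scale = "linear",
                   labels = rep(c("PA", "GA"), c(n0, n1)))
  truth <- data.frame(gene_id = gid[strong], delta_log2 = deltas[strong])
  attr(truth, "moderate") <- data.frame(gene_id = gid[moderate],
                                        delta_log2 = deltas[moderate])
  list(matrix = em, truth = truth)
}

#' Write a synthetic dataset to a run directory
#'
#' Writes `matrix.tsv`, `labels.tsv` and `truth.tsv` (gene_id, delta_log2).
#'
#' @param config a [syntheticConfig()], or `"study-scale"` for
#'   [emulateStudyScale()] (seeded by `config` attribute `seed` = 1).
#' @param dir output directory, created if needed.
#' @param force overwrite a non-empty directory.
#' @return Invisibly, the list from the generator.
#' @export
writeSyntheticDataset <- function(config, dir, force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) && !force)
    stop(sprintf("output directory '%s' is not empty (use force = TRUE)", dir),
         call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- if (identical(config, "study-scale")) emulateStudyScale()
       else generateDataset(config)
  writeExpressionMatrix(d$matrix, file.path(dir, "matrix.tsv"))
  writeLabels(d$matrix, file.path(dir, "labels.tsv"))
  writeResultTable(d$truth, file.path(dir, "truth.tsv"))
  invisible(d)
}
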