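#' Configuration for a full pipeline run
#'
#' Exactly one input source must be given: either `matrixPath` +
#' `labelsPath` (TSV files, see [readExpressionMatrix()] and [readLabels()])
#' or a [syntheticConfig()]. The single `seed` is expanded into independent
#' per-stage seeds (synthetic generation, bootstrap loop), so changing `B`
#' never perturbs the generated data.
#'
#' @param matrixPath,labelsPath input TSV paths, or `NULL`.
#' @param synthetic a [syntheticConfig()], or `NULL`.
#' @param normalize apply quantile normalization (default TRUE).
#' @param alpha significance level for the DE table (default 0.05).
#' @param B bootstrap iterations (default 1000).
#' @param kMax largest candidate signature size (default 10).
#' @param ridgeLambda ridge penalty (default 1).
#' @param thresholds ROC threshold grid.
#' @param rankingMode `"per-iteration"` (default) or `"global"`.
#' @param seed master seed.
#' @param outDir output directory.
#' @return A validated `pipelineConfig` list.
#' @export
pipelineConfig <- function(matrixPath = NULL, labelsPath = NULL,
                           synthetic = NULL, normalize = TRUE,
                           alpha = 0.05, B = 1000L, kMax = 10L,
                           ridgeLambda = 1.0,
                           thresholds = seq(0.05, 0.95, by = 0.05),
                           rankingMode = c("per-iteration", "global"),
                           seed = 1L, outDir = tempfile("appsig_run_")) {
  rankingMode <- match.arg(rankingMode)
  fromFiles <- !is.null(matrixPath) || !is.null(labelsPath)
  if (fromFiles && (is.null(matrixPath) || is.null(labelsPath)))
    stop("matrixPath and labelsPath must be given together", call. = FALSE)
  if (fromFiles == !is.null(synthetic))
    stop("give exactly one input source: file paths or a synthetic config",
         call. = FALSE)
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]", call. = FALSE)
  if (B < 1L) stop("B must be >= 1", call. = FALSE)
  if (kMax < 1L) stop("kMax must be >= 1", call. = FALSE)
  if (ridgeLambda < 0) stop("ridgeLambda must be >= 0", call. = FALSE)
  if (any(thresholds < 0 | thresholds > 1))
    stop("thresholds must lie in [0, 1]", call. = FALSE)
  cfg <- list(matrixPath = matrixPath, labelsPath = labelsPath,
              synthetic = synthetic, normalize = isTRUE(normalize),
              alpha = alpha, B = as.integer(B), kMax = as.integer(kMax),
              ridgeLambda = ridgeLambda, thresholds = thresholds,
              rankingMode = rankingMode, seed = as.integer(seed),
              outDir = outDir)
  class(cfg) <- "pipelineConfig"
  cfg
}

# Expand the master seed into named per-stage seeds (< 2^31).
stageSeeds <- function(seed) {
  set.seed(seed)
  stats::setNames(sample.int(.Machine$integer.max - 1L, 2L),
                  c("synthetic", "bootstrap"))
}

#' Run the full signature-discovery pipeline
#'
#' Executes, in fixed order: data loading or synthetic generation, quantile
#' normalization, log2 transformation, the whole-cohort differential
#' expression table, the bootstrap discovery/validation signature search,
#' signature selection, and ROC/AUC evaluation. Writes to `config$outDir`:
#' `de_table.tsv`, `iteration_records.tsv`, `per_size_summary.tsv`,
#' `signature.txt`, `roc_table.tsv`, `auc_summary.tsv` and `manifest.yml`.
#' A partial manifest (flagged `status: failed`) is written even when a
#' stage aborts.
#'
#' @param config a [pipelineConfig()].
#' @return Invisibly, a list with components `matrix`, `de`, `run`,
#'   `selection`, `roc`, `auc`, `manifest`.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "pipelineConfig"))
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  seeds <- stageSeeds(config$seed)
  manifest <- list(
    config = config[setdiff(names(config), "synthetic")],
    synthetic = if (!is.null(config$synthetic))
      unclass(config$synthetic) else NULL,
    stage_seeds = as.list(seeds),
    version = as.character(utils::packageVersion("appsig")),
    status = "failed", stage = "input")
  writeManifest <- function()
    yaml::write_yaml(manifest, file.path(config$outDir, "manifest.yml"))
  on.exit(writeManifest())

  em <- if (!is.null(config$synthetic)) {
    cfg <- config$synthetic
    cfg$seed <- seeds[["synthetic"]]
    truth <- generateDataset(cfg)
    writeResultTable(truth$truth, file.path(config$outDir, "truth.tsv"))
    truth$matrix
  } else {
    readLabels(config$labelsPath, readExpressionMatrix(config$matrixPath))
  }
  manifest$n_genes <- nrow(em)
  manifest$class_counts <- as.list(table(classLabels(em)))

  manifest$stage <- "preprocess"
  emLog <- preprocessMatrix(em, normalize = config$normalize)

  manifest$stage <- "diffexpr"
  de <- runDE(emLog, alpha = config$alpha)
  writeResultTable(de[setdiff(names(de), "p_bh")],
                   file.path(config$outDir, "de_table.tsv"))
  manifest$n_significant <- attr(de, "n_significant")
  manifest$pct_significant <- attr(de, "pct_significant")

  manifest$stage <- "signature_search"
  run <- runDiscoveryValidation(emLog, B = config$B, kMax = config$kMax,
                                lambda = config$ridgeLambda,
                                seed = seeds[["bootstrap"]],
                                rankingMode = config$rankingMode)
  rec <- run@records
  flat <- data.frame(iteration = rec$iteration, size = rec$size,
                     genes = vapply(rec$genes, paste, "", collapse = ","),
                     discovery_auc = rec$discovery_auc,
                     validation_auc = rec$validation_auc)
  writeResultTable(flat, file.path(config$outDir, "iteration_records.tsv"))
  failed <- sum(is.na(rec$validation_auc[rec$size == 1L]))
  manifest$iterations_completed <- config$B - failed
  manifest$iterations_failed <- failed

  manifest$stage <- "selection"
  sel <- selectBestSignature(run)
  writeResultTable(sel@perSize, file.path(config$outDir,
                                          "per_size_summary.tsv"))
  writeLines(paste(sel@genes, collapse = "\t"),
             file.path(config$outDir, "signature.txt"))
  manifest$signature <- as.list(sel@genes)
  manifest$signature_size <- sel@size

  manifest$stage <- "evaluation"
  roc <- aggregateROC(run, sel@size, thresholds = config$thresholds)
  writeResultTable(roc, file.path(config$outDir, "roc_table.tsv"))
  auc <- summarizeAUC(run, sel@size)
  writeResultTable(as.data.frame(auc),
                   file.path(config$outDir, "auc_summary.tsv"))
  manifest$auc <- auc

  manifest$stage <- "done"
  manifest$status <- "ok"
  invisible(list(matrix = em, de = de, run = run, selection = sel,
                 roc = roc, auc = auc, manifest = manifest))
}

#' Report a completed run directory
#'
#' Pure function of the run artifacts (no recomputation): prints the
#' selected signature, the per-size mean validation AUCs, and the headline
#' line in the conventional style
#' `AUC was X% (SE Y, CL Z)` using the normal-approximation lower limit,
#' with the percentile limit alongside.
#'
#' @param runDir directory written by [runPipeline()].
#' @return Invisibly, the report lines.
#' @export
reportRun <- function(runDir) {
  need <- function(f) {
    p <- file.path(runDir, f)
    if (!file.exists(p)) stop(sprintf("missing run artifact: %s", f),
                              call. = FALSE)
    p
  }
  sig <- strsplit(readLines(need("signature.txt"))[1L], "\t")[[1L]]
  perSize <- readResultTable(need("per_size_summary.tsv"))
  auc <- readResultTable(need("auc_summary.tsv"))
  lines <- c(
    sprintf("Selected signature (%d genes): %s", length(sig),
            paste(sig, collapse = ", ")),
    "Mean validation AUC by signature size:",
    sprintf("  size %2d: %.3f (n = %d)", perSize$size,
            perSize$mean_validation_auc, perSize$n_iterations),
    sprintf("AUC was %.0f%% (SE %.0f, CL %.1f)", 100 * auc$mean_auc,
            100 * auc$se_auc, 100 * auc$cl_lower_normal),
    sprintf("  percentile lower 95%% limit: %.1f%%",
            100 * auc$cl_lower_percentile))
  cat(lines, sep = "\n")
  invisible(lines)
}
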