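#' Sensitivity and specificity at a probability threshold
#'
#' Predicts GA when the class probability is strictly greater than
#' `threshold`, so the 0 and 1 boundaries are well-defined. Sensitivity is
#' the true-positive rate with respect to GA (class 1), specificity the
#' true-negative rate with respect to PA (class 0).
#'
#' @param probabilities GA class probabilities in \[0, 1\].
#' @param labels binary labels (0 = PA, 1 = GA, or a PA/GA factor) with both
#'   classes present.
#' @param threshold probability cut-point.
#' @return c(sensitivity, specificity).
#' @export
confusionAtThreshold <- function(probabilities, labels, threshold) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  if (length(unique(labels)) < 2L)
    stop("labels must contain both classes", call. = FALSE)
  if (any(probabilities < 0 | probabilities > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  pred <- probabilities > threshold
  c(sensitivity = sum(pred & labels == 1L) / sum(labels == 1L),
    specificity = sum(!pred & labels == 0L) / sum(labels == 0L))
}

#' Concordance (rank) AUC
#'
#' AUC as the probability that a random GA sample scores above a random PA
#' sample, with ties counted one half:
#' \eqn{(\#\{s_{GA} > s_{PA}\} + 0.5\,\#ties) / (n_{GA} n_{PA})}. Computed
#' via midranks; identical to trapezoidal integration of the
#' full-resolution ROC curve.
#'
#' @param probabilities scores (higher = more GA-like).
#' @param labels binary labels with both classes present.
#' @return AUC in \[0, 1\].
#' @examples
#' aucConcordance(c(0.8, 0.3, 0.6, 0.1), c(1, 1, 0, 0))  # 0.75
#' @export
aucConcordance <- function(probabilities, labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("labels must contain both classes", call. = FALSE)
  r <- rank(probabilities)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Threshold-swept ROC aggregated over bootstrap iterations
#'
#' For a chosen signature size, computes sensitivity and specificity on each
#' iteration's out-of-bag validation set at every threshold of the grid,
#' then reports their mean and bootstrap SE across iterations. Following the
#' bootstrap convention, SE is the standard deviation of the per-iteration
#' statistic (ddof = 1), not SD/sqrt(B).
#'
#' @param run a [BootstrapRun-class] from [runDiscoveryValidation()].
#' @param size signature size whose records to aggregate (default: all sizes
#'   pooled is not meaningful, so the size must be given).
#' @param thresholds probability grid (default 0.05 to 0.95 by 0.05).
#' @return data.frame: `threshold`, `sensitivity_mean`, `sensitivity_se`,
#'   `specificity_mean`, `specificity_se`, `n_iterations`.
#' @export
aggregateROC <- function(run, size, thresholds = seq(0.05, 0.95, by = 0.05)) {
  stopifnot(is(run, "BootstrapRun"))
  rec <- run@records[run@records$size == size &
                       !is.na(run@records$validation_auc), , drop = FALSE]
  if (nrow(rec) < 2L)
    stop("need at least 2 contributing iterations", call. = FALSE)
  sens <- spec <- matrix(NA_real_, nrow(rec), length(thresholds))
  for (i in seq_len(nrow(rec))) {
    pr <- rec$validation_probs[[i]]
    lb <- rec$validation_labels[[i]]
    for (j in seq_along(thresholds)) {
      ss <- confusionAtThreshold(pr, lb, thresholds[j])
      sens[i, j] <- ss[1L]; spec[i, j] <- ss[2L]
    }
  }
  data.frame(
    threshold = thresholds,
    sensitivity_mean = colMeans(sens),
    sensitivity_se = apply(sens, 2L, stats::sd),
    specificity_mean = colMeans(spec),
    specificity_se = apply(spec, 2L, stats::sd),
    n_iterations = nrow(rec))
}

#' Bootstrap summary of the validation AUC
#'
#' Mean of the per-iteration out-of-bag validation AUCs for one signature
#' size, with the bootstrap SE (SD across iterations, ddof = 1) and two
#' lower 95% confidence limits: the normal approximation (mean - 1.96 SE)
#' and the 2.5th percentile of the per-iteration AUCs.
#'
#' @param run a [BootstrapRun-class].
#' @param size signature size to summarize.
#' @return A list: `mean_auc`, `se_auc`, `cl_lower_normal`,
#'   `cl_lower_percentile`, `n_iterations`.
#' @export
summarizeAUC <- function(run, size) {
  stopifnot(is(run, "BootstrapRun"))
  aucs <- run@records$validation_auc[run@records$size == size]
  aucs <- aucs[!is.na(aucs)]
  if (length(aucs) < 2L)
    stop("need at least 2 iterations with a validation AUC", call. = FALSE)
  m <- mean(aucs); s <- stats::sd(aucs)
  list(mean_auc = m, se_auc = s,
       cl_lower_normal = m - 1.96 * s,
       cl_lower_percentile = unname(stats::quantile(aucs, 0.025)),
       n_iterations = length(aucs))
}
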