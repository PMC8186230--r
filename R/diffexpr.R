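#' Welch's unequal-variance t-test
#'
#' Two-sided Welch test: t = (mean1 - mean0) / sqrt(s1^2/n1 + s0^2/n0) with
#' sample variances (divisor n - 1) and Welch-Satterthwaite degrees of
#' freedom. Positive t means higher in group 1 (GA). Degenerate inputs
#' follow fixed conventions so no gene is ever dropped: both variances zero
#' with equal means gives t = 0, p = 1; both variances zero with different
#' means gives p = 0 (infinite t).
#'
#' @param group0,group1 numeric vectors, each of length >= 2.
#' @return A list with `t`, `df`, `p`.
#' @examples
#' welchTest(c(1, 2, 3), c(2, 4, 6))
#' @export
welchTest <- function(group0, group1) {
  if (length(group0) < 2L || length(group1) < 2L)
    stop("each group needs at least 2 values", call. = FALSE)
  r <- rowWelch(matrix(c(group0, group1), nrow = 1L),
                seq_along(group0), length(group0) + seq_along(group1))
  list(t = r$t[1L], df = r$df[1L], p = r$p[1L])
}

# Vectorized row-wise Welch test. x: genes x samples; idx0/idx1: column
# indices of the two groups. Row means are removed before the variance pass
# for numerical stability at high baseline intensities.
rowWelch <- function(x, idx0, idx1) {
  n0 <- length(idx0); n1 <- length(idx1)
  x0 <- x[, idx0, drop = FALSE]; x1 <- x[, idx1, drop = FALSE]
  m0 <- rowMeans(x0); m1 <- rowMeans(x1)
  v0 <- rowSums((x0 - m0)^2) / (n0 - 1)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  se2 <- v1 / n1 + v0 / n0
  d <- m1 - m0
  t <- d / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  deg <- se2 == 0
  if (any(deg)) {
    eq <- deg & d == 0
    t[eq] <- 0; p[eq] <- 1
    ne <- deg & d != 0
    t[ne] <- sign(d[ne]) * Inf; p[ne] <- 0
    df[deg] <- n0 + n1 - 2
  }
  list(t = t, df = df, p = p, log2fc = d)
}

#' Log2 fold change between groups
#'
#' Difference of group means on the log2 scale, `mean(group1) -
#' mean(group0)`; equal to the log2 ratio of geometric means of the
#' linear-scale intensities.
#'
#' @param group0,group1 non-empty numeric vectors of log2 values.
#' @return numeric(1).
#' @export
log2FoldChange <- function(group0, group1) {
  if (!length(group0) || !length(group1))
    stop("both groups must be non-empty", call. = FALSE)
  mean(group1) - mean(group0)
}

#' Per-gene differential expression between PA and GA
#'
#' Runs the Welch test and log2 fold change for every gene of a log2-scale
#' matrix, flagging genes with two-sided p < `alpha` as significant (raw
#' p-values; the study design applies no multiple-testing adjustment, but a
#' Benjamini-Hochberg column is provided for reference). Row order matches
#' the input gene order.
#'
#' @param x a log2-scale [ExprMatrix-class] with PA/GA labels attached.
#' @param alpha significance level (default 0.05).
#' @return A data.frame with columns `gene_id`, `t`, `df`, `p`, `log2fc`,
#'   `p_bh`, `significant`, and attributes `n_significant` and
#'   `pct_significant` (percentage at one decimal).
#' @export
runDE <- function(x, alpha = 0.05) {
  stopifnot(is(x, "ExprMatrix"))
  if (exprScale(x) != "log2")
    stop("differential expression expects a log2-scale matrix", call. = FALSE)
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]", call. = FALSE)
  y <- labelCodes(x)
  r <- rowWelch(exprValues(x), which(y == 0L), which(y == 1L))
  tab <- data.frame(
    gene_id = geneIds(x),
    t = r$t, df = r$df, p = r$p, log2fc = r$log2fc,
    p_bh = stats::p.adjust(r$p, method = "BH"),
    significant = r$p < alpha
  )
  attr(tab, "alpha") <- alpha
  attr(tab, "n_significant") <- sum(tab$significant)
  attr(tab, "pct_significant") <-
    round(100 * sum(tab$significant) / nrow(tab), 1L)
  tab
}
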