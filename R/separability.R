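#' Fisher Discriminant Ratio between two groups
#'
#' Scalar cluster-separability index: the squared difference between the
#' group means divided by the sum of the squared group standard deviations.
#' A large value means the two groups form well-separated clusters (the
#' cluster assumption of semi-supervised learning plausibly holds); a value
#' near zero means the groups overlap and cluster-based label inference is
#' unreliable.
#'
#' Two conventions are offered.  In one dimension (`univariate`) the index
#' is `(m1 - m2)^2 / (s1^2 + s2^2)` with sample (n-1) standard deviations.
#' In `d > 1` dimensions (`pooled`) the numerator is the squared Euclidean
#' norm of the mean difference and the denominator the sum over features of
#' both groups' sample variances — a pooled extension of the scalar formula,
#' chosen because separability of multi-dimensional feature clouds must be
#' summarised by one number.  Affine maps `x -> a x + b` leave either
#' version unchanged.
#'
#' @param group1,group2 numeric vectors, or matrices with the same number
#'   of columns; each group needs at least 2 points (sample SD).
#' @param mode `"auto"` (univariate when `d == 1`, pooled otherwise),
#'   `"univariate"` or `"pooled"`.
#' @param tol mean-difference tolerance below which the ratio is reported
#'   as exactly 0.
#' @return An object of class `fdr_report`: list with `value` (non-negative,
#'   `Inf` when both variances vanish but the means differ), `mode`, `n1`,
#'   `n2`.
#' @examples
#' fisher_discriminant_ratio(c(0, 2), c(4, 6))$value  # 4
#' @export
fisher_discriminant_ratio <- function(group1, group2,
                                      mode = c("auto", "univariate",
                                               "pooled"),
                                      tol = 1e-12) {
  mode <- match.arg(mode)
  g1 <- as.matrix(group1); g2 <- as.matrix(group2)
  if (ncol(g1) != ncol(g2)) stop("groups must have the same dimension")
  if (nrow(g1) < 2L || nrow(g2) < 2L)
    stop("each group needs at least 2 points for a sample SD")
  d <- ncol(g1)
  if (mode == "auto") mode <- if (d == 1L) "univariate" else "pooled"
  if (mode == "univariate" && d != 1L)
    stop("univariate mode requires 1-dimensional groups")

  m1 <- colMeans(g1); m2 <- colMeans(g2)
  v1 <- apply(g1, 2, stats::var); v2 <- apply(g2, 2, stats::var)
  num <- sum((m1 - m2)^2)
  den <- sum(v1) + sum(v2)
  scale_ref <- max(sqrt(sum(m1^2)), sqrt(sum(m2^2)), 1)
  value <- if (sqrt(num) <= tol * scale_ref) 0 else if (den == 0) Inf else
    num / den
  structure(list(value = value,
                 mode = if (d == 1L) mode else "pooled-multivariate",
                 n1 = nrow(g1), n2 = nrow(g2)),
            class = "fdr_report")
}

#' @export
print.fdr_report <- function(x, ...) {
  cat(sprintf("fdr_report (%s): FDR = %.6g  [n1 = %d, n2 = %d]\n",
              x$mode, x$value, x$n1, x$n2))
  invisible(x)
}

#' FDR between two labeled classes of a dataset
#'
#' Convenience wrapper slicing a [feature_table()] by two class ids of its
#' [partial_labels()] and delegating to [fisher_discriminant_ratio()].
#'
#' @param table a [feature_table()].
#' @param labels a [partial_labels()].
#' @param class1,class2 class ids to compare.
#' @param mode see [fisher_discriminant_ratio()].
#' @return An `fdr_report`.
#' @export
class_separability <- function(table, labels, class1, class2,
                               mode = "auto") {
  check_table_labels(table, labels)
  i1 <- which(labels$labels == class1)
  i2 <- which(labels$labels == class2)
  if (!length(i1) || !length(i2))
    stop("both classes must have labeled instances")
  fisher_discriminant_ratio(table$values[i1, , drop = FALSE],
                            table$values[i2, , drop = FALSE],
                            mode = mode)
}
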