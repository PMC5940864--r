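#' Binary classification metrics
#'
#' Computes accuracy, sensitivity `TP / (TP + FN)`, specificity
#' `TN / (TN + FP)` and the AUC — the probability that a random positive's
#' score exceeds a random negative's, with ties counted one half (computed
#' by the midrank formula, exactly equivalent to comparing all pairs).
#' Metrics are fractions; formatting as percentages is left to reporting.
#'
#' @param truth character vector of true class ids.
#' @param predicted character vector of predicted class ids.
#' @param scores optional numeric decision scores, larger = more positive;
#'   required for AUC.
#' @param positive the class id counted as positive.
#' @return A list with `accuracy`, `sensitivity`, `specificity`, `auc`,
#'   and the confusion counts `tp`, `fn`, `tn`, `fp`.  When the truth
#'   contains no positives (or no negatives) the undefined entries are `NA`
#'   sentinels, never an error.
#' @examples
#' compute_metrics(c("p","p","n","n"), c("p","n","n","n"),
#'                 scores = c(3, 1, 2, 0), positive = "p")
#' @export
compute_metrics <- function(truth, predicted, scores = NULL, positive) {
  stopifnot(length(truth) == length(predicted))
  if (!is.null(scores)) stopifnot(length(scores) == length(truth))
  pos <- truth == positive
  tp <- sum(pos & predicted == positive)
  fn <- sum(pos & predicted != positive)
  tn <- sum(!pos & predicted != positive)
  fp <- sum(!pos & predicted == positive)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  acc <- (tp + tn) / length(truth)
  auc <- NA_real_
  if (!is.null(scores) && any(pos) && any(!pos) && !anyNA(scores)) {
    r <- rank(scores)                      # midranks handle ties as 1/2
    n1 <- sum(pos); n0 <- sum(!pos)
    auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  list(accuracy = acc, sensitivity = sens, specificity = spec, auc = auc,
       tp = tp, fn = fn, tn = tn, fp = fp)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test for paired metric vectors (for example
#' per-fold accuracies of two methods).  Zero differences are dropped
#' (Wilcoxon's original rule); the statistic is `W = min(W+, W-)` where
#' `W+`/`W-` are the rank sums of positive/negative differences, using
#' midranks for tied magnitudes.  For `n <= 12` retained pairs the p-value
#' is exact, by enumeration of all `2^n` sign assignments of the observed
#' magnitudes (`p = P(min(W+, W-) <= observed)`); beyond that a normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param a,b equal-length numeric vectors of paired measurements.
#' @return A list with `statistic` (`W`), `w_plus`, `w_minus`, `p_value`,
#'   `n_effective` (pairs retained after dropping zeros) and `method`
#'   (`"exact"` or `"normal"`).
#' @examples
#' wilcoxon_paired(c(5, 6, 7, 8, 9, 10), c(1, 2, 3, 4, 5, 6))$p_value
#' @export
wilcoxon_paired <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    stop("all paired differences are zero: the test is undefined")
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r[d < 0])
  w <- min(w_plus, w_minus)
  if (n <= 12L) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    wp <- as.vector(signs %*% r)
    s_tot <- sum(r)
    p <- mean(pmin(wp, s_tot - wp) <= w)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (w_plus - mu - sign(w_plus - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  list(statistic = w, w_plus = w_plus, w_minus = w_minus, p_value = p,
       n_effective = n, method = method)
}

#' Bonferroni-adjusted significance level
#'
#' Divides the family-wise error rate by the number of comparisons times
#' the number of tails.  With six pairwise comparisons and a two-tailed
#' test at `alpha = 0.05` the adjusted level reports (3 decimals) as 0.004.
#' The conventional `alpha / comparisons` adjustment is `tails = 1`.
#'
#' @param alpha family-wise type-I error rate, in `(0, 1)`.
#' @param n_comparisons number of pairwise comparisons.
#' @param tails 1 or 2.
#' @return The adjusted alpha at full precision; round for display.
#' @examples
#' round(bonferroni_alpha(0.05, 6, 2), 3)  # 0.004
#' @export
bonferroni_alpha <- function(alpha, n_comparisons, tails = 2) {
  stopifnot(alpha > 0, alpha < 1, n_comparisons >= 1, tails %in% c(1, 2))
  alpha / (n_comparisons * tails)
}

#' Compare two per-fold metric vectors
#'
#' Paired Wilcoxon signed-rank test plus the Bonferroni-adjusted level and
#' the resulting significance call.
#'
#' @param a,b paired per-fold metric vectors (same folds, two methods).
#' @param alpha family-wise level; default 0.05.
#' @param n_comparisons number of comparisons in the family; default 1.
#' @param tails tails of the adjustment; default 2.
#' @return A list of class `comparison_result` with the test output,
#'   `adjusted_alpha` and logical `significant`.
#' @export
compare_methods <- function(a, b, alpha = 0.05, n_comparisons = 1,
                            tails = 2) {
  test <- wilcoxon_paired(a, b)
  adj <- bonferroni_alpha(alpha, n_comparisons, tails)
  structure(c(test, list(adjusted_alpha = adj,
                         significant = test$p_value < adj)),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf(
    "comparison_result: W = %g, p = %.4g (%s), adjusted alpha = %.3f -> %s\n",
    x$statistic, x$p_value, x$method, x$adjusted_alpha,
    if (x$significant) "significant" else "not significant"))
  invisible(x)
}

# Deterministic assignment of groups to folds: seeded permutation of the
# group ids, then round-robin.
make_group_folds <- function(group_ids, folds, seed) {
  gids <- unique(group_ids)
  if (folds > length(gids))
    stop("more folds than groups: grouped CV is impossible")
  perm <- withr_local_seed(seed, sample(gids))
  fold_of_group <- stats::setNames(rep(seq_len(folds),
                                       length.out = length(perm)), perm)
  unname(fold_of_group[group_ids])
}

withr_local_seed <- function(s, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(s)
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
    assign(".Random.seed", old, envir = globalenv()))
  expr
}

fit_method <- function(method, table, labels, C, gamma,
                       tie_fallback_class, k = "auto") {
  switch(method,
    supervised = fit_supervised(table, labels, C = C, gamma = gamma),
    s3db = fit_cluster_then_label(table, labels, method = "s3db",
                                  C = C, gamma = gamma, k = k,
                                  tie_fallback_class = tie_fallback_class),
    ssfcm = fit_cluster_then_label(table, labels, method = "ssfcm",
                                   C = C, gamma = gamma),
    stop("unknown method: ", method))
}

slice_dataset <- function(table, labels, idx) {
  list(table = feature_table(table$values[idx, , drop = FALSE],
                             instance_ids = table$instance_ids[idx],
                             group_ids = if (is.null(table$group_ids)) NULL
                                         else table$group_ids[idx]),
       labels = partial_labels(labels$labels[idx],
                               classes = labels$classes))
}

#' Grouped (patient-wise) cross-validation
#'
#' Folds hold out entire groups, so instances from one group never span
#' train and test; for the semi-supervised methods the held-out rows are
#' excluded from the labeler as well as the classifier, so no structural
#' leakage occurs.  Within each training fold every `(C, gamma)` grid cell
#' is scored by inner grouped cross-validation on the *labeled* rows of the
#' inner validation groups, the sensitivity-constrained operating point is
#' selected ([select_operating_point()]), the model is refitted on the full
#' training fold at the selected parameters, and the held-out fold is
#' scored against the true labels.
#'
#' @param table a [feature_table()] with group ids.
#' @param labels a [partial_labels()]; unlabeled rows participate in the
#'   semi-supervised labelers but never in metric computation for
#'   selection.
#' @param truth full-length true class ids, used only to score held-out
#'   folds.
#' @param method `"supervised"`, `"s3db"` or `"ssfcm"`.
#' @param folds number of folds; at most the number of groups.
#' @param grid list with numeric `C_values` and `gamma_values`.
#' @param positive class id treated as positive.
#' @param target_sensitivity operating-point constraint; default 0.95.
#' @param tie_fallback_class tie class for `"s3db"`.
#' @param k neighbourhood size for `"s3db"`; default `"auto"`.
#' @param inner_folds inner folds for grid scoring; default
#'   `min(3, groups in the training fold)`.
#' @param seed seed for the group-to-fold permutation.
#' @return An object of class `metrics_report`: list with `per_fold` (data
#'   frame of fold metrics and selected parameters), `means` (fold means,
#'   `NA` sentinels excluded with a warning), `method`, `n_folds`.
#' @export
grouped_cross_validate <- function(table, labels, truth, method, folds,
                                   grid, positive,
                                   target_sensitivity = 0.95,
                                   tie_fallback_class = NULL, k = "auto",
                                   inner_folds = NULL, seed = 1) {
  check_table_labels(table, labels)
  if (is.null(table$group_ids)) stop("grouped CV needs group ids")
  stopifnot(length(truth) == nrow(table$values))
  if (!all(c("C_values", "gamma_values") %in% names(grid)) ||
      !length(grid$C_values) || !length(grid$gamma_values))
    stop("grid must have non-empty C_values and gamma_values")
  fold_id <- make_group_folds(table$group_ids, folds, seed)
  cells <- expand.grid(C = grid$C_values, gamma = grid$gamma_values,
                       KEEP.OUT.ATTRS = FALSE)

  rows <- vector("list", folds)
  for (f in seq_len(folds)) {
    test_idx <- which(fold_id == f)
    train_idx <- which(fold_id != f)
    tr <- slice_dataset(table, labels, train_idx)

    # inner grouped CV over training groups scores each grid cell
    tr_groups <- unique(tr$table$group_ids)
    n_inner <- if (is.null(inner_folds)) min(3L, length(tr_groups)) else
      min(inner_folds, length(tr_groups))
    sel <- if (n_inner >= 2L) {
      inner_id <- make_group_folds(tr$table$group_ids, n_inner,
                                   seed + 1000L * f)
      score_cell <- function(C, gamma) {
        cm <- c(tp = 0, fn = 0, tn = 0, fp = 0)
        for (g in seq_len(n_inner)) {
          in_tr <- slice_dataset(tr$table, tr$labels, which(inner_id != g))
          val_idx <- which(inner_id == g & !is.na(tr$labels$labels))
          if (!length(val_idx)) next
          mdl <- tryCatch(
            fit_method(method, in_tr$table, in_tr$labels, C, gamma,
                       tie_fallback_class, k),
            error = function(e) NULL)
          if (is.null(mdl)) next
          pr <- predict(mdl, tr$table$values[val_idx, , drop = FALSE])
          mt <- compute_metrics(tr$labels$labels[val_idx], pr$label,
                                positive = positive)
          cm <- cm + c(tp = mt$tp, fn = mt$fn, tn = mt$tn, fp = mt$fp)
        }
        c(sensitivity = if (cm["tp"] + cm["fn"] > 0)
            unname(cm["tp"] / (cm["tp"] + cm["fn"])) else NA_real_,
          specificity = if (cm["tn"] + cm["fp"] > 0)
            unname(cm["tn"] / (cm["tn"] + cm["fp"])) else NA_real_)
      }
      ss <- t(mapply(score_cell, cells$C, cells$gamma))
      gr <- cbind(cells, ss)
      tryCatch(select_operating_point(gr, target_sensitivity),
               error = function(e) NULL)
    } else NULL
    if (is.null(sel))
      sel <- list(C = cells$C[1L], gamma = cells$gamma[1L],
                  achieved_sensitivity = NA_real_,
                  achieved_specificity = NA_real_)

    mdl <- fit_method(method, tr$table, tr$labels, sel$C, sel$gamma,
                      tie_fallback_class, k)
    pr <- predict(mdl, table$values[test_idx, , drop = FALSE])
    mt <- compute_metrics(truth[test_idx], pr$label,
                          scores = orient_scores(pr, mdl, positive),
                          positive = positive)
    rows[[f]] <- data.frame(fold = f, C = sel$C, gamma = sel$gamma,
                            val_sensitivity = sel$achieved_sensitivity,
                            val_specificity = sel$achieved_specificity,
                            accuracy = mt$accuracy,
                            sensitivity = mt$sensitivity,
                            specificity = mt$specificity, auc = mt$auc,
                            n_test = length(test_idx))
  }
  per_fold <- do.call(rbind, rows)
  metric_cols <- c("accuracy", "sensitivity", "specificity", "auc")
  if (anyNA(per_fold[metric_cols]))
    warning("undefined fold metrics (single-class fold?) excluded from means")
  means <- colMeans(per_fold[metric_cols], na.rm = TRUE)
  structure(list(per_fold = per_fold, means = as.list(means),
                 method = method, n_folds = folds),
            class = "metrics_report")
}

orient_scores <- function(pr, mdl, positive) {
  if (length(mdl$classes) != 2L || anyNA(pr$score)) return(NULL)
  if (identical(positive, mdl$classes[2L])) pr$score else -pr$score
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("metrics_report (%s, %d folds)\n", x$method, x$n_folds))
  cat(sprintf("  mean accuracy    %6.1f %%\n", 100 * x$means$accuracy))
  cat(sprintf("  mean sensitivity %6.1f %%\n", 100 * x$means$sensitivity))
  cat(sprintf("  mean specificity %6.1f %%\n", 100 * x$means$specificity))
  cat(sprintf("  mean AUC         %6.3f\n", x$means$auc))
  invisible(x)
}
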