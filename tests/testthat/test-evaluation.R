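test_that("confusion metrics follow the standard formulas", {
  truth <- c(rep("p", 10), rep("n", 10))
  pred <- c(rep("p", 9), "n", rep("n", 8), "p", "p")
  m <- compute_metrics(truth, pred, positive = "p")
  expect_equal(m$sensitivity, 0.9)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$accuracy, 0.85)
  # undefined sentinels when a class is absent
  m2 <- compute_metrics(rep("p", 5), rep("p", 5), positive = "p")
  expect_true(is.na(m2$specificity))
  expect_equal(m2$sensitivity, 1)
})

test_that("AUC equals the all-pairs probability, ties counting one half", {
  truth <- c("p", "p", "n", "n")
  expect_equal(compute_metrics(truth, truth, scores = c(4, 3, 2, 1),
                               positive = "p")$auc, 1)
  expect_equal(compute_metrics(truth, truth, scores = c(1, 1, 1, 1),
                               positive = "p")$auc, 0.5)
  set.seed(83)
  for (rep in 1:20) {
    n <- sample(10:200, 1)
    truth <- sample(c("p", "n"), n, replace = TRUE,
                    prob = c(0.4, 0.6))
    if (length(unique(truth)) < 2) next
    scores <- sample(round(rnorm(n), 1))  # coarse grid forces ties
    got <- compute_metrics(truth, truth, scores = scores,
                           positive = "p")$auc
    expect_equal(got, oracle_auc(truth, scores, "p"))
  }
})

test_that("signed-rank test matches full enumeration and the base oracle", {
  # all six differences positive: W = 0, p = 2/64
  w <- wilcoxon_paired(c(5, 6, 7, 8, 9, 10), c(1, 2, 3, 4, 5, 6))
  expect_equal(w$statistic, 0)
  expect_equal(w$p_value, 2 / 64)
  expect_identical(w$method, "exact")

  set.seed(91)
  for (rep in 1:20) {
    n <- sample(4:10, 1)
    a <- round(rnorm(n), 1)
    b <- round(rnorm(n), 1)
    if (all(a == b)) next
    got <- wilcoxon_paired(a, b)
    expect_equal(got$p_value, oracle_wilcoxon_p(a, b))
    # symmetry: swapping the vectors swaps the one-sided rank sums
    rev <- wilcoxon_paired(b, a)
    expect_equal(rev$p_value, got$p_value)
    expect_equal(rev$w_plus, got$w_minus)
  }

  # where no zeros/ties interfere, the base implementation agrees exactly
  set.seed(92)
  a <- rnorm(9); b <- rnorm(9)
  expect_equal(wilcoxon_paired(a, b)$p_value,
               stats::wilcox.test(a, b, paired = TRUE,
                                  exact = TRUE)$p.value)

  expect_error(wilcoxon_paired(c(1, 2), c(1, 2)), "undefined")
})

test_that("multiple-testing adjustment divides by comparisons and tails", {
  expect_equal(round(bonferroni_alpha(0.05, 6, 2), 3), 0.004)
  expect_equal(bonferroni_alpha(0.05, 6, 2), 0.05 / 12)
  expect_equal(bonferroni_alpha(0.05, 1, 1), 0.05)
  expect_equal(bonferroni_alpha(0.05, 5, 1), 0.01)
  cmp <- compare_methods(c(5, 6, 7, 8, 9, 10), c(1, 2, 3, 4, 5, 6),
                         n_comparisons = 6, tails = 2)
  expect_false(cmp$significant)  # 0.03125 > 0.00417
  expect_equal(cmp$adjusted_alpha, 0.05 / 12)
})

test_that("grouped folds partition instances exactly, by whole groups", {
  ds <- generate_dataset(synthetic_config(n_per_class = 60, n_groups = 6,
                                          label_fraction = 0.3, seed = 21))
  fold_id <- ssclust:::make_group_folds(ds$table$group_ids, 3, seed = 5)
  expect_length(fold_id, nrow(ds$table$values))
  expect_setequal(unique(fold_id), 1:3)
  # a group never straddles folds
  expect_true(all(tapply(fold_id, ds$table$group_ids,
                         function(f) length(unique(f))) == 1))
  # union of test folds is everything, with no overlap
  expect_equal(sort(unlist(lapply(1:3, function(f) which(fold_id == f)))),
               seq_along(fold_id))
  expect_error(ssclust:::make_group_folds(ds$table$group_ids, 7, 1),
               "more folds than groups")
})

test_that("grouped cross-validation reports fold metrics and parameters", {
  ds <- generate_dataset(synthetic_config("gaussian_blobs",
                                          n_per_class = 60, d = 2,
                                          separation = 5, n_groups = 4,
                                          label_fraction = 0.3, seed = 77))
  grid <- list(C_values = c(1, 10), gamma_values = c(0.5))
  rep_sup <- grouped_cross_validate(ds$table, ds$labels, ds$truth,
                                    method = "supervised", folds = 2,
                                    grid = grid, positive = "c2", seed = 4)
  expect_s3_class(rep_sup, "metrics_report")
  expect_equal(nrow(rep_sup$per_fold), 2L)
  expect_true(all(rep_sup$per_fold$C %in% grid$C_values))
  expect_equal(sum(rep_sup$per_fold$n_test), nrow(ds$table$values))
  expect_true(rep_sup$means$accuracy > 0.8)  # separable blobs

  rep_s3db <- grouped_cross_validate(ds$table, ds$labels, ds$truth,
                                     method = "s3db", folds = 2,
                                     grid = grid, positive = "c2",
                                     tie_fallback_class = "c1", seed = 4)
  expect_true(rep_s3db$means$accuracy > 0.8)
})

test_that("single-class test folds yield sentinels, not crashes", {
  set.seed(71)
  X <- matrix(rnorm(40), 20, 2)
  X[11:20, 1] <- X[11:20, 1] + 6
  truth <- rep(c("c1", "c2"), each = 10)
  # group g2 is entirely class c1, so its test fold has no positives;
  # g1 spans both classes, keeping every training fold two-class
  groups <- c(rep("g1", 5), rep("g2", 5), rep("g1", 5), rep("g3", 5))
  ft <- feature_table(X, group_ids = groups)
  pl <- partial_labels(ifelse(seq_len(20) %% 2 == 0, truth, NA))
  grid <- list(C_values = 1, gamma_values = 0.5)
  expect_warning(
    rep1 <- grouped_cross_validate(ft, pl, truth, method = "supervised",
                                   folds = 3, grid = grid,
                                   positive = "c2", seed = 2),
    "excluded from means")
  expect_true(anyNA(rep1$per_fold$sensitivity) ||
                anyNA(rep1$per_fold$specificity))
  expect_false(anyNA(rep1$means$accuracy))
})
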