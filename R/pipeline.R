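#' Supervised RBF-SVM baseline
#'
#' Fits a kernel max-margin classifier (radial basis function kernel) on the
#' labeled rows only; unlabeled rows are discarded, mirroring a supervised
#' workflow in which unlabeled data simply does not exist.
#'
#' @param table a [feature_table()].
#' @param labels a [partial_labels()] with at least two labeled classes.
#' @param C positive trade-off between margin size and training error.
#' @param gamma positive RBF kernel width; default `1 / d`.
#' @param class_weights optional named vector of per-class weights (e.g.
#'   inverse class frequencies) passed to the classifier; default `NULL`
#'   (unweighted).
#' @return An object of class `ssl_model` wrapping the fitted classifier,
#'   with elements `method` (`"supervised"`), `classes`, `params`,
#'   `assignment` (`NULL` here) and `d`.
#' @examples
#' ft <- feature_table(matrix(c(-5, -4, 4, 5), ncol = 1))
#' pl <- partial_labels(c("a", "a", "b", "b"))
#' m <- fit_supervised(ft, pl, C = 1, gamma = 0.5)
#' predict(m, ft)$label
#' @export
fit_supervised <- function(table, labels, C = 1, gamma = NULL,
                           class_weights = NULL) {
  check_table_labels(table, labels)
  idx <- labeled_indices(labels)
  y <- labels$labels[idx]
  if (length(unique(y)) < 2L)
    stop("supervised fitting needs at least two labeled classes")
  new_ssl_model(table$values[idx, , drop = FALSE],
                factor(y, levels = labels$classes[labels$classes %in% y]),
                method = "supervised", C = C, gamma = gamma,
                class_weights = class_weights, assignment = NULL)
}

#' Cluster-then-label: semi-supervised labeler + RBF-SVM
#'
#' Runs the chosen semi-supervised labeler — seeded density-based
#' clustering ([s3db()]) or semi-supervised fuzzy c-means
#' ([run_ssfcm()]) — and then trains the kernel classifier on *all* rows
#' with their given, inferred and tie labels, so the decision boundary is
#' informed by the structure of the unlabeled data.
#'
#' @inheritParams fit_supervised
#' @param method `"s3db"` or `"ssfcm"`.
#' @param k neighbourhood size for `"s3db"` (or `"auto"`).
#' @param tie_fallback_class tie class for `"s3db"`; see [assign_labels()].
#' @param m,max_iter,tol ssFCM settings; see [run_ssfcm()].
#' @param include_ties if `FALSE`, tie-labeled rows are dropped from the
#'   classifier's training set (they keep their fallback label in the
#'   stored assignment).  Default `TRUE`.
#' @param standardize passed to [s3db()].
#' @return An `ssl_model`; element `assignment` stores the labeler's
#'   full assignment result.
#' @export
fit_cluster_then_label <- function(table, labels,
                                   method = c("s3db", "ssfcm"),
                                   C = 1, gamma = NULL,
                                   k = "auto", tie_fallback_class,
                                   m = 2, max_iter = 1000, tol = 1e-6,
                                   include_ties = TRUE,
                                   standardize = FALSE,
                                   class_weights = NULL) {
  method <- match.arg(method)
  check_table_labels(table, labels)
  assignment <- switch(method,
    s3db = s3db(table, labels, k = k,
                tie_fallback_class = tie_fallback_class,
                standardize = standardize),
    ssfcm = run_ssfcm(table, labels, m = m, max_iter = max_iter,
                      tol = tol)$assignment)
  keep <- if (include_ties) seq_along(assignment$labels) else
    which(assignment$provenance != "tie")
  y <- assignment$labels[keep]
  if (length(unique(y)) < 2L)
    stop("augmented labels collapse to a single class; cannot fit")
  new_ssl_model(table$values[keep, , drop = FALSE],
                factor(y, levels = assignment$classes[assignment$classes %in% y]),
                method = method, C = C, gamma = gamma,
                class_weights = class_weights, assignment = assignment)
}

# Shared constructor: delegates the max-margin optimisation to the external
# RBF-kernel classifier; this package never reimplements it.
new_ssl_model <- function(X, y, method, C, gamma, class_weights, assignment) {
  stopifnot(C > 0)
  d <- ncol(X)
  if (is.null(gamma)) gamma <- 1 / d
  stopifnot(gamma > 0)
  svm_fit <- e1071::svm(x = X, y = y, scale = FALSE, kernel = "radial",
                        cost = C, gamma = gamma,
                        class.weights = class_weights)
  structure(list(svm = svm_fit, method = method,
                 classes = levels(y), d = d,
                 params = list(C = C, gamma = gamma),
                 assignment = assignment),
            class = "ssl_model")
}

#' @export
print.ssl_model <- function(x, ...) {
  cat(sprintf("ssl_model (%s): %d classes, C = %g, gamma = %g\n",
              x$method, length(x$classes), x$params$C, x$params$gamma))
  invisible(x)
}

#' Predict labels and decision scores
#'
#' @param object an `ssl_model`.
#' @param table a [feature_table()] (or bare matrix) with the same feature
#'   dimension the model was fitted on.
#' @param ... unused.
#' @return A data frame with one row per instance: `label`, and for binary
#'   models `score`, the real-valued decision value oriented so that larger
#'   scores favour the *second* class level (`object$classes[2]`).
#'   Multiclass models return `NA` scores.
#' @export
predict.ssl_model <- function(object, table, ...) {
  X <- if (inherits(table, "feature_table")) table$values else as.matrix(table)
  if (ncol(X) != object$d)
    stop("feature dimension mismatch: model expects ", object$d)
  pr <- stats::predict(object$svm, X, decision.values = TRUE)
  lab <- as.character(pr)
  score <- rep(NA_real_, nrow(X))
  if (length(object$classes) == 2L) {
    dv <- attr(pr, "decision.values")
    # libsvm names the column "A/B" with positive values favouring A;
    # flip so that positive scores favour classes[2]
    raw <- dv[, 1L]
    first <- strsplit(colnames(dv)[1L], "/", fixed = TRUE)[[1L]][1L]
    score <- if (identical(first, object$classes[2L])) raw else -raw
  }
  data.frame(label = lab, score = score, stringsAsFactors = FALSE)
}

#' Select the sensitivity-constrained operating point
#'
#' Given grid-search results, picks the parameter set whose validation
#' sensitivity reaches the target (default 95%) with maximal specificity.
#' If no set reaches the target, falls back to the maximum-sensitivity set;
#' remaining ties are broken by higher specificity, then smaller `C`, then
#' smaller `gamma`, so the choice is deterministic.
#'
#' @param grid_results data frame with columns `C`, `gamma`, `sensitivity`,
#'   `specificity` (fractions in `[0, 1]`).
#' @param target_sensitivity required validation sensitivity; default 0.95.
#' @return An object of class `operating_point`: list with `C`, `gamma`,
#'   `achieved_sensitivity`, `achieved_specificity`, and `met_target`.
#' @examples
#' g <- data.frame(C = c(1, 1, 10), gamma = c(0.1, 1, 1),
#'                 sensitivity = c(0.96, 0.95, 0.90),
#'                 specificity = c(0.30, 0.50, 0.90))
#' select_operating_point(g)
#' @export
select_operating_point <- function(grid_results, target_sensitivity = 0.95) {
  req <- c("C", "gamma", "sensitivity", "specificity")
  if (!is.data.frame(grid_results) || nrow(grid_results) == 0L ||
      !all(req %in% names(grid_results)))
    stop("grid_results must be a non-empty data frame with columns ",
         paste(req, collapse = ", "))
  g <- grid_results
  ok <- !is.na(g$sensitivity) & g$sensitivity >= target_sensitivity
  pool <- if (any(ok)) g[ok, , drop = FALSE] else g[!is.na(g$sensitivity), ,
                                                    drop = FALSE]
  if (nrow(pool) == 0L) stop("no grid cell has a defined sensitivity")
  ord <- order(if (any(ok)) rep(0, nrow(pool)) else -pool$sensitivity,
               -pool$specificity, pool$C, pool$gamma)
  best <- pool[ord[1L], ]
  structure(list(C = best$C, gamma = best$gamma,
                 achieved_sensitivity = best$sensitivity,
                 achieved_specificity = best$specificity,
                 met_target = any(ok)),
            class = "operating_point")
}

#' @export
print.operating_point <- function(x, ...) {
  cat(sprintf(
    "operating_point: C = %g, gamma = %g (sens %.3f, spec %.3f%s)\n",
    x$C, x$gamma, x$achieved_sensitivity, x$achieved_specificity,
    if (x$met_target) "" else "; target not reached, max-sensitivity fallback"))
  invisible(x)
}

#' Save / load a fitted model
#'
#' The model is stored as a JSON metadata file (method, classes, parameters,
#' feature dimension, optional path of the assignment CSV) next to the
#' classifier handle serialized in R's native format under the same stem.
#'
#' @param model an `ssl_model`.
#' @param path path of the JSON metadata file to write.
#' @param assignment_csv optional path to an assignment CSV already written
#'   with [write_assignment_csv()]; recorded by reference.
#' @return `path`, invisibly (`save_model`); the restored `ssl_model`
#'   (`load_model`).
#' @export
save_model <- function(model, path, assignment_csv = NULL) {
  stopifnot(inherits(model, "ssl_model"))
  handle <- paste0(sub("\\.json$", "", path), ".rds")
  saveRDS(model, handle)
  meta <- list(method = model$method, classes = model$classes,
               d = model$d, C = model$params$C, gamma = model$params$gamma,
               handle = basename(handle),
               assignment_csv = assignment_csv)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  meta <- jsonlite::read_json(path)
  model <- readRDS(file.path(dirname(path), meta$handle))
  stopifnot(inherits(model, "ssl_model"))
  model
}
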