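#' Construct a feature table
#'
#' A feature table is the shared substrate of all methods in the package: an
#' `n x d` numeric matrix of dimensionless features together with unique
#' instance identifiers and, optionally, group identifiers (for example the
#' patient a pathology patch was extracted from).  Group identifiers drive
#' grouped (patient-wise) cross-validation, where whole groups are held out
#' so that instances from one patient never span train and test.
#'
#' @param values numeric matrix or data frame with `n >= 1` rows and
#'   `d >= 1` columns; all entries must be finite.
#' @param instance_ids character vector of `n` unique identifiers.  Defaults
#'   to `"x1" ... "xn"`.
#' @param group_ids optional vector of length `n` naming the group (patient)
#'   of each instance.
#' @return An object of class `feature_table` with elements `values`
#'   (numeric matrix), `instance_ids` and `group_ids` (or `NULL`).
#' @examples
#' ft <- feature_table(matrix(rnorm(20), 10, 2), group_ids = rep(1:2, each = 5))
#' ft
#' @export
feature_table <- function(values, instance_ids = NULL, group_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("feature table needs at least one row and one column")
  if (!all(is.finite(values)))
    stop("all feature values must be finite")
  n <- nrow(values)
  if (is.null(instance_ids)) instance_ids <- paste0("x", seq_len(n))
  instance_ids <- as.character(instance_ids)
  if (length(instance_ids) != n) stop("instance_ids must have length n")
  if (anyDuplicated(instance_ids)) stop("instance_ids must be unique")
  if (!is.null(group_ids)) {
    group_ids <- as.character(group_ids)
    if (length(group_ids) != n) stop("group_ids must have length n")
  }
  dimnames(values) <- NULL
  structure(list(values = values, instance_ids = instance_ids,
                 group_ids = group_ids),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d instances x %d features", nrow(x$values),
              ncol(x$values)))
  if (!is.null(x$group_ids))
    cat(sprintf(", %d groups", length(unique(x$group_ids))))
  cat("\n")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Construct a partial label vector
#'
#' Holds the semi-supervised split: every instance carries either a class id
#' or the unlabeled sentinel `NA`.
#'
#' @param labels vector of class ids; `NA` (or, for character input, the
#'   empty string or `"?"`) marks an unlabeled instance.
#' @param classes ordered character vector of permitted class ids; defaults
#'   to the sorted distinct labeled values.
#' @return An object of class `partial_labels` with elements `labels`
#'   (character, `NA` = unlabeled) and `classes`.
#' @examples
#' partial_labels(c("c1", NA, "c2", NA))
#' @export
partial_labels <- function(labels, classes = NULL) {
  labels <- as.character(labels)
  labels[!is.na(labels) & labels %in% c("", "?")] <- NA_character_
  if (is.null(classes)) classes <- sort(unique(labels[!is.na(labels)]))
  classes <- as.character(classes)
  if (anyDuplicated(classes)) stop("classes must be unique")
  bad <- !is.na(labels) & !(labels %in% classes)
  if (any(bad))
    stop("labels outside the class alphabet: ",
         paste(unique(labels[bad]), collapse = ", "))
  structure(list(labels = labels, classes = classes),
            class = "partial_labels")
}

#' @export
print.partial_labels <- function(x, ...) {
  cat(sprintf("partial_labels: %d labeled / %d unlabeled, classes: %s\n",
              sum(!is.na(x$labels)), sum(is.na(x$labels)),
              paste(x$classes, collapse = ", ")))
  invisible(x)
}

labeled_indices <- function(labels) which(!is.na(labels$labels))
unlabeled_indices <- function(labels) which(is.na(labels$labels))

check_table_labels <- function(table, labels) {
  if (length(labels$labels) != nrow(table$values))
    stop("labels and feature table disagree on the number of instances")
  invisible(TRUE)
}

#' Read a feature table and partial labels from CSV
#'
#' Expects a header row with feature columns `f1 ... fd`, a `label` column
#' in which the empty string or `?` marks unlabeled instances, and optional
#' `instance_id` and `group` columns.
#'
#' @param path path to the CSV file.
#' @param classes optional class alphabet passed to [partial_labels()].
#' @return A list with elements `table` ([feature_table()]) and `labels`
#'   ([partial_labels()]).
#' @seealso [write_dataset_csv()], [write_assignment_csv()]
#' @export
read_dataset_csv <- function(path, classes = NULL) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "character", na.strings = NULL)
  feat_cols <- grep("^f[0-9]+$", names(df), value = TRUE)
  if (length(feat_cols) == 0L) stop("no feature columns f1...fd found")
  feat_cols <- feat_cols[order(as.integer(sub("^f", "", feat_cols)))]
  if (!"label" %in% names(df)) stop("missing 'label' column")
  values <- vapply(df[feat_cols], as.numeric, numeric(nrow(df)))
  values <- matrix(values, nrow = nrow(df),
                   dimnames = list(NULL, feat_cols))
  ids <- if ("instance_id" %in% names(df)) df$instance_id else NULL
  groups <- if ("group" %in% names(df)) df$group else NULL
  lab <- df$label
  lab[lab %in% c("", "?", "NA")] <- NA_character_
  list(table = feature_table(values, instance_ids = ids, group_ids = groups),
       labels = partial_labels(lab, classes = classes))
}

#' Write a feature table and labels to CSV
#'
#' Inverse of [read_dataset_csv()]: columns `instance_id`, `f1 ... fd`,
#' `label` (empty string for unlabeled) and, when present, `group`.
#'
#' @param table a [feature_table()].
#' @param labels a [partial_labels()] (or a plain character vector).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dataset_csv <- function(table, labels, path) {
  lab <- if (inherits(labels, "partial_labels")) labels$labels else
    as.character(labels)
  check_stopifnot <- length(lab) == nrow(table$values)
  if (!check_stopifnot) stop("labels length must match the table")
  d <- ncol(table$values)
  df <- data.frame(instance_id = table$instance_ids,
                   as.data.frame(table$values) |>
                     stats::setNames(paste0("f", seq_len(d))),
                   label = ifelse(is.na(lab), "", lab),
                   check.names = FALSE)
  if (!is.null(table$group_ids)) df$group <- table$group_ids
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Pairwise Euclidean distances between the rows of A and the rows of B.
# Uses the expansion ||a-b||^2 = ||a||^2 + ||b||^2 - 2 a.b with clamping at
# zero; exact distances are the contract, and at the problem sizes handled
# here the O(n m d) cost is negligible.
cross_dist <- function(A, B) {
  sq <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  sq[sq < 0] <- 0
  sqrt(sq)
}

# Per-feature zero-mean unit-variance standardization; constant features are
# left centred only (dividing by a zero SD would poison the distances).
standardize_features <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  sweep(sweep(x, 2, mu, "-"), 2, sdv, "/")
}
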