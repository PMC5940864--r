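#' Default neighbourhood size for core radii
#'
#' The heuristic neighbourhood size is one tenth of the number of points in
#' the data space, clamped to the feasible range `[1, n - 1]` (a point is
#' never its own neighbour, so at most `n - 1` neighbours exist).
#'
#' @param n_points total number of points (labeled + unlabeled); must be
#'   at least 2 so that a neighbourhood exists.
#' @return A positive integer `k`.
#' @examples
#' default_k(100)  # 10
#' default_k(5)    # 1
#' @export
default_k <- function(n_points) {
  n_points <- as.integer(n_points)
  if (length(n_points) != 1L || is.na(n_points) || n_points < 2L)
    stop("n_points must be a single integer >= 2")
  min(max(1L, n_points %/% 10L), n_points - 1L)
}

#' Core radii of the labeled seeds
#'
#' For every labeled seed the core radius `eps` is the Euclidean distance to
#' its k-th nearest *other* point over the pooled labeled-plus-unlabeled
#' table.  Core radii are small in dense regions and large in sparse ones;
#' they are the density term of the seeded distance.
#'
#' @param table a [feature_table()].
#' @param labels a [partial_labels()] for the same table.
#' @param k neighbourhood size, `1 <= k <= n - 1`.
#' @return An object of class `density_profile`: list with `k`, `eps`
#'   (one radius per seed) and `labeled_index` (seed positions in the
#'   table).
#' @examples
#' ft <- feature_table(matrix(c(0, 1, 3, 7), ncol = 1))
#' pl <- partial_labels(c("a", NA, NA, NA))
#' compute_core_radii(ft, pl, k = 2)$eps  # 3
#' @export
compute_core_radii <- function(table, labels, k) {
  check_table_labels(table, labels)
  n <- nrow(table$values)
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L || k >= n)
    stop("k must satisfy 1 <= k <= n - 1")
  seeds <- labeled_indices(labels)
  if (length(seeds) == 0L) stop("at least one labeled instance is required")
  D <- cross_dist(table$values[seeds, , drop = FALSE], table$values)
  # a point is not its own neighbour: mask the seed itself by index, so
  # duplicate points at distance zero still count as neighbours
  D[cbind(seq_along(seeds), seeds)] <- Inf
  eps <- apply(D, 1L, function(row) sort(row, partial = k)[k])
  structure(list(k = k, eps = as.numeric(eps), labeled_index = seeds),
            class = "density_profile")
}

#' @export
print.density_profile <- function(x, ...) {
  cat(sprintf("density_profile: %d seeds, k = %d, eps in [%.4g, %.4g]\n",
              length(x$eps), x$k, min(x$eps), max(x$eps)))
  invisible(x)
}

#' Seeded distance matrix between labeled seeds and unlabeled points
#'
#' The seeded distance from seed `i` to unlabeled point `j` is
#' `d[i, j] = max(eps[i], ||p_i - q_j||)`: the Euclidean distance floored at
#' the seed's core radius, so that seeds in sparse regions reach out less
#' competitively than seeds in dense ones.
#'
#' @param table,labels as in [compute_core_radii()].
#' @param profile a `density_profile` computed on the same table and
#'   labeled set.
#' @return An object of class `seeded_distance_matrix`: list with the
#'   `l x u` matrix `d`, `labeled_index`, `unlabeled_index` and `eps`.
#' @export
seeded_distances <- function(table, labels, profile) {
  check_table_labels(table, labels)
  if (!inherits(profile, "density_profile"))
    stop("profile must be a density_profile")
  seeds <- labeled_indices(labels)
  if (!identical(as.integer(profile$labeled_index), as.integer(seeds)))
    stop("profile was computed on a different labeled set")
  unl <- unlabeled_indices(labels)
  E <- cross_dist(table$values[seeds, , drop = FALSE],
                  table$values[unl, , drop = FALSE])
  # eps recycles down each column (row i = seed i)
  d <- matrix(pmax(profile$eps, as.vector(E)), nrow(E), ncol(E))
  structure(list(d = d, labeled_index = seeds, unlabeled_index = unl,
                 eps = profile$eps),
            class = "seeded_distance_matrix")
}

#' Assign unlabeled points to the closest seed under the seeded distance
#'
#' Every unlabeled point receives the class of the seed minimising the
#' seeded distance.  When the minimum is attained (within the relative
#' tolerance `tie_tol`) by seeds of two or more distinct classes, the point
#' is a tie and receives `tie_fallback_class` — for binary tasks this is the
#' negative class, matching the convention that an equidistant point is
#' assigned a negative label.  Ties between same-class seeds are not ties:
#' the class is unambiguous and the lowest seed index wins.
#'
#' @param distances a `seeded_distance_matrix`.
#' @param labels the [partial_labels()] the matrix was built from.
#' @param tie_fallback_class class id used for tie points; must be in the
#'   class alphabet.  There is no default: for more than two classes no
#'   canonical fallback exists, so the caller must always choose.
#' @param tie_tol relative tie tolerance: distances `d1`, `d2` are tied when
#'   `|d1 - d2| <= tie_tol * max(d1, d2, 1)`.
#' @return An object of class `s3db_assignment`: list with full-length
#'   `labels`, `provenance` (`given`, `inferred` or `tie`), `assigned_seed`
#'   (table index of the winning seed for inferred points, `NA` otherwise)
#'   and `classes`.
#' @export
assign_labels <- function(distances, labels, tie_fallback_class,
                          tie_tol = 1e-12) {
  if (!inherits(distances, "seeded_distance_matrix"))
    stop("distances must be a seeded_distance_matrix")
  if (!identical(as.integer(distances$labeled_index),
                 as.integer(labeled_indices(labels))) ||
      !identical(as.integer(distances$unlabeled_index),
                 as.integer(unlabeled_indices(labels))))
    stop("distances were computed for a different labeled/unlabeled split")
  if (missing(tie_fallback_class) || length(tie_fallback_class) != 1L ||
      !(tie_fallback_class %in% labels$classes))
    stop("tie_fallback_class must be a single id from the class alphabet")

  n <- length(labels$labels)
  out <- labels$labels
  provenance <- ifelse(is.na(out), NA_character_, "given")
  assigned_seed <- rep(NA_integer_, n)
  seeds <- distances$labeled_index
  seed_class <- labels$labels[seeds]

  for (jj in seq_along(distances$unlabeled_index)) {
    j <- distances$unlabeled_index[jj]
    dj <- distances$d[, jj]
    dmin <- min(dj)
    tied <- which(abs(dj - dmin) <= tie_tol * pmax(pmax(dj, dmin), 1))
    cls <- unique(seed_class[tied])
    if (length(cls) > 1L) {
      out[j] <- tie_fallback_class
      provenance[j] <- "tie"
    } else {
      out[j] <- cls
      provenance[j] <- "inferred"
      assigned_seed[j] <- seeds[min(tied)]
    }
  }
  structure(list(labels = out, provenance = provenance,
                 assigned_seed = assigned_seed, classes = labels$classes),
            class = "s3db_assignment")
}

#' Seeded density-based cluster-then-label assignment
#'
#' Composes the three steps of the semi-supervised seeded density-based
#' clustering method: core radii of the labeled seeds over the pooled data
#' ([compute_core_radii()]), the seeded max-distance matrix
#' ([seeded_distances()]), and nearest-seed assignment with the negative-
#' label tie rule ([assign_labels()]).  The result labels every point and is
#' fully deterministic given its inputs.
#'
#' @inheritParams compute_core_radii
#' @inheritParams assign_labels
#' @param k neighbourhood size, or `"auto"` for [default_k()] (one tenth of
#'   the number of points).
#' @param standardize if `TRUE`, features are standardized to zero mean and
#'   unit variance before any distance is computed.  Default `FALSE`:
#'   distances are taken on the features as given.
#' @return An `s3db_assignment` (see [assign_labels()]); the resolved `k` is
#'   attached as element `k`.
#' @examples
#' ft <- feature_table(matrix(c(0, 3, 1.4), ncol = 1))
#' pl <- partial_labels(c("A", "B", NA))
#' s3db(ft, pl, k = 1, tie_fallback_class = "B")$labels
#' @export
s3db <- function(table, labels, k = "auto", tie_fallback_class,
                 standardize = FALSE, tie_tol = 1e-12) {
  check_table_labels(table, labels)
  if (standardize)
    table <- feature_table(standardize_features(table$values),
                           instance_ids = table$instance_ids,
                           group_ids = table$group_ids)
  n <- nrow(table$values)
  if (identical(k, "auto")) k <- default_k(n)
  profile <- compute_core_radii(table, labels, k)
  dmat <- seeded_distances(table, labels, profile)
  res <- assign_labels(dmat, labels, tie_fallback_class, tie_tol = tie_tol)
  res$k <- profile$k
  res
}

#' @export
print.s3db_assignment <- function(x, ...) {
  tab <- table(factor(x$provenance, levels = c("given", "inferred", "tie")))
  cat(sprintf("s3db_assignment: %d given, %d inferred, %d tie\n",
              tab[["given"]], tab[["inferred"]], tab[["tie"]]))
  invisible(x)
}

#' Write an assignment result to CSV
#'
#' Columns: `instance_id`, `label`, `provenance`, `assigned_seed` (the
#' instance id of the winning seed, empty for given and tie rows).
#'
#' @param assignment an `s3db_assignment`.
#' @param table the [feature_table()] it was computed on.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_assignment_csv <- function(assignment, table, path) {
  seed_id <- ifelse(is.na(assignment$assigned_seed), "",
                    table$instance_ids[assignment$assigned_seed])
  df <- data.frame(instance_id = table$instance_ids,
                   label = assignment$labels,
                   provenance = assignment$provenance,
                   assigned_seed = seed_id)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
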