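#' Semi-supervised fuzzy c-means objective
#'
#' The objective sums, over classes and points, membership-weighted squared
#' Euclidean distances to the class prototypes: a crisp, fixed term for the
#' labeled points plus a fuzzy term for the unlabeled points.  The squared
#' norm is used throughout so that the alternating membership and prototype
#' updates are exact coordinate minimisers of this objective.
#'
#' @param V `c x d` prototype matrix.
#' @param U `c x l` crisp labeled membership matrix (columns sum to 1).
#' @param U_star `c x u` unlabeled membership matrix (columns sum to 1).
#' @param X `l x d` labeled points; `X_star` `u x d` unlabeled points.
#'   Either block may have zero rows.
#' @param X_star see `X`.
#' @param m fuzziness degree, `> 1` (default 2).
#' @return Non-negative scalar objective value.
#' @export
ssfcm_objective <- function(V, U, U_star, X, X_star, m = 2) {
  V <- as.matrix(V)
  stopifnot(m > 1)
  obj <- 0
  if (length(X) && nrow(X) > 0L)
    obj <- obj + sum((U^m) * cross_dist(V, as.matrix(X))^2)
  if (length(X_star) && nrow(X_star) > 0L)
    obj <- obj + sum((U_star^m) * cross_dist(V, as.matrix(X_star))^2)
  obj
}

#' Fuzzy membership update for unlabeled points
#'
#' Standard fuzzy c-means membership minimiser for fixed prototypes:
#' `u*_ij = 1 / sum_c (d_ij / d_cj)^(2/(m-1))`.  A point coinciding with one
#' or more prototypes puts all its mass, split equally, on the coinciding
#' prototypes.
#'
#' @param X_star `u x d` unlabeled points.
#' @param V `c x d` prototypes.
#' @param m fuzziness degree `> 1`.
#' @return `c x u` membership matrix whose columns sum to 1.
#' @export
ssfcm_memberships <- function(X_star, V, m = 2) {
  stopifnot(m > 1)
  V <- as.matrix(V); X_star <- as.matrix(X_star)
  D <- cross_dist(V, X_star)                  # c x u
  U <- matrix(0, nrow(V), ncol(D))
  for (j in seq_len(ncol(D))) {
    dj <- D[, j]
    zero <- dj == 0
    if (any(zero)) {
      U[zero, j] <- 1 / sum(zero)
    } else {
      w <- dj^(-2 / (m - 1))
      U[, j] <- w / sum(w)
    }
  }
  U
}

#' Prototype update
#'
#' Membership-weighted mean of labeled and unlabeled points:
#' `v_i = (sum_j u_ij^m x_j + sum_j u*_ij^m x*_j) / (sum u_ij^m + sum u*_ij^m)`.
#'
#' @param X,U labeled points (`l x d`) and their `c x l` memberships.
#' @param X_star,U_star unlabeled points (`u x d`) and their `c x u`
#'   memberships.
#' @param m fuzziness degree `> 1`.
#' @return `c x d` prototype matrix.
#' @export
ssfcm_prototypes <- function(X, U, X_star, U_star, m = 2) {
  stopifnot(m > 1)
  c_num <- if (length(U)) nrow(U) else nrow(U_star)
  d <- if (length(X) && nrow(as.matrix(X)) > 0L) ncol(as.matrix(X)) else
    ncol(as.matrix(X_star))
  num <- matrix(0, c_num, d)
  den <- numeric(c_num)
  if (length(X) && nrow(as.matrix(X)) > 0L) {
    W <- U^m
    num <- num + W %*% as.matrix(X)
    den <- den + rowSums(W)
  }
  if (length(X_star) && nrow(as.matrix(X_star)) > 0L) {
    W <- U_star^m
    num <- num + W %*% as.matrix(X_star)
    den <- den + rowSums(W)
  }
  if (any(den == 0))
    stop("degenerate class: zero total membership mass")
  num / den
}

#' Semi-supervised fuzzy c-means clustering
#'
#' Baseline cluster-then-label method: fuzzy c-means in which the labeled
#' points keep crisp, fixed memberships at their given class while the
#' unlabeled memberships and the prototypes are alternately re-estimated
#' until the objective stabilises.  Unlabeled points are then hard-labeled
#' by maximal membership.  The number of clusters equals the number of
#' distinct labeled classes, prototypes are initialised at the labeled
#' class means, and no randomness is involved, so the result is
#' deterministic.
#'
#' Because the prototypes are single points per class, the method implicitly
#' assumes roughly Gaussian, convex clusters; it degrades on non-convex
#' shapes such as crescent pairs, which is exactly the regime the seeded
#' density-based method is designed to survive.
#'
#' @param table a [feature_table()].
#' @param labels a [partial_labels()] with at least one labeled point in
#'   every class.
#' @param m fuzziness degree `> 1`; default 2.
#' @param max_iter maximum number of update rounds; default 1000.
#' @param tol relative objective-change convergence tolerance; default 1e-6.
#' @return A list of class `ssfcm_fit`:
#'   \describe{
#'     \item{assignment}{an `s3db_assignment`-style result (`labels`,
#'       `provenance` in `given`/`inferred`, `classes`).}
#'     \item{state}{list with prototypes `V`, memberships `U` and `U_star`,
#'       `m`, and the non-increasing `objective_trace`.}
#'     \item{iterations}{rounds performed.}
#'   }
#' @examples
#' ft <- feature_table(matrix(c(0, 0.2, 10, 10.2, 0.1, 9.9), ncol = 1))
#' pl <- partial_labels(c("lo", "lo", "hi", "hi", NA, NA))
#' run_ssfcm(ft, pl)$assignment$labels
#' @export
run_ssfcm <- function(table, labels, m = 2, max_iter = 1000, tol = 1e-6) {
  check_table_labels(table, labels)
  stopifnot(m > 1, max_iter >= 1)
  lab_idx <- labeled_indices(labels)
  unl_idx <- unlabeled_indices(labels)
  classes <- labels$classes
  present <- classes %in% labels$labels[lab_idx]
  if (!all(present))
    stop("every class needs at least one labeled point; missing: ",
         paste(classes[!present], collapse = ", "))
  X <- table$values[lab_idx, , drop = FALSE]
  X_star <- table$values[unl_idx, , drop = FALSE]
  y <- labels$labels[lab_idx]
  c_num <- length(classes)

  # crisp fixed labeled memberships; prototypes start at class means
  U <- matrix(0, c_num, length(lab_idx))
  U[cbind(match(y, classes), seq_along(y))] <- 1
  V <- ssfcm_prototypes(X, U, NULL, NULL, m)

  U_star <- matrix(0, c_num, length(unl_idx))
  trace <- numeric(0)
  prev <- Inf
  iters <- 0L
  repeat {
    iters <- iters + 1L
    if (length(unl_idx)) U_star <- ssfcm_memberships(X_star, V, m)
    V <- ssfcm_prototypes(X, U, X_star, U_star, m)
    obj <- ssfcm_objective(V, U, U_star, X, X_star, m)
    trace <- c(trace, obj)
    if (is.finite(prev) && abs(prev - obj) <= tol * max(prev, 1e-12)) break
    if (iters >= max_iter) break
    prev <- obj
  }

  out <- labels$labels
  provenance <- ifelse(is.na(out), "inferred", "given")
  if (length(unl_idx)) {
    hard <- apply(U_star, 2L, which.max)  # ties: lowest class index
    out[unl_idx] <- classes[hard]
  }
  assignment <- structure(list(labels = out, provenance = provenance,
                               assigned_seed = rep(NA_integer_, length(out)),
                               classes = classes),
                          class = "s3db_assignment")
  structure(list(assignment = assignment,
                 state = list(V = V, U = U, U_star = U_star, m = m,
                              objective_trace = trace),
                 iterations = iters),
            class = "ssfcm_fit")
}

#' @export
print.ssfcm_fit <- function(x, ...) {
  cat(sprintf(
    "ssfcm_fit: %d classes, %d iterations, final objective %.6g\n",
    nrow(x$state$V), x$iterations,
    x$state$objective_trace[length(x$state$objective_trace)]))
  invisible(x)
}

#' Write a fuzzy membership matrix to CSV
#'
#' Long format: one row per (instance, class) pair with the membership
#' value; labeled instances carry their crisp memberships.
#'
#' @param fit an `ssfcm_fit`.
#' @param table the [feature_table()] it was computed on.
#' @param labels the [partial_labels()] used for the fit.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_membership_csv <- function(fit, table, labels, path) {
  classes <- fit$assignment$classes
  M <- matrix(0, length(classes), nrow(table$values))
  M[, labeled_indices(labels)] <- fit$state$U
  if (length(unlabeled_indices(labels)))
    M[, unlabeled_indices(labels)] <- fit$state$U_star
  df <- data.frame(
    instance_id = rep(table$instance_ids, each = length(classes)),
    class = rep(classes, times = nrow(table$values)),
    membership = as.vector(M))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
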