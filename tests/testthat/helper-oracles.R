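# Independent reference implementations used as oracles.  These are written
# in the most literal way possible (explicit loops, full sorts) and share no
# code with the package internals they check.

# Naive seeded density-based cluster-then-label: O(l * u * n) with explicit
# per-point distance sorts.
oracle_s3db <- function(X, labels, classes, k, tie_fallback, tie_tol = 1e-12) {
  n <- nrow(X)
  euc <- function(i, j) sqrt(sum((X[i, ] - X[j, ])^2))
  seeds <- which(!is.na(labels))
  eps <- numeric(length(seeds))
  for (si in seq_along(seeds)) {
    i <- seeds[si]
    d_others <- sort(sapply(setdiff(seq_len(n), i), euc, i = i))
    eps[si] <- d_others[k]
  }
  out <- labels
  provenance <- ifelse(is.na(labels), NA_character_, "given")
  assigned <- rep(NA_integer_, n)
  for (j in which(is.na(labels))) {
    dj <- sapply(seq_along(seeds), function(si) max(eps[si], euc(seeds[si], j)))
    dmin <- min(dj)
    tied <- which(abs(dj - dmin) <= tie_tol * pmax(pmax(dj, dmin), 1))
    cls <- unique(labels[seeds[tied]])
    if (length(cls) > 1L) {
      out[j] <- tie_fallback
      provenance[j] <- "tie"
    } else {
      out[j] <- cls
      provenance[j] <- "inferred"
      assigned[j] <- seeds[min(tied)]
    }
  }
  list(labels = out, provenance = provenance, assigned_seed = assigned,
       eps = eps)
}

# All-pairs AUC with ties counted one half.
oracle_auc <- function(truth, scores, positive) {
  pos <- which(truth == positive)
  neg <- which(truth != positive)
  total <- 0
  for (i in pos) for (j in neg)
    total <- total + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  total / (length(pos) * length(neg))
}

# Exact two-sided signed-rank p-value by a literal loop over all 2^n sign
# assignments of the observed magnitudes (zero differences already removed).
oracle_wilcoxon_p <- function(a, b) {
  d <- (a - b)[a != b]
  r <- rank(abs(d))
  n <- length(d)
  w_obs <- min(sum(r[d > 0]), sum(r[d < 0]))
  s_tot <- sum(r)
  hits <- 0L
  for (mask in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(mask))[seq_len(n)]
    wp <- sum(r[bits == 1L])
    if (min(wp, s_tot - wp) <= w_obs) hits <- hits + 1L
  }
  hits / 2^n
}

# Random semi-supervised instance for property tests.
random_instance <- function(n_max = 200, d_max = 10, classes_max = 4) {
  n <- sample(10:n_max, 1)
  d <- sample(1:d_max, 1)
  n_classes <- sample(2:classes_max, 1)
  X <- matrix(stats::rnorm(n * d), n, d)
  classes <- paste0("k", seq_len(n_classes))
  lab_pool <- n_classes:max(n_classes, n %/% 3)
  n_lab <- lab_pool[sample.int(length(lab_pool), 1)]
  lab_idx <- sample(n, n_lab)
  labels <- rep(NA_character_, n)
  # guarantee every class at least once among the labeled points
  labels[lab_idx] <- c(classes,
                       sample(classes, n_lab - n_classes, replace = TRUE))
  k <- sample(seq_len(min(n - 1, 25)), 1)
  list(X = X, labels = labels, classes = classes, k = k,
       tie_fallback = classes[1])
}
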