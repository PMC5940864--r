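test_that("default_k applies the one-tenth rule with clamping", {
  expect_identical(default_k(100), 10L)
  expect_identical(default_k(1000), 100L)
  expect_identical(default_k(5), 1L)     # floor(0.5) clamped up to 1
  expect_identical(default_k(2), 1L)
  expect_identical(default_k(10), 1L)    # never exceeds n - 1
  expect_error(default_k(1), "integer >= 2")
})

test_that("core radii are kth-other-point distances, excluding self", {
  ft <- feature_table(matrix(c(0, 1, 3, 7), ncol = 1))
  pl <- partial_labels(c("a", NA, NA, NA))
  expect_equal(compute_core_radii(ft, pl, k = 1)$eps, 1.0)
  expect_equal(compute_core_radii(ft, pl, k = 2)$eps, 3.0)
  expect_equal(compute_core_radii(ft, pl, k = 3)$eps, 7.0)
  expect_error(compute_core_radii(ft, pl, k = 4), "k must satisfy")
})

test_that("core radii are non-decreasing in k and handle duplicates", {
  set.seed(11)
  X <- matrix(rnorm(60), 30, 2)
  X[2, ] <- X[1, ]                       # duplicate of a labeled seed
  ft <- feature_table(X)
  pl <- partial_labels(c("a", rep(NA, 28), "b"))
  eps_by_k <- sapply(1:29, function(k) compute_core_radii(ft, pl, k)$eps[1])
  expect_true(all(diff(eps_by_k) >= 0))
  expect_equal(eps_by_k[1], 0)           # the duplicate counts as a neighbor
})

test_that("seeded distances floor Euclidean distances at the core radius", {
  ft <- feature_table(matrix(c(0, 10, 1, 5, 3), ncol = 1))
  pl <- partial_labels(c("a", "b", NA, NA, NA))
  prof <- compute_core_radii(ft, pl, k = 2)
  dm <- seeded_distances(ft, pl, prof)
  expect_equal(dim(dm$d), c(2L, 3L))
  E <- abs(outer(c(0, 10), c(1, 5, 3), "-"))
  expect_equal(dm$d, pmax(matrix(prof$eps, 2, 3), E))
  expect_true(all(dm$d >= prof$eps))
  expect_true(all(dm$d >= E))
  # mismatched profile is rejected
  pl2 <- partial_labels(c("a", "b", "a", NA, NA))
  expect_error(seeded_distances(ft, pl2, prof), "different labeled set")
})

test_that("assignment reproduces the two constructed core-radius scenarios", {
  # scenario (a): q inside both radii, Euclidean-closer to p1, but
  # eps2 < eps1, so the seeded distance hands q to p2
  ft <- feature_table(matrix(c(0, 3, 1.4), ncol = 1))
  pl <- partial_labels(c("A", "B", NA))
  prof <- structure(list(k = 1L, eps = c(4, 2), labeled_index = c(1L, 2L)),
                    class = "density_profile")
  a <- assign_labels(seeded_distances(ft, pl, prof), pl,
                     tie_fallback_class = "B")
  expect_identical(a$labels[3], "B")
  expect_identical(a$provenance[3], "inferred")
  expect_identical(a$assigned_seed[3], 2L)

  # scenario (b): q inside eps1 only, but eps1 > ||p2 - q||
  ft <- feature_table(matrix(c(0, 5, 2), ncol = 1))
  pl <- partial_labels(c("A", "B", NA))
  prof <- structure(list(k = 1L, eps = c(6, 1), labeled_index = c(1L, 2L)),
                    class = "density_profile")
  a <- assign_labels(seeded_distances(ft, pl, prof), pl,
                     tie_fallback_class = "B")
  expect_identical(a$labels[3], "B")
})

test_that("equidistant points between classes take the fallback label", {
  ft <- feature_table(matrix(c(-1, 1, 0), ncol = 1))
  pl <- partial_labels(c("pos", "neg", NA))
  prof <- structure(list(k = 1L, eps = c(2, 2), labeled_index = c(1L, 2L)),
                    class = "density_profile")
  a <- assign_labels(seeded_distances(ft, pl, prof), pl,
                     tie_fallback_class = "neg")
  expect_identical(a$labels[3], "neg")
  expect_identical(a$provenance[3], "tie")
  expect_true(is.na(a$assigned_seed[3]))
  # fallback class must come from the alphabet, explicitly
  expect_error(assign_labels(seeded_distances(ft, pl, prof), pl,
                             tie_fallback_class = "zzz"), "class alphabet")
})

test_that("same-class minimum ties are not ties; lowest seed index wins", {
  ft <- feature_table(matrix(c(-1, 1, 0, 9), ncol = 1))
  pl <- partial_labels(c("A", "A", NA, "B"), classes = c("A", "B"))
  prof <- structure(list(k = 1L, eps = c(0.1, 0.1, 0.1),
                         labeled_index = c(1L, 2L, 4L)),
                    class = "density_profile")
  a <- assign_labels(seeded_distances(ft, pl, prof), pl,
                     tie_fallback_class = "B")
  expect_identical(a$labels[3], "A")
  expect_identical(a$provenance[3], "inferred")
  expect_identical(a$assigned_seed[3], 1L)
})

test_that("composed method matches the brute-force reference on random data", {
  set.seed(101)
  for (rep in 1:25) {
    inst <- random_instance(n_max = 80, d_max = 6)
    ft <- feature_table(inst$X)
    pl <- partial_labels(inst$labels, classes = inst$classes)
    got <- s3db(ft, pl, k = inst$k, tie_fallback_class = inst$tie_fallback)
    ref <- oracle_s3db(inst$X, inst$labels, inst$classes, inst$k,
                       inst$tie_fallback)
    expect_identical(got$labels, ref$labels)
    expect_identical(got$provenance, ref$provenance)
    expect_identical(got$assigned_seed, ref$assigned_seed)
  }
})

test_that("assignments are invariant under translation and rotation", {
  set.seed(7)
  inst <- random_instance(n_max = 60, d_max = 5)
  d <- ncol(inst$X)
  ft <- feature_table(inst$X)
  pl <- partial_labels(inst$labels, classes = inst$classes)
  base <- s3db(ft, pl, k = inst$k, tie_fallback_class = inst$tie_fallback)
  # random rotation via QR of a Gaussian matrix, plus a translation
  Q <- qr.Q(qr(matrix(rnorm(d * d), d, d)))
  Xt <- sweep(inst$X %*% Q, 2, runif(d, -5, 5), "+")
  moved <- s3db(feature_table(Xt), pl, k = inst$k,
                tie_fallback_class = inst$tie_fallback)
  expect_identical(moved$labels, base$labels)
  expect_identical(moved$provenance, base$provenance)
})

test_that("when no core radius binds, assignment is 1-nearest-labeled-neighbor", {
  set.seed(23)
  # tight clumps of k+1 seeds make every eps a tiny within-clump distance,
  # while all unlabeled points sit well outside any clump: no radius binds
  k <- 5
  centers <- matrix(c(0, 0, 100, 0, 0, 100), 3, 2, byrow = TRUE)
  seeds <- centers[rep(1:3, each = k + 1), ] +
    matrix(rnorm(3 * (k + 1) * 2, sd = 0.005), 3 * (k + 1), 2)
  theta <- runif(15, 0, 2 * pi)
  sat <- centers[rep(1:3, each = 5), ] +
    runif(15, 2, 20) * cbind(cos(theta), sin(theta))
  X <- rbind(seeds, sat)
  n_seed <- nrow(seeds)
  labels <- c(rep(c("a", "b", "c"), each = k + 1), rep(NA, 15))
  ft <- feature_table(X)
  pl <- partial_labels(labels)
  prof <- compute_core_radii(ft, pl, k = k)
  E <- ssclust:::cross_dist(seeds, sat)
  expect_true(all(prof$eps <= apply(E, 1, min)))   # construction holds
  a <- s3db(ft, pl, k = k, tie_fallback_class = "a")
  nn <- labels[apply(E, 2, which.min)]
  expect_identical(a$labels[-seq_len(n_seed)], nn)
})

test_that("zero unlabeled points and label renaming behave as identities", {
  set.seed(3)
  X <- matrix(rnorm(20), 10, 2)
  ft <- feature_table(X)
  full <- partial_labels(rep(c("a", "b"), 5))
  a <- s3db(ft, full, k = 2, tie_fallback_class = "a")
  expect_identical(a$labels, full$labels)
  expect_true(all(a$provenance == "given"))

  part <- partial_labels(c("a", "b", rep(NA, 8)))
  a1 <- s3db(ft, part, k = 2, tie_fallback_class = "a")
  renamed <- partial_labels(c("X", "Y", rep(NA, 8)), classes = c("X", "Y"))
  a2 <- s3db(ft, renamed, k = 2, tie_fallback_class = "X")
  expect_identical(a2$labels, unname(c(a = "X", b = "Y")[a1$labels]))
})

test_that("auto k resolves to the one-tenth default", {
  set.seed(5)
  ft <- feature_table(matrix(rnorm(100), 50, 2))
  pl <- partial_labels(c("a", "b", rep(NA, 48)))
  a <- s3db(ft, pl, k = "auto", tie_fallback_class = "a")
  expect_identical(a$k, 5L)
  expect_identical(a$labels,
                   s3db(ft, pl, k = 5, tie_fallback_class = "a")$labels)
})

test_that("dataset and assignment CSV round-trips preserve content", {
  set.seed(9)
  ds <- generate_dataset(synthetic_config(n_per_class = 20, n_groups = 2,
                                          seed = 4))
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset_csv(ds$table, ds$labels, path)
  back <- read_dataset_csv(path)
  expect_equal(back$table$values, ds$table$values, tolerance = 1e-12)
  expect_identical(back$table$group_ids, ds$table$group_ids)
  expect_identical(back$labels$labels, ds$labels$labels)

  a <- s3db(ds$table, ds$labels, tie_fallback_class = "c1")
  apath <- withr::local_tempfile(fileext = ".csv")
  write_assignment_csv(a, ds$table, apath)
  adf <- read.csv(apath, colClasses = "character")
  expect_identical(adf$label, a$labels)
  expect_identical(adf$provenance, a$provenance)
})
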