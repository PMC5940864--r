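Package: ssclust
Title: Semi-Supervised Seeded Density-Based Clustering and
    Cluster-then-Label Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for semi-supervised learning on tabular feature data by
    the cluster-then-label strategy.  The core method is seeded
    density-based clustering: every labeled seed receives a core radius
    (the distance to its k-th nearest neighbour over the pooled
    labeled and unlabeled data), unlabeled points are assigned to the
    seed minimising the density-aware seeded distance
    max(core radius, Euclidean distance), and the augmented labels train
    a kernel support-vector classifier.  Also included: a semi-supervised
    fuzzy c-means baseline with crisp labeled memberships, the Fisher
    Discriminant Ratio as a cluster-separability diagnostic, synthetic
    generators (Gaussian blobs with unequal densities, crescent pairs,
    overlapping classes) with patient-like group structure, grouped
    (patient-wise) cross-validation with sensitivity-constrained
    operating-point selection, and paired Wilcoxon significance testing
    with Bonferroni adjustment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
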