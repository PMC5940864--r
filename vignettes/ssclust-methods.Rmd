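---
title: "Seeded density-based cluster-then-label: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seeded density-based cluster-then-label: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssclust)
```

## The problem

In many biomedical imaging studies — breast pathology patch triaging is the
motivating case — expert labels are expensive, so a feature table of `n`
instances has only a small labeled subset while thousands of unlabeled
instances from the same patients sit idle.  Semi-supervised learning (SSL)
tries to exploit the unlabeled points.  Its working premises are the
*cluster assumption* (points of one class form high-density groups
separated by low-density regions) and the *smoothness assumption* (nearby
points likely share a label).  When those hold, inferring labels from
cluster structure and then training a supervised classifier on the
augmented labels — the *cluster-then-label* strategy — can beat training on
the labeled subset alone.  When they fail, SSL can actively hurt; this
package therefore ships the separability diagnostic and the controlled
generators needed to tell the regimes apart.

## Seeded density-based clustering (S³DB)

The core method assigns every unlabeled point to a labeled *seed* using a
density-aware dissimilarity.  For each labeled seed $p_i$, the *core
radius* $\varepsilon_i$ is the Euclidean distance from $p_i$ to its $k$-th
nearest other point, computed over the pooled labeled-plus-unlabeled
table: small in dense regions, large in sparse ones.  The *seeded
distance* from seed $i$ to unlabeled point $q_j$ is

$$d_{ij} = \max\left(\varepsilon_i,\; \lVert p_i - q_j \rVert_2\right),$$

and $q_j$ takes the class of the seed minimising $d_{ij}$.  Flooring the
distance at the core radius means a seed in a sparse region competes with
an inflated reach: an unlabeled point that is Euclidean-closer to a sparse
seed can still be captured by a dense one, which is exactly the behaviour
wanted when classes differ in density.  If the minimum is attained by
seeds of two or more distinct classes, the point is *equidistant* and
receives a configurable fallback class — the negative class in the binary
screening setting, the conservative choice when a triaging mistake on a
positive is costlier.  No distributional assumption is made about cluster
shape, so the method survives non-convex clusters (crescents) that defeat
prototype-based clustering.

### Parameters and conventions

* **`k`** (neighbourhood size): the minimum number of neighbours that
  could form a cluster.  The default is one tenth of the number of points
  in the data space, a heuristic that is stable once `k` is reasonably
  large; it is clamped to `[1, n-1]` because a point is not its own
  neighbour (otherwise `k = 1` would always give
  $\varepsilon = 0$).  Floor rounding is used.
* **Distance**: Euclidean on the features as given.  An optional
  per-feature standardization flag (`standardize = TRUE`, default off) is
  exposed for tables whose features live on wildly different scales; it is
  off by default because distances on engineered feature vectors are
  usually meant as-is.
* **Tie tolerance** $\tau$: two floating-point distances are tied when
  $|d_1 - d_2| \le \tau \max(d_1, d_2, 1)$ with $\tau = 10^{-12}$.  Exact
  ties are measure-zero for continuous features, but a documented
  tolerance makes the tie rule reproducible across platforms.
* **Ties within one class** are not ties: the class is unambiguous and the
  lowest seed index wins, keeping the assignment deterministic.
* **Fallback class**: for more than two classes no canonical "negative"
  exists, so `tie_fallback_class` must always be supplied explicitly.
* **Duplicates**: duplicate points are legal; $\varepsilon = 0$ can occur
  only when at least `k` duplicates of a seed exist, in which case the max
  degrades gracefully to the plain Euclidean distance.
* Core radii are always computed over the full table passed in; if an
  extra unlabeled pool is to participate, merge it before calling.

The implementation vectorises the distance computations but is contracted
to match, label-for-label, a naive reference that sorts all pairwise
distances; the test suite enforces this on hundreds of random instances.

## The ssFCM baseline

Semi-supervised fuzzy c-means minimises

$$\rho_m = \sum_{i=1}^{c}\sum_{j=1}^{l} u_{ij}^m \lVert x_j - v_i
\rVert^2 + \sum_{i=1}^{c}\sum_{j=1}^{u} u_{ij}^{*m} \lVert x_j^* - v_i
\rVert^2$$

over prototypes $V$ and unlabeled memberships $U^*$, with the labeled
memberships $U$ held crisp and fixed at the given labels.  Design choices,
each isolated behind one function:

* **Squared norm.**  The objective is stated here with the squared
  Euclidean norm, the standard fuzzy-c-means convention for which the
  closed-form membership and prototype updates are exact coordinate
  minimisers; with an unsquared norm those updates would only be
  approximate.  (Formulations that print an unsquared norm exist; the
  squared convention is the one under which the alternating scheme
  provably descends, which the tests assert.)
* **Fuzziness** `m = 2`, the conventional default.
* **Initialisation** at the labeled class means — deterministic, no RNG,
  so repeated runs agree bit for bit.
* **Convergence**: relative objective change below `1e-6`, capped at 1000
  rounds.
* `c` equals the number of distinct labeled classes.

Unlabeled points are hard-labeled by maximal membership.  Because each
class is summarised by a single prototype, the method implicitly assumes
convex, roughly Gaussian clusters; the crescent generator exists to
exercise precisely that failure mode, and the suite checks that the seeded
density method outperforms it there.

## Composition with the kernel classifier

The max-margin classifier is a dependency contract, not something this
package reimplements: an RBF-kernel SVM (from e1071/libsvm) fitted with
cost `C` and kernel width `gamma`, exposing real-valued decision scores.
The supervised baseline trains on the labeled rows only (unlabeled rows
are discarded).  The cluster-then-label methods train on *all* rows with
their given, inferred and tie labels — the standard reading of handing the
discovered structure to the classifier; a flag (`include_ties = FALSE`)
drops tie rows for callers who prefer not to train on fallback labels.
With zero unlabeled rows every method reduces to the same supervised fit.

### Operating-point selection

Parameter search selects *parameter sets*, not score thresholds: among
grid cells whose validation sensitivity reaches the target (default 95%),
the cell with maximal specificity wins.  When no cell reaches the target
the rule needs a fallback, chosen here as maximal sensitivity, then
specificity, then smallest `C`, then smallest `gamma` — deterministic and
conservative.  Class-imbalance weights (inverse frequency) are available
via `class_weights` but default off.

## Separability diagnostic

The Fisher Discriminant Ratio between two groups is

$$\mathrm{FDR} = \frac{(\bar m_1 - \bar m_2)^2}{\bar s_1^2 + \bar s_2^2},$$

with *sample* (n−1) standard deviations, chosen for unbiasedness.  The
formula is scalar; for `d > 1` this package defines a pooled-multivariate
mode — squared norm of the mean difference over the summed per-feature
variances — because a multi-dimensional cloud must be summarised by one
number and no single canonical convention exists.  Both modes are labeled
in the report.  Affine feature maps cancel.  Zero variance with distinct
means reports an explicit `Inf` sentinel rather than an error.  As a rough
reading: values well above ~0.3 indicate clusters clean enough for
cluster-then-label; values near zero indicate the cluster assumption is
violated and supervised learning on the labeled subset is the safer bet.

## Synthetic data: what it emulates, and what it does not

Real pathology feature tables (bag-of-words texture histograms in ~100
dimensions, per-patient batches of a few hundred patches, a minority of
them labeled) are not distributable.  The generator reproduces the
*statistical skeleton* that the methods respond to: multi-class clusters,
unequal within-class density, per-patient (group) heterogeneity, and a
controllable labeled fraction revealed either uniformly or by whole
groups (emulating studies where a few patients are fully annotated).
Constants that the data do not pin down were fixed once:

* crescents: two half-annuli of radius 1, noise SD 0.1, vertical offset
  0.25 — a standard two-moons shape; `density_ratio` scales the second
  arc's noise so crescent data can also be density-varying;
* group heterogeneity: a per-group mean jitter of 0.25 within-class SD;
* randomness: one root seed with fixed per-component offsets (features,
  group jitter, label masking), so runs are reproducible and the masking
  can be varied independently of the geometry.

What the generator does **not** emulate: texture-feature correlations,
label noise, patch spatial autocorrelation within a slide, and the heavy
class imbalance of real triaging data.  Passing tests on this generator
therefore demonstrate the *mechanisms* (density-aware capture, prototype
failure on non-convex shapes, SSL failure under overlap), not clinical
performance.

### The three presets

The presets encode three separability regimes whose FDRs are ordered high
> mid > low by construction, mirroring the qualitative spread seen across
screening-grade and hard diagnostic tasks:

* `triaging_like` — a crescent pair with the second arc 1.5× noisier:
  well-separated (FDR ≈ 1.6 as generated) but irregular, non-convex,
  density-varying clusters.  A deliberate design choice: with ~50 labeled
  points in two dimensions, *any* compact convex geometry (e.g. two
  Gaussian blobs) is already solved by a supervised RBF-SVM, leaving SSL
  nothing to add; the regime where cluster structure genuinely carries
  information the labeled subset lacks is well-clustered but non-convex
  structure, and that is the regime screening tasks with high separability
  occupy.
* `lvbm_like` — Gaussian blobs at separation 1.5 pooled SDs (FDR ≈ 0.55).
* `bvm_like` — near-complete overlap, separation 0.25 (FDR ≈ 0.02): the
  cluster assumption is violated by construction.

All presets use 1000 points (500 per class), 8 groups and a 5% uniform
label fraction, matching the scale at which the evaluation properties are
asserted.

## Evaluation harness

* **Grouped cross-validation** holds out whole groups; for SSL methods the
  held-out rows are excluded from the labeler *and* the classifier, so no
  structural leakage is possible.  Within each training fold, grid cells
  are scored by an inner grouped cross-validation (default
  `min(3, training groups)` inner folds) on the *labeled* rows of the
  inner validation groups — true labels of unlabeled rows are never
  consulted for selection, only for scoring held-out folds.
* **Metrics** are fractions internally (sensitivity `TP/(TP+FN)`,
  specificity `TN/(TN+FP)`, accuracy, AUC by the midrank formula, exactly
  the all-pairs probability with ties at one half); percentages appear
  only in formatted reports.  Single-class test folds yield explicit `NA`
  sentinels that are excluded from fold means with a warning.
* **Paired Wilcoxon signed-rank test**: zero differences are dropped
  (Wilcoxon's original rule), magnitudes are midranked,
  `W = min(W+, W-)`, and for up to 12 retained pairs the two-sided
  p-value is exact by enumeration of all `2^n` sign assignments;
  beyond that a tie-corrected normal approximation with continuity
  correction is used.
* **Bonferroni adjustment** divides by comparisons × tails, so a
  six-comparison two-tailed family at α = 0.05 reports an adjusted level
  of 0.004 (3 decimals); the conventional α/comparisons is `tails = 1`.
  Full precision is kept internally.

## Problem sizes used by the shipped tests

The test suite and the acceptance script exercise: oracle equivalence on
200 random instances (n ≤ 200, d ≤ 10, 2–4 classes); ssFCM descent on 100
random instances and recovery on 6σ-separated blobs (n = 400, 5% labels,
20 seeds); preset comparisons over 20 seeds at n = 1000; and exact-test
cross-checks up to the enumeration limit.  These sizes were chosen as the
smallest at which the stochastic properties are stable across seeds while
a full run stays comfortably interactive.

## Known limitations

* The seeded assignment is transductive: it labels the unlabeled pool it
  was given and generalisation comes only from the downstream classifier.
* Exact Euclidean distances are the contract; no approximate-neighbour
  indexing is provided, so very large tables pay the full O(l·u·d) cost.
* Sensitivity/specificity (and hence operating-point selection) are
  binary; multiclass problems are handled as label assignment plus
  one-vs-rest compositions by the caller.
* In high dimensions with strongly unequal class densities, Euclidean
  neighbourhood distances concentrate and *any* distance-based labeler —
  this one included — degrades; the separability diagnostic should be
  consulted before trusting the inferred labels.
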