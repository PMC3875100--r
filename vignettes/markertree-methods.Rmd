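---
title: "Methods: decision-tree biomarker discovery in markertree"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decision-tree biomarker discovery in markertree}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markertree)
```

# The problem and the model

`markertree` searches a two-class expression matrix (probes × samples,
log2 intensities, labels tumor/normal) for a minimal set of probes whose
decision-tree classifier discriminates the classes well under
cross-validation. The pipeline has three statistical components, each
usable on its own.

## Differential-expression prefilter

Each probe is tested with an ordinary two-sample t-test (tumor vs
normal). The default is the pooled-variance Student test; Welch and a
paired variant are available by flag. P-values are corrected across
probes with the Benjamini–Hochberg step-up procedure, and a probe is kept
when its adjusted *P* is strictly below `alpha` (default 0.001) **and**
its tumor mean exceeds its normal mean. The direction rule reflects the
intended clinical use: overexpressed markers are easier to assay than
depleted ones.

Two caveats are deliberate and documented rather than hidden. First, no
variance moderation (empirical-Bayes shrinkage) is applied; moderated
pipelines will keep different — usually larger — probe sets on the same
data, so kept-set sizes are not comparable across methods. The result
object and its print method say so. Second, the test is unpaired by
default even for paired tissue designs, matching the most common default
of interactive GEO analysis tools; `paired = TRUE` performs the matched
test when within-class sample order encodes the pairing.

## Decision-tree induction

Trees are grown by recursive binary partitioning on continuous features.
At a node with *n* samples, every distinct observed value *v* of every
candidate feature except the feature's maximum defines a candidate split
{≤ *v*} vs {> *v*}; splits leaving a child below `min_leaf` (default 2)
are inadmissible. Candidates are scored by information gain (default) or
gain ratio. Growth stops at class purity, below `2 * min_leaf` samples,
or when no admissible split has positive score. Leaf labels follow the
majority rule; a tied leaf inherits the parent's majority, and a tied
root takes the lexicographically first class (`"normal"`), so induction
is deterministic end to end — no randomness anywhere.

**MDL correction (default on).** The score of a continuous-threshold
split is charged `log2(d)/n` bits, where *d* is the number of admissible
candidate thresholds at the node. This is the continuous-attribute
correction of C4.5 release 8 and its Java re-implementation J48. It
matters enormously for expression data: without it, essentially any
threshold over Gaussian noise has positive gain, trees grow to the
`min_leaf` floor, and the cross-validated accuracy of even a genuinely
informative probe collapses (on the reference simulation below, a true
marker's LOOCV accuracy drops from ~0.8 to ~0.65 while the tree triples
in size). Because the correction is part of tree *induction* but not of
the definition of information gain, `best_split()` exposes it as a flag
that defaults to off — the standalone operation returns the textbook
gain — while `c45_control()` defaults it to on.

**Threshold convention.** Split thresholds are observed training values,
never midpoints, so printed rules quote intensities that occur in the
data (a rule like `If g > 7.523 then tumor` refers to a real observed
value 7.523). The convention has one measurable cost: under LOOCV, a
held-out sample lying on the class boundary falls beyond the threshold
fitted without it, so a single perfectly separating feature tops out at
(n−1)/n rather than 1.0. The test suite asserts that ceiling rather than
pretending the effect away.

**Error-based pruning.** After growing, subtrees are replaced bottom-up
by their majority leaf whenever the leaf's pessimistic error estimate
`N * ucf(E, N, CF)` does not exceed the sum of its leaves' estimates.
`ucf(E, N, CF)` is the upper limit of the one-sided binomial confidence
interval — the largest error rate *p* with `P(X ≤ E | N, p) = CF` —
computed by exact Beta-quantile inversion `qbeta(1 − CF, E + 1, N − E)`
rather than the historical normal approximation (at `E = 0` this is the
closed form `1 − CF^(1/N)`; at `E = N` the bound is 1). The default
confidence factor 0.25 is the conventional setting. Subtree *raising* is
not performed. Two independent pruner implementations exist (an R
reference, `prune_tree()`, and the C++ induction path) and the tests
assert they produce identical trees.

## Cross-validation and selection

LOOCV runs *n* deterministic folds in sample order; accuracy is the mean
of the 0/1 outcomes, and sensitivity/specificity/accuracy come from the
confusion matrix accumulated over held-out predictions (tumor positive;
a metric with a zero denominator is reported as `NA`, never as 0).
Stratified k-fold CV shuffles each class with a user seed and deals
samples round-robin, continuing the fold cycle across classes so that
`k = n` reproduces the LOOCV partition exactly; fold assignment is a pure
function of sample order and seed.

The SFFS wrapper greedily appends, each iteration, the candidate probe
whose addition maximizes LOOCV accuracy of the tree on the augmented set.
Accuracy ties break by smaller prefilter adjusted *P* (when supplied),
then lexicographic probe id. Termination uses `patience = 2`: the search
stops after two consecutive iterations without strict improvement, which
encodes the observed practice of stopping once two extra candidates add
nothing; `max_iter` (default 10) caps runtime. The reported panel is the
shortest prefix of the chosen sequence attaining the maximum observed
accuracy. Note the evaluation protocol mirrors the original study design:
selection and the reported CV estimate use the same data, which biases
accuracy upward; an unbiased estimate requires re-running selection
inside each fold, which the package leaves to the user (run `sffs()` on
training folds of an outer loop).

# The synthetic-data generator

`simulate_expression()` emulates a normalized two-class microarray
experiment: background probes iid Normal(`mu_bg`, `sigma_bg`) in both
classes, defaulting to mean 8 and SD 1 on the log2 scale — typical
magnitudes for RMA-style summarized intensities. Planted roles:

* `single_marker` / `down_marker`: shifted ±`delta`·σ in **all** tumor
  samples;
* `pair_A` / `pair_B`: the complementary pair — A shifted +`delta`·σ in a
  seeded random tumor subset of size `round(f · n_tumor)`, B in exactly
  the complementary subset. Neither gene alone covers all tumors; at a
  shift large enough to separate the classes the pair supports a depth-2
  tree that does.

The default spec is the package's reference scenario: 30 tumor / 30
normal samples, 500 probes, one pair at `delta = 2`, `f = 0.9`. Sample
sizes and probe count were chosen to keep a full SFFS run over all probes
in seconds while matching the order of magnitude of small clinical
cohorts; `delta = 2` gives markers that are strongly significant
marginally (t ≈ 7 at n = 30/30) without being trivially separable.

What the generator does **not** emulate — and therefore what passing
tests do not show about real data: correlated probes, heavy-tailed or
heteroscedastic noise, batch and dye effects, intensity-dependent
variance, and annotation issues like multiple probes per gene. Gaussian
homoscedastic noise is the simplest model consistent with log2
intensities, and the complementary-pair construction is deterministic
given the seed precisely so that tests can assert exact ground truth.

**A known limitation worth stating plainly:** at the default
`delta = 2σ` the shifted and background distributions overlap by roughly
16% per tail, so the pair does *not* support a perfectly separating tree,
the weak partner's conditional signal (10% of tumors) is far below what
n = 60 can resolve against 498 noise candidates, and wrapper selection
usually picks an overfitting noise probe at the second step instead of
the planted partner. The acceptance suite measures this honestly (the
pair-recovery rate at `delta = 2` is near zero) and the same measurement
at `delta = 5` — where separation actually holds — recovers the pair with
a two-step improvement in ~90% of seeds. Wrapper selection's
vulnerability to selection overfitting at small n is a real property of
the method, not an implementation artifact.

A second protocol subtlety: under LOOCV on *balanced* null data a
majority-leaf tree scores ~0, not the majority rate, because removing the
held-out sample tips the training majority against it. Null-behavior
checks therefore use unbalanced designs, where "accuracy ≈ majority-class
rate" is well-posed.

# Numerical and interface choices

* Quartiles for the array-QC 1.5×IQR screen use linear interpolation
  (`stats::quantile` type 7); an array fails only when ≥ 2 of its three
  quality parameters fall outside their intervals.
* The replicate "2-fold percentage" counts raw-scale ratios > 2 **or**
  < 1/2 (symmetric reading); both QC cuts (*r* > 0.95, 2-fold % < 15) are
  strict inequalities.
* The density-profile inspection of replicate arrays is exported as a
  histogram table (`intensity_histogram()`) for visual review — no
  quantitative pass/fail exists for it.
* Split-score ties inside one feature resolve to the lowest threshold,
  across features to the first feature offered; both by construction
  (first strict improvement wins), keeping induction order-deterministic.
* Degenerate inputs are defined, not crashed on: two zero-variance groups
  with equal means give t = 0, p = 1; a constant feature yields "no
  split"; a training fold that loses one class yields a majority-leaf
  tree and is noted in the CV result.
* Missing cells are rejected at load time by default; an opt-in flag
  imputes a probe's per-class mean. Values are assumed log2; `log2 =
  TRUE` transforms raw positives, and no auto-detection is attempted.
* Matrix orientation is fixed (probes × samples); labels are exactly
  `"tumor"` / `"normal"` with tumor the positive class everywhere.
* All serialization is text (JSON for trees/traces/CV results, TSV for
  rule and DE tables) and lossless: thresholds are written with full
  precision (`%.17g`), and a deserialized tree predicts identically.

# Problem sizes in the test suite

Oracle-equivalence tests run on small exhaustive cases (≤ 8 samples, ≤ 5
features, 100 random fixtures; 1000 random p-vectors for the BH oracle;
bisection checks of the pruning bound to 1e-9). Statistical behavior
(planted-marker recovery, null false-positive control) runs the reference
scenario over 20 and 50 generator seeds respectively. These sizes were
chosen so the whole suite exercises every code path in a few minutes
while the statistical assertions still have negligible flake
probability under their fixed seeds.

# Limitations

* Binary classes only; multiway and categorical splits, missing-value
  fractional instances, boosting/bagging are out of scope.
* No variance moderation in the prefilter (see above).
* The default protocol reports selection-biased CV accuracy by design
  (mirroring the original study protocol); nest the selection for
  unbiased estimates.
* The CLI's `pipeline` follows the filter → select order; complementary
  markers whose marginal effect is too weak for the prefilter require
  `--candidates all`.
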