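---
title: "Learning small ER-status classifiers from gene expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning small ER-status classifiers from gene expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Estrogen-receptor (ER) status steers the treatment of invasive breast
cancer: ER-positive tumors respond to endocrine therapy, ER-negative tumors
do not. The reference assay, immunohistochemistry on formalin-fixed tissue,
is semi-quantitative and notoriously sensitive to pre-analytic variables.
An RNA-based call from a handful of transcripts is an attractive
alternative — but only if the classifier is small enough for targeted
assays and stable enough to transfer between labs and array platforms.

`ersvm` implements the full route from a raw features-by-samples intensity
table to such a classifier: a normalization chain, a non-parametric
relevance measure, a redundancy-aware feature ranking, a linear max-margin
learner wrapped in a model-size selection rule, and a fixed published
three-gene ER rule that can be applied to new cohorts, including cohorts
measured on a different platform. A synthetic-cohort generator with planted
ground truth makes every stage testable without patient data.

```{r, eval = FALSE}
library(ersvm)

d <- generate_cohort(synthetic_config(seed = 1)) |>
  ld_transform(\(m) {
    m |>
      filter_features(require_annotation = FALSE) |>
      impute_missing() |>
      normalize_chain(c("floor", "per_array", "per_feature",
                        "log_ratio", "zscore"))
  })
fit <- fit_fs_svm(d, seed = 1)
glance(fit)
autoplot(fit)
```

## Normalization

Raw single-channel intensities pass through four arithmetic steps:

1. **Floor** (`floor_baseline()`): every value below 0.1 is replaced by
   0.1. The floor is in raw intensity units; it exists so the ratio steps
   below are defined and stable.
2. **Per-array scaling** (`normalize_per_array()`): each array is divided
   by its own 50th percentile, removing global brightness differences
   between hybridizations. The 50th percentile is the type-7 (linear
   interpolation) median — percentile dialects differ, so this is pinned.
3. **Per-feature scaling** (`normalize_per_feature()`): each probe is
   divided by its median across samples, moving probes onto a common
   fold-change scale.
4. **Z-scores** (`zscore()`): each probe is standardized to mean 0,
   variance 1 across the cohort, using the *population* standard deviation
   (divisor *n*). The choice of divisor is recorded in the fitted
   parameters; nothing downstream depends on it beyond consistency.

Z-scores confer the property the whole transfer story rests on:
`z(a * x + b) = z(x)` for any `a > 0`. A per-probe gain or offset — which is
what a different scanner, labeling chemistry, or probe sequence
introduces — vanishes exactly. For this reason z-scores are **always refit
on the cohort being classified**, never carried over from training data.

Two variants complete the toolkit. `exponentiate()` undoes a log transform
for cohorts deposited on log scale (the base is a flag; natural log by
default, since the depositing pipeline rarely documents it).
`log_actb_normalize()` is the single-sample alternative: log expression of
the target probes minus log expression of the housekeeping gene ACTB in
the same sample, which cancels any per-sample multiplicative factor and
needs no reference population at all.

**Optional log-ratio step.** The chain as listed z-scores the
median-centered *ratios*, which for log-normal intensities are heavily
right-skewed. `log_ratio()` (log2 of the N3 output) can be inserted before
the z-score; it makes per-probe distributions near-Gaussian, which suits a
margin classifier. Whether the original pipeline z-scored ratios or logs is
not documented anywhere we could pin down, so the literal ratio-scale chain
is the default and the log variant is explicit. All synthetic benchmarks in
this package use the log variant, because the generator plants its class
signal as Gaussian shifts on log scale — that is the regime in which the
two-Gaussian accuracy oracles used by the tests are valid.

**Missing values.** Presence is defined as "non-missing measurement" (we
have no access to platform detection flags). `filter_features()` keeps
probes with a database annotation that are present in at least
`ceiling(0.25 * n)` samples by default — the generalization of the common
44-of-176 rule — and the exact integer can be pinned. Residual missing
cells after filtering are imputed with the per-feature median of observed
values (`impute_missing()`), a robust choice that leaves the median-scaling
steps unchanged; the imputation count is reported.

## Relevance: Parzen-window mutual information

The relevance of a probe *G* for the class *C* is the mutual information

$$ I(G;C) = \sum_{c} \int p(g, c) \log_2 \frac{p(g, c)}{p(g)\,P(c)} \, dg $$

with the class-conditional densities estimated by Gaussian-kernel Parzen
windows and `P(c)` the empirical class prior. Implementation choices, all
of which are parameters:

* **Units: bits** (log base 2). For a two-class problem this puts estimates
  on the interpretable 0–1 scale bounded by the class entropy
  (≈ 0.95 bits at a 112/176 prior).
* **Bandwidth:** Silverman's rule-of-thumb
  `0.9 * min(sd, IQR/1.34) * n^(-1/5)`, computed per class on the
  class-conditional sample. Because the bandwidth scales with the data, the
  estimate is invariant under positive affine transforms of *g* (MI is
  reparameterization-invariant; the estimator inherits this up to
  quadrature error, tested at 0.02 bits).
* **Quadrature:** a fixed 512-point grid spanning the data range extended
  by three bandwidths. Halving the grid moves estimates by well under
  10^-3 bits on smooth data (asserted in the tests), so the grid is not a
  sensitive knob.
* Small negative estimates (possible through quadrature truncation) are
  clipped to zero.

Calibration, all against independent oracles computed in the test suite:
under independence (n = 400) estimates stay below 0.05 bits; for perfectly
separated balanced classes the estimate is within 0.1 bit of the exact
1-bit discrete answer; for two-Gaussian mixtures (n = 2000) it lands within
0.05 bits of the numerically integrated closed-form value.

Feature–feature MI (the redundancy term below) uses the same machinery in
two dimensions: a product-kernel density on a 64 × 64 grid whose marginals
are integrated from the joint, keeping the estimate internally consistent.

## Ranking: minimum redundancy, maximum relevance

`mrmr_rank()` orders features greedily. Rank 1 is the most relevant
feature; with *t* features selected, the next is the remaining candidate
maximizing

$$ I(f; C) \;-\; \frac{1}{t} \sum_{s \in \text{selected}} I(f; s) $$

— the mutual-information *difference* form of the criterion, the default of
the system that popularized it (a quotient form exists; a flag is reserved
but unimplemented). A probe that merely duplicates an already-selected
probe has `I(f;s)` near its self-information, driving its score negative
and demoting it below weaker but complementary probes. This matters on
arrays, where one gene is routinely represented by several probes.

Ties in relevance or score are broken by input feature order (first wins),
making the ranking deterministic. Setting `redundancy_weight = 0` reduces
the ranking to descending relevance, which the tests use as a degenerate
check.

Pairwise continuous MI is the expensive part: the exact greedy step is
quadratic in the number of features. `pool_size` restricts the greedy stage
to the most relevant candidates (standard practice at transcriptome
scale); `NULL` — the default of `mrmr_rank()` itself — evaluates the exact
criterion, and the wrapper below uses a pool of `max(3 * r_max, 40)`. The
tests verify that the greedy sequence is identical to an exhaustive
re-evaluation of the criterion at every step on exact (unpooled) runs.

## The wrapper: feature-selecting SVM

`fit_fs_svm()` combines three ingredients:

1. **Stratified folds** (`stratified_folds()`, k = 10 by default): sample
   ids are shuffled within class by a seeded generator and dealt
   round-robin, with the dealing position carried across classes — fold
   sizes and per-class counts each differ by at most one, and the partition
   is a pure function of the seed.
2. **Accuracy curve** (`accuracy_curve()`): for every fold, features are
   ranked by mRMR *on the training portion only* — the held-out fold
   contributes nothing to its own ranking, which the tests verify by
   corrupting a held-out fold and asserting the ranking does not move. A
   linear SVM is trained on the top r features for r = 1..18 (r_max is
   configurable; 18 covers the region where curves level out) and scored on
   the held-out fold. Per size, the curve records the mean and the sample
   standard deviation (divisor k − 1) of the k fold accuracies.
3. **One-SD rule** (`select_r_star()`): the selected size is the smallest r
   whose mean-plus-SD reaches the high-water-mark mean accuracy. The
   maximizer always qualifies, so r* exists and never exceeds the argmax;
   among qualifying r the smallest wins, and ties in the maximum go to the
   first maximal r.

The final model re-ranks features on the complete dataset and trains the
linear SVM on the top r* features. The reported `cv_accuracy` is the
curve's mean ± SD at r* — an honest cross-validated figure for that model
size, though (as always with a data-driven size rule) not a fully unbiased
estimate for the final refit model.

The SVM itself is the soft-margin linear machine from libsvm (via e1071),
cost C = 1, no internal rescaling (the data are already z-scores).
Prediction is `sign(w · x + w0)` with exact ties called positive, a
documented convention. The learner contract is pinned by closed-form
fixtures in the tests (midpoint boundary for separable pairs, training
accuracy 1 on separable clouds) rather than by solver internals, so any
compliant solver could back it.

## The fixed three-gene classifier

`eq3_classify()` applies a published linear rule for ER status over
cohort-level z-scores of three probes:

| probe (Agilent) | gene | weight |
|---|---|---|
| A_32_P104334 | AW972815 transcript | −0.2466 |
| A_23_P75056 | GATA3 | +2.2165 |
| A_23_P372234 | CA12 | +1.2934 |

GATA3 and CA12 are strongly up-regulated in ER-positive tumors; the
classifier is essentially a weighted two-gene vote with a small correction.
The original rule's intercept is not recoverable from the published
coefficients, so the default threshold is 0 on z-scored inputs — the
natural choice, since each z-scored probe is centered — exposed both as an
argument and in the model-JSON schema, and `refit_threshold()` can
re-derive an intercept from any labeled cohort by accuracy maximization.

Cross-platform application goes through a one-to-one probe map
(`map_probes()`; the bundled `er3_probe_map("affymetrix")` carries the
three sequence-matched Affymetrix counterparts). Only the three probes used
are z-scored — the rest of the target array is not needed — and z-scores
are always refit on the target cohort. Cohorts deposited on log scale are
exponentiated first (`exponentiate_base`).

## The synthetic generator

`generate_cohort()` emulates the structure of a single-channel tumor
cohort: log-normal raw intensities (log-intensity baselines ~ N(6, 1)),
class labels drawn from a 112/176 positive prior, `n_informative = 3`
probes whose log-intensities shift by `effect_size = 2` within-class SDs
between classes (signs alternating, so both up- and down-regulated markers
occur), two noisy redundant copies per informative probe
(copy noise SD 0.5 on log scale, echoing the duplicate-probe phenomenon),
989 uninformative probes, one low-variance housekeeping probe (`ACTB`, log
SD 0.1), and per-cell dropout at presence rate 0.98. Defaults were chosen
once to mirror a mid-sized training cohort and are not tuned per test.
The planted truth travels with the cohort (`$truth`), so recovery can be
scored. `generate_platform_pair()` replays the same latent signals through
a second instrument: per-probe log-normal gain (σ = 0.25), additive
intensity offset (SD 2 against baselines of ~e^6), log-scale measurement
noise (SD 0.2), and fresh probe names plus the translation map.

What the generator does *not* emulate: probe-sequence effects, spatial
array artifacts, batch structure, correlated noise between uninformative
genes, label noise in the reference assay, or class-dependent missingness.
Passing the planted-recovery tests therefore demonstrates that the
machinery is correct and calibrated under clean log-normal conditions, not
that any particular accuracy will be attained on real tumors.

## Problem sizes and known behavior

The test-suite and acceptance-script simulations use cohorts of 200
samples by ~1,000 features, 10-fold cross-validation up to r = 18, MI
calibration at n = 400–2,000, and 20 seeds for the planted-recovery sweep
— sizes at which every distributional claim in the tests has adequate
power while a full run stays comfortably on a laptop.

One behavior is worth stating plainly, because it is a property of the
method rather than a defect: the one-SD rule is deliberately parsimonious.
On cohorts with three planted effect-2 features it usually selects r* = 2
(occasionally 1), where the Bayes-optimal accuracy is Φ(√2) ≈ 0.92
(Φ(1) ≈ 0.84 at r* = 1). The fitted models track those ceilings closely —
the implementation loses essentially nothing to estimation — but a
held-out accuracy of 0.90 is then only reachable in the subset of seeds
where the rule keeps two strong features or more. Users who prefer
accuracy over parsimony at these effect sizes should inspect the
`accuracy_curve` and choose the argmax instead; both numbers are in every
fitted object.

## Degenerate inputs and numerical conventions

* Constant features make z-scores and MI undefined; both operations abort
  naming the offending features, and the presence filter is the intended
  remedy.
* A minority class smaller than the fold count is allowed (some folds then
  carry none of it), but every class needs at least two members.
* Fold construction, cohort generation and the whole fit are pure
  functions of their seeds; reruns are bit-identical, which the pipeline
  tests assert at the artifact-checksum level.
* TSV round trips are bit-exact (shortest-round-trip doubles); model JSON
  holds ~15 significant digits.
* The floored stage enforces values ≥ floor; the raw stage accepts any
  finite values, because log-scale cohorts legitimately contain negatives
  before `exponentiate()`.
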