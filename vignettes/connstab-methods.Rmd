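---
title: "Stability-selected connectome classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stability-selected connectome classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis problem

Clinically defined subgroups of a psychiatric cohort — for example
patients with a low versus a high number of mood episodes, or the two
diagnostic subtypes of bipolar disorder — are to be distinguished from
resting-state functional connectivity, optionally pooled with regional
morphometry. Connectomes are wide: a 268-region parcellation yields
35,778 edge features for at most a few dozen subjects per group, and
most edges are irrelevant or mutually redundant. `connstab` implements a
three-stage answer:

1. **Stability selection.** Features are ranked by minimum-redundancy
   maximum-relevance (mRMR) on many bootstrap resamples of the cohort;
   the per-feature selection count over resamples measures how stably a
   feature is chosen.
2. **Threshold sweep with nested cross-validated classification.** For
   each count threshold `t`, the features selected in more than `t`
   resamples form a candidate set. Every admissible set is handed to a
   repeated, nested cross-validated SVM with an RBF kernel; the
   threshold with the best mean test accuracy wins.
3. **Interpretation and screens.** Features re-selected in more than 90%
   of the nested-CV repeats are reported as *major features* with the
   direction of their group difference and the network pair they
   connect; multiple linear regression quantifies how much variance in
   verbal-memory scores the selected features explain; confound screens
   relate the selected features to symptom scores, illness duration,
   mood state and medication.

# Feature engineering

Subjects whose mean framewise displacement exceeds 0.2 mm are excluded
(`filterMotion()`; the boundary value is kept). Pearson correlations
between ROI time series are variance-stabilized with Fisher's r-to-z
transform, `z = atanh(r)`, with `|r|` clipped to `1 - 1e-7` so that
degenerate perfect correlations stay finite. The strict upper triangle
is vectorized in row-major order — (1,2), (1,3), ..., (2,3), ... — a
documented, round-trippable ordering (`vectorizeMatrix()` /
`devectorizeMatrix()`); each edge carries the network pair of its
endpoints. Morphometric features (regional volume, cortical thickness),
when supplied, are z-scored across subjects before entering the common
selection pool, since mutual-information discretization is sensitive to
scale mixing.

Age and sex are regressed out of every feature before selection
(`residualizeFeatures()`). The default `mode = "whole_sample"` fits each
per-feature OLS on the whole sample, the classical whole-cohort
covariate control of this analysis family; it is also a known source of
train/test leakage, which is why a `fold_safe` mode (fit on training
subjects, apply to all) is provided for leakage-free workflows. The
default remains `whole_sample` because the pipeline is meant to reproduce the
established procedure, leakage included; see *Known limitations*.

# Mutual information and the MIQ criterion

Relevance and redundancy are measured with plug-in mutual information on
discretized features. The default discretizer (`sd3`) assigns three
states at cut points one SD either side of the mean; equal-frequency
binning is available as an alternative. For a candidate feature `x`, the
mutual information quotient is

$$MIQ_x = V_x / W_x,$$

with `V` the MI between `x` and the class label and `W` the mean MI
between `x` and the already-selected features. The greedy selector picks
the most relevant feature first and thereafter maximizes MIQ. Three
conventions the quotient itself leaves open are fixed as follows:

* **Step 1** has no selected set; it is ranked by pure relevance.
* **`W = 0`** (a candidate carrying no information about any selected
  feature) ranks above every finite quotient, ordered by `V`.
* **Ties** break toward the lower feature index. To make tie-breaking
  well-defined across summation orders, pairwise MI values are rounded
  to 12 decimals and quotients to 9 before comparison — mathematically
  equal scores then compare equal bit-for-bit in both the fast C++
  selector and the brute-force R oracle (`mrmrBruteOracle()`, a literal
  per-step re-evaluation kept free of caching, against which the
  selector is tested exactly).

Redundancy is accumulated against the *selected set*, not the whole
pool: against a fixed pool the quotient would be a constant per feature
and selection could never respond to redundancy already admitted. Using
the mean rather than the sum of pairwise MI is rank-equivalent at any
fixed step, since all candidates divide by the same set size.

# Bootstrap stability selection

Each of `B` resamples draws `floor(0.9 n)` subjects with replacement
(for a 98-subject cohort, 88 draws; subsampling without replacement is a
configuration option) and runs mRMR for `kPerRun` features. Resamples
that lose a class are redrawn and logged; a redraw rate above 10%
triggers a warning with the class counts. `kPerRun` defaults to 50 — the
quantity is absorbed by the threshold sweep, which is the actual
selection dial.

The threshold grid is expressed as proportions of `B` (0.15 to 0.95 in
steps of 0.05), so the same grid is meaningful at `B = 1000` (150, 200,
..., 950) and at the desk-scale `B = 200` used in the packaged
verification runs. Accumulated sets use a strict inequality
(`count > t`), are nested, and shrink with `t`. To keep the learner
below the curse of dimensionality, only sets no larger than
`floor(2/3 n)` — the size of the largest outer-training fold — proceed
to classification (`capByDimensionality()`); classification additionally
requires at least two features. In the full-scale analysis this cap
reproduces the practice of classifying only the 0.40–0.80 band of the
grid.

# Nested cross-validation

Each of `repeats` (100 at full scale) repeats draws a stratified 3-fold
outer split. Within an outer-training fold, mRMR re-ranks the candidate
set on training subjects only and keeps the top 80% (configurable); the
SVM-RBF cost and kernel width are tuned by stratified 10-fold inner
cross-validation over `C ∈ {0.01, 0.1, 1, 10, 100}` and
`γ ∈ {0.25, 0.5, 1, 2, 4} / (p · var)`, where `p` is the retained
feature count and `var` the overall variance of the training values
(grid ties keep the first grid point: smallest `C`, then smallest `γ`).
Outer-test accuracy, sensitivity, specificity and rank-based
(Mann-Whitney) AUC are averaged over the three folds; repeats are
summarized as mean ± SD. Fold seeds derive from a master seed by a fixed
counter (`seed + 7919 r`), so all repeats are reproducible and
independent runs with the same seed are identical.

The best threshold maximizes mean accuracy; an exact tie resolves to the
larger threshold, i.e. the sparser feature set. A feature counts toward
the major-feature rule in a repeat when the inner re-ranking kept it in
a majority of the outer folds (any-fold and all-folds aggregations are
available); features with counts strictly above 90% of the repeats form
the `MajorFeatureSet`, annotated with the sign of the residualized group
difference (positive = higher in the positive class) and the network
pair. Per-repeat accuracies of two classifications are compared with a
pooled-variance independent-samples t test; two identical constant
accuracy vectors are reported as no difference (`t = 0, p = 1`) rather
than an error, and constant vectors with different means raise an error
because no within-group variance exists to test against.

# Cognition regression, confounds, demographics

`regressCognition()` fits one OLS per verbal-memory task (immediate and
delayed recall, learning slope, recognition, retention) on all selected
features jointly, reporting R², the overall-F p value, and
Benjamini-Hochberg q values across the five tasks of a subgroup split
(cross-split pooling is the caller's choice of family). Complete cases
are used per task, and `n > p + 1` is enforced. Two feature-set choices
are meaningful and both supported: the accumulated set at the best
threshold (the default for the regressions) and the repeatedly selected
major features (the default for the confound screens).

`confoundScreen()` uses Pearson correlations for continuous clinical
variables, pooled-variance t tests for binary medication flags, and
one-way ANOVA across mood states, with BH adjustment within each
(variable × feature-set) family. Degenerate variables (a single level,
or a level with fewer than two subjects) are dropped with a warning.
`groupCompareDemographics()` compares subgroups with pooled-variance t
tests (means ± SD reported) and a chi-square test without continuity
correction for sex; both tests are also exposed on printed summary
statistics (`pooledTTest()`, `chisqNoCorrection()`), and the raw-data
path reproduces the summary path exactly. Pooled variance rather than
Welch, and no Yates correction, are deliberate: they are the variants
that reproduce the significance levels conventionally reported with
this design.

# The synthetic cohort generator

Because the clinical MRI data this analysis family targets are not
public, `generateCohort()` builds cohorts carrying exactly the structure
the pipeline assumes, so that every stage is testable end to end:

* Two groups of configurable size (default 43 and 55, the episode-count
  design) with edge features drawn directly on the residual Fisher-z
  scale as Gaussians (`noiseSD` defaults to 0.25, a realistic
  between-subject spread of z-connectivity).
* A configurable number of planted edges (default 10) whose group means
  differ by `effectSize` Cohen's d units with random sign; all other
  edges carry no group effect.
* Age ~ Normal(38, 13) truncated to [18, 70] and sex ~ Bernoulli(0.3
  male), optionally leaking into every feature with coefficient
  `covariateConfounding`.
* Five verbal-memory scaled scores generated as `y = Xw + ε` over the
  planted edges, with the noise variance solved in closed form from the
  realized variance of `Xw` so that the population R² equals
  `cognitionR2` exactly (default 0.6) — making R² recovery a sharp
  target rather than a tuned one.
* Symptom scores, illness duration, mood state, medication flags and
  mean FD with realistic magnitudes; the additional subgroup labels
  (hospitalizations, suicide, psychosis, diagnosis) are drawn
  independently of the features. Mean FD is drawn below 0.2 mm: the
  generator emulates a post-QC sample.

Cohorts are deterministic functions of their configuration, including
the seed. `generateTimeseries()` optionally materializes per-subject
ROI series whose population correlation equals the inverse Fisher
transform of the subject's feature row, for testing the connectivity
path; dense random z-matrices need not be positive definite, in which
case linear shrinkage toward the identity is required and the error
says so. What the generator does **not** emulate: scanner artifacts,
motion, hemodynamics, spatial autocorrelation between edges, or
heavy-tailed clinical score distributions. Passing tests therefore
certify the statistical machinery, not robustness to real acquisition
noise.

Default problem sizes in the packaged tests are desk-scale by design: 30
regions (435 edges), `B = 200` bootstrap resamples, 20 nested-CV
repeats; the grid, cap and rules are identical at full scale (268
regions, `B = 1000`, 100 repeats).

# Known limitations

* **Whole-cohort selection is optimistic.** Bootstrap selection draws
  every resample from the same cohort, so features with chance
  in-cohort association are re-selected far more stably than a naive
  `kPerRun / p` intuition suggests, and downstream cross-validated
  accuracy inherits that optimism even though the nested CV itself is
  leak-free (its hygiene is verified by a canary test, and
  permuted-label runs on fixed feature sets are calibrated at chance).
  On null cohorts the full pipeline therefore reports above-chance
  accuracy; `scripts/acceptance.R` computes this quantity explicitly
  (`null_best_accuracy`). This mirrors the double-dipping acknowledged
  in the analysis family the package implements; `fold_safe`
  residualization and per-fold re-ranking mitigate but do not remove
  it. Conclusions about real data should rest on the comparison of
  subgroup classifications against each other and against such a null
  baseline, not on absolute accuracy alone.
* **Class imbalance moves the chance level.** With a 43/55 split the
  majority-guess rate is 0.561, not 0.5; null bands should be stated
  against it.
* The plug-in MI estimator on three states is biased upward for small
  samples; this affects absolute MI values, not materially the
  rankings, and the brute-force oracle shares the estimator by design.
* Only binary subgroup contrasts are supported; no probability
  calibration, alternative learners, or error-controlled stability
  selection (complementary-pairs bounds) are provided.
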