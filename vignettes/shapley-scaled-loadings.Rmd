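---
title: "Explaining ordinal radiomic classification with Shapley-scaled loading vectors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Explaining ordinal radiomic classification with Shapley-scaled loading vectors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radshap)
options(radshap.verbose = FALSE)
```

## The model and its assumptions

`radshap` classifies MRI slices into the four ordinal background parenchymal
enhancement (BPE) grades — minimal, mild, moderate, marked — from tabular
radiomic features, and explains each prediction at the level of the radiomic
features themselves. The pipeline assumes:

* **Rows are slices, columns are named radiomic features.** Names follow the
  `<filter>_<class>_<type>` convention of the dominant extraction tools, so
  real extractor output loads unchanged. Labels are integers 1–4; all slices
  of a patient share one label.
* **A low-dimensional representation carries the class signal.** Features
  are z-scored with training-set mean and population SD and projected onto
  the first `k` unit-norm principal axes (`k = 4` by default). The
  classifier only ever sees these `k` scores, which is what makes
  post-hoc attribution over components tractable and exact.
* **Slices within a patient are correlated**, so splits operate on whole
  patients, never on slices.

The classifier is a compact feed-forward network: blocks of dense →
batch-normalization → ReLU → dropout, a 4-unit softmax head, class-weighted
categorical cross-entropy (weights `n_total / (4 n_c)`, the inverse-frequency
form that reduces to 1 under balance), Adam, Glorot-uniform weights, zero
biases. Training runs a fixed number of epochs and returns the parameter
state with the lowest class-weighted validation loss (checkpoint granularity:
end of epoch). Batch normalization uses batch statistics during training and
exponential running averages (momentum 0.99, epsilon 1e-3) at inference;
dropout is inference-off. The activation and its position are not dictated by
the architecture sketch the design follows; ReLU after normalization is the
conventional choice and is fixed here.

## Shapley attribution in component space

For each slice the four class probabilities are attributed to the `k`
component inputs with Shapley values. The value function is the
background-expectation form: `v(S)` is the mean model probability when
components in `S` take the explained slice's values and the others keep a
background row's values, averaged over the background set (by default the
full training-set scores; a seeded subsample is available for large tables
and is recorded in the explanation object). Base values are the mean model
output over the background — "the average model output over the training
dataset". With `k ≤ 15` every one of the `2^k` coalitions is enumerated and
the kernel-regression estimator solves the exactly determined constrained
weighted least-squares problem, so the estimates are exact (the package also
ships `exact_shapley()`, an independent enumeration oracle used by the test
suite; the two agree to numerical precision). Probabilities, not logits, are
explained: base values and force-plot-style readings are then on the scale a
reader expects.

## Shapley-scaled loading vectors

Each radiomic feature `i` owns the loading vector `(φ_i1, …, φ_ik)`. For an
explained prediction the Shapley row `α` of the *predicted* class (always the
prediction, even when it disagrees with the truth — predictions are what is
being explained) scales those coordinates:

* unscaled length `V(X_i) = √(Σ_j φ_ij²)`,
* Shapley-scaled length `V_SHAP(X_i) = √(Σ_j (α_j φ_ij)²)` — the feature's
  importance for this prediction,
* orientation `O(X_i) = Σ_j α_j φ_ij` — signed: positive pushes the class
  probability up.

The printed form of these equations in the source material drops the `j`
subscript on `φ`; the sums are read with `φ_ij`, the only reading under
which the 4-D vector construction is meaningful.

Features are then pooled by **feature type** — the terminal name token,
across filters *and* texture-matrix classes, so GLRLM/GLDM/GLSZM
GrayLevelNonUniformity merge while first-order Entropy and GLCM JointEntropy
stay distinct. Within a report, type-level mean lengths are min–max rescaled
to [0, 1] (the rescale is monotone, so the mask below is unaffected), and
types whose mean length falls below the configured percentile (default 75th,
linear-interpolation quantile) are masked. Orientations are averaged but
never rescaled. Equal weighting is used in the type average (not weighting by
filter multiplicity). If every type mean is identical the rescale is
degenerate and all rescaled values are reported as 0.

Global reports pool all test slices the model assigned to one class and
average the Shapley-scaled coefficients `α_j φ_ij` over those slices *before*
taking lengths — with a shared loading matrix this equals using the
subset-mean Shapley vector, and opposite attributions cancel, which is the
intended behavior for a class-level consensus.

## The synthetic generator

Real BPE datasets are private, so the generator is a first-class module, not
a test afterthought. Per patient it draws a class from `class_probs` and a
latent offset; per slice a latent position `z` in `d_latent = 4` dimensions
with unit slice-level noise, the class gradient sitting on axis 1 at
equidistant means `0, e, 2e, 3e` (a straight line is the simplest generator
of a one-dimensional ordinal gradient). Features are a fixed linear map of
`z` plus independent noise; only columns whose feature type is in
`signal_feature_types` load on axis 1 (fixed +1 loading — the planted,
positively oriented direction), while all columns receive
`Normal(0, 1/√d_latent)` loadings on the other axes so total variance stays
comparable across columns.

Defaults and why:

* `n_features = 1192` — the slice-wise feature count of the motivating
  extraction setup.
* `class_probs = (0.40, 0.25, 0.20, 0.15)` — imbalance decreasing with
  grade, a stand-in (per-class counts of the motivating dataset are not
  public).
* `effect_size = 3`, `noise_sd = 0.5` — a clearly learnable but not trivial
  gradient: a plain multinomial logit on the first four PCs reaches ~0.85–0.9
  held-out accuracy at 60 patients × 40 slices, which matches the regime the
  pipeline is designed for.
* `within_patient_sd = 0.3` — patient-level residual anatomy is modeled as
  smaller than slice-level variation (SD 1); patients are correlated enough
  that slice-wise splitting would leak, which is the point of
  patient-stratified splits.
* `signal_feature_types` — RunEntropy, ZoneEntropy, DependenceEntropy,
  GrayLevelNonUniformityNormalized: entropy/uniformity-type texture measures
  of the kind that dominate BPE grading in practice, present under several
  filters and matrix classes so type-level pooling is genuinely exercised.

The generated name list crosses every feature family with every filter tag,
including shape descriptors — a real extractor computes shape only on the
unfiltered image. The departure is deliberate: it guarantees each feature
type appears under at least two filter/class combinations, so type-level
aggregation never degenerates. What the generator does **not** emulate:
scanner/site batch effects, heteroscedastic feature noise, nonlinear
feature–latent relationships, and annotation noise. Passing tests therefore
demonstrate the pipeline's correctness and its behavior under a clean
ordinal gradient, not clinical performance.

### Fixtures

`make_fixture()` registers four deterministic tables: `tiny` (8 patients × 5
slices × 40 features; its seed is chosen so all four classes appear),
`separable` (50 × 30 × 1192, effect 3, noise 0.5), `imbalanced` (50 × 20,
probabilities 0.55/0.25/0.12/0.08; seed chosen so every class has ≥ 4
patients), and `null`. The null fixture (80 × 8, effect 0) additionally sets
`within_patient_sd = 0`: the evaluation bootstrap resamples prediction
*pairs* and thus assumes exchangeable slices, so the no-signal reference
deliberately carries no latent structure of any kind — with patient-level
offsets and few test patients, predictions cluster within patients and a
slice-level interval under-covers even though no class signal exists. That
clustering effect is real and worth knowing about; the null fixture isolates
the no-signal property instead.

## Splitting

Targets are 62/19/19% of slices (±5 pp — patients are atomic, so exact
fractions are unattainable) with every class holding ≥ 10% of every set's
slices, and ≥ 2% within each CV fold's train and validation parts. The
algorithm is rejection sampling over random patient permutations packed
greedily toward the target fractions (tie-break: the set furthest below its
target), accepted only when all constraints hold; CV folds deal
class-stratified with one rotating fold pointer, keeping fold sizes within
±1. Infeasibility raises an error naming the tightest violated constraint —
constraints are never silently relaxed. Genuine infeasibility exists: the
tiny fixture's 8 atomic patients cannot hit 19 ± 5% (one patient is 12.5%,
two are 25%), and a class held by fewer than three patients cannot appear in
three sets; both raise the documented error.

## Numerical choices and degenerate inputs

* Standardization uses the population SD (n denominator); whether the
  motivating setup used n or n−1 is unknowable from its description, and the
  choice only rescales scores by a constant factor.
* PCA columns are sign-fixed (largest-|coefficient| entry positive):
  eigenvector signs are otherwise arbitrary and every Shapley-scaled
  orientation downstream would be irreproducible across runs.
* Zero-variance training features cannot be z-scored; they are dropped with
  a logged message and recorded in the model so transforms realign columns.
* Kernel SHAP with full enumeration solves the constrained WLS by
  substituting the efficiency constraint; additivity holds to ~1e-15 in
  practice and is asserted at 1e-8 in tests. The sampled-coalition path
  exists only for `k > 15` and is not used at the default `k = 4`.
* Percentile masks keep values `≥` the type-7 quantile ("below ... excluded"
  reads as strictly-below being dropped); ties at the threshold have measure
  zero for continuous scores.
* Cohen's κ on a degenerate single-cell table is 1 when the cell is
  diagonal; prediction-free tables with `p_e = 1` otherwise raise an error.
  The adjacent-error fraction is undefined (NA) with zero misclassifications.
* Ties in the probability argmax break toward the lower grade, consistently
  in prediction and attribution.
* `t_test_vs_chance()` refuses zero-variance samples with guidance rather
  than returning a meaningless p-value.

## Problem sizes used by the test suite

Unit and property tests run on the fixtures; the multi-seed experiments use
the separable fixture (1,500 slices × 1,192 features) with a reduced
classifier — two blocks (64/32), dropout 0.2, learning rate 1e-3, 40 epochs,
SHAP background subsampled to 150 training slices — and 10 simulation seeds;
the null experiment uses 20 seeds with 1,000 bootstrap resamples. These
sizes are the package's own choice of a configuration that keeps the whole
suite comfortably reproducible on a laptop while leaving the scientific
claims intact; the package defaults (`pipeline_config()`) remain the full
operating point, and the acceptance script runs one complete pipeline at
those defaults. The spec-level constants — 62/19/19 fractions, 10%/2%
minima, 150 epochs, 10,000 resamples, the 75th percentile — are never
altered by tests.

## Known limitations

* Attribution is exact only in component space; back-projection onto
  features inherits PCA's linearity. Features correlated with signal
  features receive nonzero loadings on the same components and hence nonzero
  importance — the method ranks, it does not perform variable selection with
  error control.
* The bootstrap resamples slices, not patients; under strong within-patient
  correlation its intervals are anti-conservative (see the null-fixture
  discussion above).
* Hyperparameter search is out of scope; the tuned values ship as defaults
  and a config sweep is left to the user.
* No statistical significance is attached to importance scores, and
  stability across CV folds is not assessed.
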