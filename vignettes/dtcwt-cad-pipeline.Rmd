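---
title: "Methods: dual-tree complex wavelet features for brain MR slice classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-tree complex wavelet features for brain MR slice classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtcwtcad)
```

## The problem and the model

Whole-brain classification of MR images asks whether a subject's scan
belongs to the patient (AD) or control (HC) class without segmenting
regions of interest. The pipeline in this package treats each subject
as a stack of 2-D axial slices, summarises every slice by coarse-scale
oriented texture coefficients, compresses the subject-level feature
vector by PCA, and classifies the resulting scores with a small
feed-forward network under repeated stratified cross-validation.

Two modelling commitments drive the design:

* **Shift-invariant texture.** The critically sampled real DWT is
  notoriously shift-variant: moving an image by one pixel can reshuffle
  subband energy by tens of percent, so two scans of the same brain
  that sit slightly differently in the frame would get different
  features. The dual-tree complex wavelet transform (DTCWT) fixes this
  by running two real wavelet trees offset by half a sample and reading
  their outputs as the real and imaginary parts of complex
  coefficients; coefficient *magnitudes* then vary smoothly under
  translation, and six orientations (±15°, ±45°, ±75°) are resolved
  instead of the DWT's three. The test suite quantifies this contrast
  directly: level-3 magnitude energy of an impulse changes by < 5%
  under a one-pixel shift, while the plain DWT's changes by > 20%.
* **Multi-slice subjects.** A single slice may miss the disease focus,
  so each subject contributes a contiguous block of centre slices
  (default 32) and the per-slice features are concatenated in slice
  order.

## The transform

### Filters

Level 1 uses Kingsbury's near-symmetric 13/19-tap biorthogonal pair;
levels ≥ 2 use his 14-tap Q-shift pair. Both trees share the level-1
taps, tree B being tree A delayed by one sample — realised by sampling
phase rather than by convolving with shifted taps. At Q-shift levels,
tree B's filters are the exact time-reverses of tree A's, giving the
quarter-sample group-delay offset that makes the combined complex
wavelet approximately analytic (one-sided in frequency), which is the
source of both shift invariance and directional selectivity.

Two numerical refinements are applied to the published tap values, both
well inside their printed precision:

* the 19-tap level-1 dual is projected (constrained least squares,
  max change 5 × 10⁻⁸) onto the exact halfband conditions of its
  13-tap partner, making two-channel reconstruction exact at double
  precision rather than at the ~10⁻⁸ level of the printed decimals;
* the 14-tap Q-shift filter is projected (Gauss–Newton, max change
  1.3 × 10⁻⁷) onto exact orthonormality *and* an exact zero at the
  Nyquist frequency, so its high-pass annihilates constant images
  exactly and its DC gain is exactly √2.

### Boundary handling and inversion

Level 1 is computed undecimated with **symmetric (reflect) extension**:
the level-1 filters are symmetric and odd-length, so filtering commutes
with half-point reflection and the biorthogonal synthesis pair inverts
the stage exactly, with no boundary error at the image edge — the only
edge a brain slice actually has.

Levels ≥ 2 use **circular extension**. The Q-shift filters are
orthonormal but not linear-phase; under symmetric extension such
filters cannot achieve exact reconstruction without specially designed
boundary filters, whereas under circular extension the decimated
two-channel filter bank is an exactly orthogonal linear operator whose
inverse is its transpose. This choice is what delivers machine-precision
round trips (measured ‖x − inverse(forward(x))‖∞ ≈ 10⁻¹⁵, asserted
< 10⁻⁸ in the tests) at every level and size. By level 2 the signal
being wrapped is an already-smoothed quarter-resolution low-pass, and
synthetic brain slices have near-constant background at their borders,
so wrap-around effects on features are negligible.

Images whose sides are not divisible by 2^levels are padded once, up
front, by edge replication to the next multiple; the original extent is
recorded and the inverse crops back to it. (An equivalent
pad-per-level scheme exists; the upfront pad keeps every stage's
bookkeeping trivial and round trips exact.)

Every 1-D filtering step is linear, so it is materialised once per
(filter, length) as a dense matrix and applied by BLAS multiplication;
a cache keyed on (filter, length) means a stack of equally sized slices
pays construction cost once. A 5-level decomposition of a 256 × 256
slice takes ~10 ms.

### Orientation labels

The six complex subbands per level are formed from the four
row-tree × column-tree combinations by the unitary combinations
w<sub>x</sub>w<sub>y</sub> and w<sub>x</sub>conj(w<sub>y</sub>) with
w = u_A − i·u_B, scaled by 1/(2√2) so total pyramid energy tracks image
energy (within 1% on random images; exact at Q-shift levels). The
mapping from the two combinations to the ±θ labels is a pure
convention; it was fixed empirically from oriented-grating responses
and is pinned by the directionality tests. One subtlety is documented
in the code: the level-1 high-pass band aliases under decimation,
which flips the frequency sign resolved by the half-sample delay, so
the ± assignment of the ±15°/±75° fields at level 1 is reversed
relative to deeper levels. Level-1 ± discrimination is also inherently
weaker (the half-sample-delay Hilbert approximation is poorest for the
widest band); the classification features use only the coarsest level,
where discrimination is strong (≥ 60% of a matched grating's level
energy in one subband; 96% for a diagonal grating at its matched
level).

## Features

Per slice: intensities are rescaled to [0, 1] (8-bit inputs divided by
255, 16-bit by 65535; inputs already in [0, 1] untouched), bilinearly
resized to 256 × 256 (EBImage), decomposed to 5 levels, and the six
level-5 subbands are flattened in canonical orientation order
(+15, +45, +75, −15, −45, −75), row-major, real parts before imaginary
parts: 6 × 8 × 8 × 2 = 768 features. Per subject: the 32 centre slices
(contiguous window centred on the stack midpoint, lower-median start on
ties) contribute 32 × 768 = 24,576 columns. Demographics are *not*
appended by default — the feature-count arithmetic above excludes
them — but `with_demographics = TRUE` adds z-scored age, gender (M = 1),
education, socio-economic status and MMSE after the wavelet block.
A `magnitude_only` flag stores |z| instead of (Re, Im), halving the
count; it is off by default because 768 = 2 × 384 forces the
real/imaginary convention.

## Reduction

`fit_pca()` centres columns (no per-feature rescaling by default:
wavelet coefficients share a scale) and takes the SVD of the centred
matrix — the features × features covariance is never formed. With
*n* subjects, at most *n* − 1 components carry variance, e.g. a
126-subject matrix yields a 126 × 125 score matrix at full rank.
Component signs follow the largest-|loading|-positive convention so
results do not depend on the LAPACK backend. `select_components()`
returns the smallest k whose cumulative variance fraction reaches the
threshold (default 0.90); a fixed `pcs` override is available since a
practitioner may prefer to pick k by downstream accuracy.

During cross-validation the PCA is refitted on the nine training folds
of every split and applied to the held-out fold (`pca_mode =
"per-fold"`, the default): fitting the reduction on all subjects before
splitting leaks information from the validation fold into the training
representation. A `"global"` mode that fits once on everything is
provided for comparison with protocols that reduce first and validate
afterwards; it is mildly optimistic and not the default.

## Network and training

The classifier is a two-layer feed-forward network N_I–10–1: sigmoid
hidden units, a linear output unit, biases in both layers (a `no_bias`
flag reproduces the textbook equations without intercepts). Targets
are HC = 0, AD = 1 with decision threshold 0.5 (ties to AD). The loss
is the cost-weighted mean of squared errors
Σᵢcᵢ(Oᵢ − Tᵢ)² / Σᵢcᵢ; with all cᵢ = 1 it is the plain MSE, and the
default `"balanced"` setting takes cᵢ inversely proportional to class
frequency so that 28 patients are not drowned out by 98 controls.

Training is Møller's scaled conjugate gradient in the standard
formulation: curvature along each conjugate direction is estimated by a
one-sided finite difference of the gradient (σ = 5 × 10⁻⁵), a
Levenberg-style λ (initial 10⁻⁶, halved after well-modelled steps,
quadrupled after poor ones, clamped to [10⁻¹⁵, 10¹⁰⁰]) keeps the
quadratic model trustworthy, and no line searches are performed. The
loss trace over accepted iterates is non-increasing by construction and
the whole trajectory is reproducible from the seed. The analytic
backpropagated gradient is verified against central finite differences
(10⁻⁶ relative) in the tests. Weight initialisation is
Nguyen–Widrow-style: hidden input vectors scaled to magnitude
0.7·N_H^(1/N_I) with biases spread across the same range.

Hidden size defaults to 10; the information-theoretic sizing rule
sometimes used to justify that number is out of scope here, so the
value is a plain configuration default.

## Evaluation protocol

`stratified_folds()` deals each class's shuffled members into k folds
(sizes within one of each other, per-class counts within one;
remainders go to the currently smallest folds with random tie-breaks).
`run_cv()` repeats the k-fold split `runs` times (default 50 × 10);
within a run all held-out predictions are pooled into a single
confusion matrix before metrics are computed — with only 2–3 AD
subjects per fold, per-fold sensitivities are too granular to average
meaningfully. Metrics are reported as mean ± sample SD over runs;
fold-level metrics and their SD are also kept, since the two
aggregations genuinely differ on unbalanced data. A master seed spawns
per-run seeds so any single run is reproducible in isolation. AD is
the positive class throughout, and undefined ratios (zero
denominators) surface as `NaN` with a warning, never as silent zeros.

## The synthetic cohort generator

`make_cohort()` emulates the *structure* of a cross-sectional elderly
cohort: 28 AD / 98 HC by default, 32 axial PNG slices of 176 × 208 per
subject, demographics (age, gender, education, SES, MMSE, CDR) drawn to
match the class-wise summary statistics of such cohorts (e.g. MMSE
21.67 ± 3.75 in AD vs 28.95 ± 1.20 in HC; CDR 1 vs 0).

Each slice is an elliptical "brain" whose axes shrink towards the
stack poles, with a bright cortical rim and two dark para-midline
ventricular lobes. Subject-level random factors (axis scales, centre
shift, intensity gain, ventricle and rim multipliers) are perturbed
per-slice by small acquisition jitters, a low-order random cosine
"tissue texture" field, and per-pixel Gaussian noise (SD 0.03 on the
[0, 1] scale). The slice-level variation matters: with only a handful
of global nuisance modes, the leading principal components would
trivially absorb 90% of the variance and the component-selection rule
would keep too few dimensions to see anything; spreading nuisance over
many weak modes reproduces the gradual cumulative-variance profile
(roughly 20–26 components at the 90% threshold on default-size
cohorts) that whole-brain feature matrices actually show.

The AD signature is morphological, not photometric: ventricle axes are
multiplied by (1 + 0.36·effect_size) and the rim width divided by
(1 + 0.28·effect_size). Mean intensity is deliberately left
uninformative so the classifier must use spatial structure. The
coefficients define the unit of `effect_size`: 1 is a clearly visible
but noisy effect (about a one-σ shift against the subject-level
jitter), 2 is a saturating separation, 0 makes the classes
exchangeable in distribution so that pipeline accuracy has to fall to
chance. These three behaviours — chance at 0, monotone growth, near
perfection at 2 — are asserted by the tests.

What the generator does **not** emulate: real anatomy (gyri, tissue
boundaries, asymmetry), scanner physics (bias fields, Rician noise,
partial-volume effects), registration error beyond small translations,
or any correlation between demographics and image content. Passing
tests therefore certify the machinery — transform, reduction, training,
protocol — on data whose ground truth is known by construction, not
clinical performance on real MRI.

## Problem sizes used by the test suite

Tests scale the study geometry down to keep the default suite fast
while preserving every structural law: the feature-arithmetic checks
run one subject at the full 32-slice / 256 × 256 / 5-level geometry
(768 and 24,576 features) and a 126 × 24,576 Gaussian matrix for the
126 × 125 score-matrix law; the end-to-end checks run the full
126-subject cohort shape (28 AD / 98 HC) at 8 slices / 128 × 128 with
10 repeats of 10-fold cross-validation; the effect-size dial uses
20 AD + 40 HC at 10 slices / 96 × 96 with 3-seed averages. The
acceptance script regenerates the per-slice feature count at the full
256 × 256 / 5-level geometry.

## Known limitations

* The orientation-label convention (including the level-1 ± flip) is
  internal; coefficients are not numerically interchangeable with other
  DTCWT implementations, which differ in boundary rules, scaling and
  band order even among themselves.
* Circular extension at deep levels can, for images with strongly
  mismatched opposite borders, mix content across the wrap; for
  brain-style images with uniform background this is immaterial.
* Level-1 ± orientation discrimination is weak (a property of the
  half-sample-delay construction, not of this implementation); only
  coarse levels feed the classifier.
* The SCG implementation optimises the exact batch loss; no
  mini-batching, early stopping or regularisation beyond the network's
  small capacity is provided.
* With 2–3 positive subjects per validation fold, fold-level
  sensitivity is quantised in steps of ⅓–½; run-level pooling is the
  supported aggregation.
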