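# dtcwtcad

Computer-aided two-class classification of multi-slice 2-D brain MR
images, for researchers who want a compact, fully scripted baseline for
separating patients with Alzheimer's disease (AD) from healthy controls
(HC) using whole-slice texture rather than segmented regions of
interest.

The pipeline is

1. **Feature extraction** — each subject contributes a stack of axial
   slices (32 centre slices by default), each resized to 256 × 256 and
   decomposed with a 2-D **dual-tree complex wavelet transform**
   (DTCWT). Two parallel real filter-bank trees, whose filters differ
   by half a sample of group delay, combine into approximately analytic
   complex wavelets with six orientations θ ∈ {±15°, ±45°, ±75°} per
   level. Unlike the decimated real DWT, the subband *magnitudes* are
   nearly invariant to small image shifts, so the features do not
   change when a brain sits a pixel or two differently in the frame.
   The six coarsest (level-5) complex subbands are flattened (real and
   imaginary parts) into 6 × 8 × 8 × 2 = **768 features per slice**,
   i.e. 32 × 768 = **24,576 per subject**.
2. **Reduction** — principal-component analysis of the subjects ×
   features matrix (SVD of the centred matrix; with *n* subjects at
   most *n* − 1 components). The score matrix keeps the smallest
   number of components whose cumulative variance reaches a threshold
   (default 90%).
3. **Classification** — a two-layer feed-forward network *N*ᵢ-10-1
   (sigmoid hidden units, linear output) minimising a class-cost
   weighted mean squared error, trained with Møller's **scaled
   conjugate gradient** (conjugate directions, finite-difference
   curvature estimates, Levenberg-style scaling — no line searches).
   Class costs default to inverse class frequency, which keeps the
   minority AD class from being ignored in unbalanced cohorts.
4. **Evaluation** — repeated stratified 10-fold cross-validation
   (50 × 10 by default) with the PCA refitted inside each training
   fold; accuracy, sensitivity, specificity and precision are reported
   as mean ± SD over runs (AD is the positive class).

Because the imaging data this pipeline targets cannot be redistributed,
the package ships a seeded **synthetic cohort generator**: elliptical
brain-like slices with a bright cortical rim and dark ventricles, in
which the AD class receives a ventricular-enlargement / rim-thinning
signature scaled by a continuous `effect_size` dial. At
`effect_size = 0` the classes are exchangeable; at 2 they are cleanly
separable. Everything — images, demographics, fold draws, weight
initialisation — is reproducible from integer seeds.

## Worked example

```r
library(dtcwtcad)

dir <- file.path(tempdir(), "demo")
make_cohort(n_ad = 16, n_hc = 32, n_slices = 8, effect_size = 2,
            seed = 1, dir = dir)

features <- build_feature_matrix(read_subjects(dir), n_slices = 8,
                                 target = c(128, 128), levels = 5)
features
#> Feature matrix: 48 subjects x 1536 features (16 AD / 32 HC)

fit_pca(features, variance_threshold = 0.90)
#> PCA model: 1536 features, 47 components
#>   selected k = 17 (90.47% of variance at threshold 0.90)

run_cv(features, runs = 5, k = 10, seed = 1)
#> 5 x 10-fold stratified cross-validation (seed 1)
#>   accuracy    0.9958 +/- 0.0093
#>   sensitivity 1.0000 +/- 0.0000
#>   specificity 0.9938 +/- 0.0140
#>   precision   0.9882 +/- 0.0263
#>   recall      1.0000 +/- 0.0000
```

Each row of the feature matrix is one subject (8 slices × 192
level-5 coefficients at this reduced 128 × 128 geometry). The PCA
keeps 17 components to cover 90% of the variance, and the
cross-validated network separates the strongly contrasted synthetic
cohort almost perfectly; at `effect_size = 0` the same pipeline sits at
chance.

The transform itself is exposed directly:

```r
x <- make_phantom("grating", c(128, 128), orientation = 45, frequency = 0.14)
pyr <- dtcwt_forward(x, levels = 4)
en <- vapply(pyr$levels[[3]], function(b) sum(Mod(b)^2), numeric(1))
round(en / sum(en), 3)
#>   +15   +45   +75   -15   -45   -75
#> 0.012 0.963 0.012 0.004 0.005 0.004
```

A 45° grating concentrates 96% of its level-3 subband energy in the
+45° band, and `max(abs(dtcwt_inverse(pyr) - x))` is at round-off
(~1e-12): the transform is perfectly invertible.

## Command line

`inst/cli/dtcwtcad.R` wires the stages into shell subcommands:

```sh
cli=$(Rscript -e 'cat(system.file("cli","dtcwtcad.R", package="dtcwtcad"))')
Rscript $cli simulate --n-ad 28 --n-hc 98 --slices 32 --effect 1.0 --seed 1 --out data/
Rscript $cli extract  --data-dir data/ --slices 32 --levels 5 --size 256 --out features.csv
Rscript $cli reduce   --features features.csv --variance 0.90 --out scores.csv
Rscript $cli evaluate --features features.csv --runs 50 --folds 10 --seed 1 --out report.json
Rscript $cli pipeline --data-dir data/ --seed 1          # everything at once
Rscript $cli sweep-levels --data-dir data/ --s-values 1,2,3,4,5
```

`dtcwt-decompose --image slice.png --levels 5 --out dir/` dumps
per-subband magnitude images and raw coefficients for inspection.

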