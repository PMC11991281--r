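---
title: "From UAV imagery to tea physiology: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From UAV imagery to tea physiology: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teacanopy)
```

`teacanopy` implements a complete desk-scale analysis pipeline linking
drone imagery of tea plantations to three physiological parameters: the leaf
area index (LAI, one-sided leaf area per unit ground area), the photochemical
reflectance index (PRI = (R531 − R570)/(R531 + R570), tracking
xanthophyll-cycle energy dissipation), and the quantum yield of photosystem II
(ΦPSII = (Fm′ − Fs)/Fm′, the fraction of absorbed light used for PSII
photochemistry). Because no field imagery or plot-level measurements are
publicly deposited for this system, the package pairs every analysis stage
with a seeded synthetic generator whose ground truth is known, so each stage
is testable end to end.

## The pipeline

1. **Scene simulation** (`generate_scene`): contiguous canopy blobs over a
   soil/weed background with class-specific Gaussian band reflectance, and an
   exact ground-truth mask.
2. **Canopy segmentation** (`segment_canopy`): SLIC superpixels, per-superpixel
   vegetation-index means, Otsu thresholds with optional dual limits and
   manual overrides.
3. **Index features** (`compute_feature_vector`): 19 colour indices (RGB) or
   50 multispectral indices (blue/green/red/red-edge/NIR), averaged over
   canopy pixels per designed square zone (DSZ, a 2 m × 2 m plot).
4. **Feature ranking** (`rank_features`): Pearson |r|, minimum-redundancy
   maximum-relevance (MRMR), and gray relational analysis (GRA).
5. **Regression sweep** (`incremental_sweep`): eight regressors refit over
   the top-k ranked features, k = 1..K, with 3-fold cross-validation and
   exhaustive grid search at every k.
6. **Parsimony and statistics** (`parsimony_select`, `describe_physiology`,
   `compare_farming_methods`, `compare_elevations`, `grouped_error_report`).

`run_pipeline()` wires the stages behind a single configuration object and
writes CSV artifacts plus a JSON manifest (configuration hash, seed, class
pixel counts), so repeated runs are auditable and byte-reproducible. The
pipeline is exposed as R functions rather than a shell tool: an analysis of
this kind is driven from scripts and the configuration object, and
`scripts/acceptance.R` shows the intended entry-point style.

## The synthetic generator: what it emulates, and what it does not

The generator emulates the features of the field setting that the analysis
actually exercises:

* **Canopy geometry.** Masks are grown from random seed pixels by
  multi-source Eden-style waves, then smoothed with three 3 × 3 majority
  passes and trimmed/extended to the exact target pixel count. We chose wave
  growth with exact-count trimming over "grow until approximately the target
  fraction" because it preserves spatial contiguity *and* makes the canopy
  fraction exact, which downstream tests can then assert tightly.
* **Spectral contrast.** Default class spectra give strong vegetation/soil
  contrast (canopy NIR 0.45 vs red 0.05; background NIR 0.20 vs red 0.15).
  A configurable per-DSZ *vigor* axis (`vigor_spectra`) interpolates canopy
  band means between a sparse/stressed endpoint and a dense/healthy endpoint.
  Without between-scene reflectance variation, zonal-mean indices are nearly
  constant across DSZs and any planted physiological relation degenerates to
  noise; vigor is the minimal realistic between-plot axis that makes the
  regression stage meaningful.
* **Measurement protocol.** PRI and ΦPSII are derived from ten simulated leaf
  readings per DSZ — reflectance pairs and fluorescence yields pushed through
  the forward formulas — and averaged, mirroring the leaf-clip protocol.
  With zero noise the outputs equal the planted relation exactly.
* **Physical envelopes.** Generated parameters are clipped to field envelopes
  (LAI 0.13–10.37, PRI −0.077–0.0766, ΦPSII 0.0729–0.8648) with every clip
  event logged; ΦPSII cannot physically exceed ~0.85.

It does **not** emulate radiative transfer, orthomosaic stitching artifacts,
shadows, sensor noise beyond additive Gaussian, or the correlation structure
of real multispectral indices. Consequently, passing recovery tests show that
the *algorithms* are implemented correctly and identify planted structure at
realistic noise levels; they do not certify field-data accuracy.

The benchmark fixture for ranking/regression tests
(`generate_feature_table` with `fixture_truth`) plants two causal features —
one saturating (`1 − exp(−3x)`), one linear — among 20 independent noise
features, with noise calibrated at generation time to a signal-to-noise ratio
of 2 (noise sd = sd(signal)/2). The saturating link reflects the
asymptotic response of canopy indices to leaf area and gives tree ensembles a
genuine nonlinearity to exploit.

## Segmentation: numerical choices

* **SLIC distance.** We use the original normalised form
  `D² = (d_colour/m)² + (d_space/S)²` with `S = sqrt(pixels/k)`. The
  compactness `m` is read on the colour scale of the feature space: 20 for
  RGB imagery converted to CIE Lab, 0.05 for 5-band reflectance (Lab has no
  5-band definition, so reflectance vectors are used directly — their scale
  is two orders of magnitude smaller, hence the smaller compactness). The
  unnormalised variant `dc² + m²(ds/S)²` makes the spatial term negligible at
  m = 0.05 and produces speckled superpixels.
* **Connectivity.** After local k-means, connected components of each label
  at least S²/4 pixels large become superpixels in their own right; smaller
  fragments are absorbed into the adjacent region with the closest mean
  colour. Merging *every* detached fragment into the largest adjacent
  superpixel — the simpler rule — destroys class purity whenever a canopy
  island is stranded inside background, and capped synthetic mask IoU near
  0.81; the size-gated rule recovers IoU ≈ 0.99.
* **Otsu on superpixel means.** Thresholding happens after superpixel
  averaging (the workflow's defence against salt-and-pepper noise), so its
  inputs are tens-to-hundreds of values. For up to 1000 distinct values the
  maximiser of between-class variance is found exactly over midpoints of
  consecutive sorted distinct values (ties: mean of maximisers); a 256-bin
  histogram path exists for pixel-scale inputs. Exact search makes the
  implementation provably equal to a brute-force oracle.
* **Dual indices combined by AND.** A superpixel is canopy only if it passes
  the Otsu threshold for *every* segmentation index (RGBVI ∧ VARI for RGB,
  EVI ∧ RVI for multispectral) and lies within any configured
  `[lower, upper]` window. AND is the conservative reading of using two
  indices "to exclude non-tea areas"; sensitivity to OR can be explored via
  single-index configurations.
* **Defaults.** `n_superpixels = pixels/400` (≈16 cm patches at the 0.8 cm/px
  default resolution); 10 SLIC iterations; deterministic given scene and
  configuration.

## Index registry

The registry ships 19 colour indices and 50 multispectral indices as
formula strings over named bands, loadable and auditable from CSV
(`read_index_registry`). Colour formulas are evaluated on digital numbers
normalised to [0, 1] and on chromatic coordinates r = R/(R+G+B) (etc.) where
the published formula requires them — the standard convention for
visible-light vegetation indices. EVI uses the canonical constants
(2.5, 6, 7.5, 1). Division by zero or a negative square-root argument marks
the pixel invalid (`NA`); invalid pixels are excluded from both the zonal
mean numerator and the pixel count, rather than being patched with an
epsilon, because epsilon fudges bias zonal means silently.

## Feature ranking

* **Pearson** uses `stats::cor`; ranking is by |r|, errors on zero-variance
  input.
* **MRMR** maximises, at each greedy step, mutual information with the target
  minus the mean mutual information with the already-selected set. Mutual
  information is a plug-in estimate (nats) on equal-frequency bins,
  `bins = ceiling(sqrt(n))` by default; equal-frequency binning is robust to
  the skewed distributions vegetation indices typically have. The bin count
  is exposed for sensitivity analysis. Negative objectives are allowed, and
  selection runs to exhaustion so a full ranking is returned.
* **GRA** min-max normalises every sequence to [0, 1], computes per-point
  absolute differences from the target, global Δmin/Δmax over all sequences,
  gray relational coefficients with distinguishing coefficient ρ = 0.5, and
  ranks by their mean. If the lone feature matches the target exactly
  (Δmax = 0) the coefficient is defined as 1, its analytic limit.
* Ties everywhere are broken by input column order, for reproducibility.

## Regression sweep

Eight regressors: 2nd-degree polynomial regression (PR), partial least
squares (PLSR, via `mixOmics`), lasso (LR) and ridge (RR, via `glmnet`),
decision tree (DTR, via `rpart`), random forest (RFR, via `ranger`), XGBoost,
and LightGBM-style leaf-wise histogram boosting. The last is implemented with
xgboost's `grow_policy = "lossguide"` + `max_leaves`, which is precisely the
leaf-wise growth strategy that distinguishes LightGBM, and accepts the same
grid (`num_leaves`, `learning_rate`, `n_estimators`).

Default grids follow the tuned ranges: α ∈ {0, 0.01, 0.1, 1, 10, 100} for
LR/RR; learning rate ∈ {0.001, 0.005, 0.01, 0.05, 0.1} and trees 50–150 step
25 for the boosters; tree depths 4–100 (DTR) and 3–50 (RFR) with
`min_samples_split` 5–50 step 5; PLSR components 2..N. Integer ranges without
a stated increment are enumerated at step 1. `rpart` caps depth at 30; deeper
grid entries are mapped to 30 (identical fits at these data sizes) and
deduplicated. Entries infeasible for the data — e.g. more PLSR components
than features — are skipped and logged. With a single feature PLSR collapses
to simple least squares, its analytic 1-component limit.

Reported accuracy is the mean over the 3 cross-validation folds (shuffled,
seeded, unstratified — the targets are continuous). No separate held-out
split is used: cross-validation is the fully specified protocol, and the
out-of-fold predictions of the winning configuration are returned for
residual analysis. PR solves its degree-2 expansion by singular-value
pseudoinverse so collinear designs return a minimum-norm solution with a
conditioning warning instead of failing — PR's instability on collinear index
sets is an expected, reported behaviour, not an error.

`parsimony_select` takes the best cross-validated R² on an accuracy curve,
sets 95% of it as the threshold, and returns the smallest feature count
meeting the threshold. When the best R² is non-positive the fractional
threshold is ill-defined and no reduction is attempted.

## Field statistics

Descriptives use the sample (n − 1) standard deviation and CV = StDev/Mean.
Farming methods are compared by a two-sample t-test, pooled or Welch
according to a Brown–Forsythe/Levene pre-test on medians at α = 0.05 (the
Welch fallback needs a homogeneity gate; Levene-on-medians is the robust
default). Elevations are compared by one-way ANOVA or Welch ANOVA on the
same gate, with Tukey HSD or Games–Howell post-hoc tests respectively,
compressed to a compact letter display. Letters are the maximal cliques of
the pairwise non-significance graph (found with `igraph`), ordered by
descending group mean, which makes the letter partition exactly derivable
from the significance matrix. Grouped prediction errors report RMSE and mean
signed error per elevation × season × farming-method cell; the sign of the
mean error flags systematic over- or under-estimation. Seasons derive from
months by Northern-Hemisphere meteorological boundaries (Mar–May spring,
etc.), appropriate for the subtropical study setting.

## Problem sizes and verification

The test-suite and acceptance-script problem sizes are the package's choice
of a desk-scale study: 96 × 96 px scenes (20 seeds) for segmentation
recovery; 500 DSZs × 22 features × 10 seeds for ranking/regression recovery;
100 random instances for each oracle-equivalence check (MRMR greedy vs
exhaustive objective evaluation; Otsu vs brute-force variance maximisation);
500 null simulations for t-test calibration. Published-summary audits
(CV recomputation, parsimony thresholds, family comparisons) use the
summary tables shipped in `inst/extdata`. Reduced hyperparameter grids are
used in the recovery benchmarks; grids are data, and the qualitative
contrasts being tested (boosting over polynomial regression, causal features
over noise) are insensitive to grid granularity.

## Known limitations

* Synthetic scenes have sharp class boundaries and no mixed pixels, shadows
  or registration error; real IoU against hand-drawn masks will be lower.
* The MRMR estimator is discretisation-based; continuous (k-NN) estimators
  can rank differently on small samples.
* The LightGBM slot reproduces the leaf-wise histogram strategy but not
  LightGBM's exact split finding, sampling, or regularisation details.
* Published-summary audits verify arithmetic consistency of reported
  accuracies, not the accuracies themselves; reproducing the field R² values
  would require the original imagery and measurements.
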