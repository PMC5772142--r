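---
title: "Connectivity-profile analysis with streamconn: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectivity-profile analysis with streamconn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`streamconn` asks a question about cortical organisation — does a
category-selective occipito-temporal area couple more strongly with the
dorsal "vision-for-action" parietal circuit or with the ventral
"vision-for-identification" temporal circuit? — and answers it with five
linked analyses on multimodal MRI: localizer GLM, seed-based resting-state
connectivity, fingerprint matching, k-NN stream classification, and a
tractography path-count statistic. This vignette explains each model, its
assumptions and parameters, the numerical conventions the implementation
fixes, and what the synthetic-data tests do and do not establish.

## The GLM engine

All voxelwise regressions share one engine (`fit_glm()`,
`seed_beta_map()`):

* **Drift.** A discrete-cosine basis with all periods longer than the
  high-pass cutoff (default 128 s) is estimated jointly with the design.
  For a run of $T$ volumes at repetition time $\Delta t$ this adds
  $\lfloor 2T\Delta t / 128 \rfloor$ orthonormal columns plus an intercept.
* **Autocorrelation.** Residual autocorrelation is modelled as a
  first-order autoregressive process with one pooled coefficient: the lag-1
  autocorrelation of the OLS residuals, pooled over voxels, corrected for
  the deflation caused by projecting out $p$ regression columns
  (approximately $(1+\rho)\,p/T$), then applied as a prewhitening filter to
  data and design before coefficients are re-estimated. Pooling is a
  deliberate desk-scale simplification: per-voxel AR estimation adds noise
  at the run lengths used here and the pooled estimate is what the test
  suite calibrates (the Monte-Carlo check at $T = 500$, $\rho = 0.4$
  recovers the coefficient within 0.05).
* **Contrasts.** $t = c^\top\hat\beta / \sqrt{\hat\sigma^2\, c^\top
  (X^\top X)^{-1} c}$ with $T - \mathrm{rank}(X)$ degrees of freedom.
  Voxels with zero residual variance get signed infinity and are logged;
  a zero contrast of a zero estimate is 0, not NaN.

The canonical HRF is the conventional double-gamma (response peak 6 s,
undershoot 16 s, peak:undershoot ratio 6), convolved at 16× microtime
resolution and sampled at volume times; each condition contributes the HRF
column and its temporal-difference derivative. Derivative columns are
nuisance only — contrasts weight the main HRF columns.

## Multi-echo combination

`combine_echoes()` weights each echo per voxel by $w_n \propto
\mathrm{TE}_n \times \mathrm{tSNR}_n$, with tSNR estimated from the first
30 volumes, normalized to sum to one, and applied to the whole run. Voxels
with a zero-variance estimation window fall back to TE-proportional
weights. The identity case (identical echoes) returns the input exactly
because the weights sum to one.

## Seed timeseries and connectivity maps

The seed signal is the **first eigenvariate** of the voxel × time matrix of
a 4 mm sphere: the leading principal component after per-voxel mean
removal. Two conventions make it deterministic: the sign is chosen so the
mean voxel loading is positive, and the component is rescaled to the
standard deviation of the ROI mean timeseries. The second convention
matters for interpretation: a seed whose voxels load with weight 1 on a
unit-variance latent signal yields a seed regressor on that latent's scale,
so a target voxel with coupling $a$ recovers $\hat\beta \approx a$.

Connectivity maps regress every voxel on the seed regressor plus 15
nuisance columns: six rigid-body motion parameters, their first-order
temporal differences, and mean signals of white-matter, CSF and
out-of-brain compartment masks. Compartment signals are plain means within
supplied masks. In the noiseless case the seed beta is invariant (to 1e−8)
to adding any linear combination of nuisance columns to the data.

## Group maps and cluster inference

Group analyses are one-sample (or paired-difference) t tests across
subjects. Clusters are formed at an uncorrected two-sided $p < 0.001$
threshold with 26-connectivity (faces, edges, corners; the common
volumetric convention), and evaluated by **cluster mass** against the
permutation distribution of the maximum cluster mass under random sign
flips of the subject maps. This nonparametric substitute for random-field
theory is exact under the symmetric-null assumption and is calibrated in
the test suite (family-wise error within the binomial band around 5% over
null simulations). The exploratory whole-brain stage operates on smoothed
maps (6 mm FWHM separable Gaussian by default); ROI and fingerprint stages
use unsmoothed betas.

## Fingerprint matching

A fingerprint is the vector of mean betas over 13 target spheres (4 mm,
fixed arm order; the packaged coordinate table stores unsigned X magnitudes
resolved per hemisphere, left = −X). Negative arms are set to zero per
subject before group summarizing — the profile is read as positive coupling
strength. Two fingerprints are compared by city-block distance after a
**joint** affine normalization mapping the minimum of the combined arms to
0 and the maximum to 1. The permutation null swaps each subject's pair of
region labels independently, recomputes the group means, re-normalizes the
permuted pair and recomputes the distance — normalization inside the loop,
so the observed range cannot bias the test. With $n_\mathrm{perm} = 5000$
and the add-one convention $p = (1 + \#\{d^\ast \ge d\}) / (1 +
n_\mathrm{perm})$, the smallest attainable p is $1/5001$ and p is never 0.
The observed statistic is computed on group-mean fingerprints (the
per-subject matrices are the permutation units); per-arm attribution uses
a logistic regression of region label on arm value across stacked
per-subject observations, Wald p, uncorrected, with perfect separation
flagged (detected both from fitting warnings and from fitted probabilities
matching the labels exactly) rather than fatal.

## Stream classification

Training items are the whole-brain connectivity patterns of the 22 atlas
parcels (13 dorsal, 9 ventral), each computed with the parcel's
eigenvariate as seed by the same GLM used for the seed maps, flattened on a
shared voxel set. Classification is k-nearest-neighbour under city-block
distance; `k` sweeps 2…8, one less than the ventral class size, so the
minority class can always win a vote. A tied vote at even `k` goes to the
label of the single nearest item — deterministic and local. The 13:9 class
imbalance is left as is (it reflects the parcellation); its consequence is
documented by a test: under label-shuffled training sets the dorsal
probability of a random query approaches the dorsal class share 13/22.
Outcomes (dorsal = 1, ventral = 0) are compared across seeds by Friedman's
rank test blocking on subject × k cells, midrank ties; fully tied blocks
(all outcomes identical) are reported as statistic 0, p = 1 rather than
0/0.

## Tractography strength

Path counts from the 20 grey/white boundary voxels nearest each seed
(world-mm distance, lexicographic tie-break) are summarized per
(subject, seed, hemisphere, stream) as the mean of
$\log_{10}((\mathrm{count} + 1)/\mathrm{total})$. The pseudo-count keeps
zero-count cells finite; normalization by the seed's total valid
streamlines makes the statistic invariant to the number of samples drawn;
the log compresses the heavy right tail of count distributions. Base,
pseudo-count and normalization are arguments of one function
(`tract_strength()`) because field conventions vary. Strengths feed
repeated-measures seed × stream (× hemisphere) ANOVAs with
Bonferroni-corrected 2 × 2 follow-ups.

## Repeated-measures ANOVA

`repeated_anova()` fits `aov()` with an `Error(subject/...)` stratum per
within-subject term, valid for the balanced complete layouts the pipeline
produces (every subject × factor cell exactly once; anything else is an
error listing the imbalance). For two-level designs the interaction F
equals the squared paired t on the difference-of-differences, which the
test suite verifies directly.

## The synthetic cohort: what it emulates and what it does not

`synthetic_cohort_config()` plants the minimal structure under which every
downstream contrast is defined and recoverable:

* two independent unit-variance AR(1) **latent network signals** (dorsal,
  ventral; autocorrelation 0.3 by default);
* three **seed sites** (4 mm spheres) with graded loadings on the latents —
  EBA-like (0.8, 0.3), LOC-like (0.5, 0.6), FBA-like (0.2, 0.8) — the
  qualitative pattern the interaction and classification analyses target;
* a **toy parcellation**: the 22 packaged parcel names tiled on a superior
  (dorsal) and an inferior (ventral) axial slab, coupled to their stream's
  latent at loading 0.6;
* **confounds with structure to remove**: random-walk motion parameters
  injected through fixed random spatial weight maps, and geometric
  white-matter/CSF/out-of-brain compartments carrying dedicated AR(1)
  nuisance signals, with a small white-matter leak into all voxels;
* voxelwise AR(1) Gaussian noise (SD 1), per-subject seed-site jitter of
  ±1 voxel, and fully recorded ground truth.

Localizer runs add condition-specific amplitudes at the seed sites
(bodies-selective at the EBA/FBA-like sites, object-selective at the
LOC-like site), with a Gaussian spatial profile (5 mm FWHM) so the planted
peak is unique, convolved with the same canonical HRF the analysis uses.
Default amplitudes give contrast peak t values around 10 over a 200-volume
run — the planted signal-to-noise typical of block-design 1-back
localizers. Tract counts are multinomial draws over
{dorsal, ventral, lost} with per-seed rates (defaults ventral-dominant for
all seeds with graded dorsal affinity, matching the anatomical situation
where all occipito-temporal seeds sit nearer the ventral targets), a
per-subject lognormal rate perturbation (SD 0.15), and 5000 streamlines
per seed.

What the generator does **not** emulate: spatial autocorrelation of noise,
MR physics (susceptibility, distortion, slice timing), anatomical geometry,
distance-dependent tractography bias, or inter-regional heterogeneity
beyond two latents. Passing tests therefore show that the statistics are
implemented correctly and are well calibrated under their own assumptions
— not that the pipeline's conclusions transfer to any particular real
dataset.

## Problem sizes used by the test and acceptance suites

Simulation sizes were chosen once to keep the full suite at desk scale
while leaving the planted effects comfortably detectable:

* default cohort: 24 × 28 × 24 voxels at 2 mm, 200 volumes, TR 2 s,
  8 subjects;
* interaction power loops: 200 cohorts of 16 subjects on a 12 × 12 × 10
  grid, 80 volumes;
* classification ordering loops: 100 cohorts of 4 subjects on a
  16 × 16 × 12 grid, 100 volumes, noise SD 0.8, with a group-level
  training set computed from one reference run (training patterns per
  subject are supported; the group-level option is used in the loops);
* coupling recovery: 50 runs of 500 volumes on a 12 × 12 × 10 grid;
* permutation calibration: 500 null datasets × 1000 permutations,
  16 subjects, 13 arms.

## Numerical conventions and degenerate inputs

* Sphere ROIs include boundary voxels (distance ≤ radius, in world mm, so
  anisotropic grids are correct); a 4 mm sphere on a 2 mm isotropic grid
  centred on a voxel centre has exactly 33 voxels. Voxel indices are
  0-based internally; all user-facing coordinates are world mm (RAS+).
* Peak localization and boundary-voxel selection break ties by
  lexicographic voxel order — platform-independent determinism.
* An empty sphere (centre outside the field of view) is an explicit
  degenerate-mask error, as are empty parcels, all-constant ROIs
  (zero-variance eigenvariate), rank-deficient designs (the error names
  the collinear columns), missing ANOVA cells, and a normalization range
  of zero (all arms equal across a fingerprint pair).
* Target spheres are not clipped to a grey-matter mask (the analysis that
  motivated the package did not state any clipping); fingerprint
  zero-masking is the only masking applied, and it is a flag.

## Known limitations

* The pooled-AR(1) + discrete-cosine engine is a deliberate simplification
  of full ML noise modelling; per-voxel AR fitting is not implemented.
* Cluster inference assumes sign-symmetric subject maps under the null.
* `aov()`-based repeated measures assumes sphericity; no
  Greenhouse–Geisser correction is applied (with 2–3 factor levels at the
  planted effect sizes this is immaterial, but real data may need it).
* The classifier offers no rebalancing or feature selection by design —
  the contract is the published procedure, not classification performance.
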