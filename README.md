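# streamconn

Connectivity-profile analysis of category-selective visual areas in R.

## The problem

The extrastriate body area (EBA) responds selectively to images of human
bodies and has traditionally been grouped with the perceptual regions of the
ventral "vision-for-identification" stream, alongside the fusiform body area
(FBA) and the object-selective lateral occipital complex (LOC). Whether EBA
instead participates in the dorsal "vision-for-action" circuit is an
anatomical question: does its connectivity profile look more like a posterior
parietal (dorsal) region or an inferior temporal (ventral) one?

`streamconn` implements the analysis pipeline used to answer that question
from multimodal MRI, as a tested, reusable R package:

1. **Seed localization** — block-design fMRI GLM with a canonical
   double-gamma HRF and its temporal derivative, discrete-cosine high-pass
   filtering (128 s cutoff), pooled AR(1) prewhitening, linear contrasts, and
   peak selection inside a restricted search sphere.
2. **Seed-based resting-state connectivity** — the first eigenvariate of a
   4 mm seed sphere regressed against every voxel alongside 15 nuisance
   regressors (6 motion + 6 motion derivatives + white-matter, CSF and
   out-of-brain compartment means), yielding per-subject beta maps
   `y_v = β_v s + Xγ + ε`, with group-level cluster inference by sign-flip
   permutation (cluster-forming p < 0.001, cluster-mass FWE p < 0.05).
3. **Connectivity fingerprints** — per-seed vectors of mean beta over 13
   target ROIs; pairs of fingerprints are jointly normalized to [0, 1] and
   compared by city-block distance `d(a, b) = Σᵢ |aᵢ − bᵢ|` against a null of
   5000 per-subject label permutations (normalization recomputed inside each
   permutation), with per-arm logistic attribution of observed differences.
4. **Stream classification** — a k-nearest-neighbour classifier (city-block
   metric, k = 2…8) labels each seed's whole-brain beta map dorsal or ventral
   by matching it to the connectivity patterns of 22 atlas parcels
   (13 dorsal, 9 ventral); outcomes are compared with Friedman's rank test.
5. **Tractography strength** — streamline path counts from the 20
   white-matter boundary voxels nearest each seed are converted to
   `log10((count + 1) / total)` and analysed with repeated-measures
   seed × stream (× hemisphere) ANOVAs.
6. **Synthetic cohorts** — a generator plants two latent AR(1) network
   signals (dorsal, ventral), seed sites with graded loadings, parcel
   couplings, motion and compartment confounds, localizer block activations
   and multinomial tract counts, recording all ground truth, so the whole
   pipeline is testable without any data download.

## Worked example

```r
library(streamconn)

cfg <- pipeline_config(
  cohort = synthetic_cohort_config(n_subjects = 4,
                                   grid_shape = c(16, 16, 12),
                                   n_volumes = 100, noise_sd = 0.8,
                                   rng_seed = 1),
  n_perm = 500, n_targets = 6, rng_seed = 1)
res <- run_pipeline(cfg, "runs/demo")

res$connect$anova
#>          effect         F df1 df2         ss           p
#> 1          seed 16.743204   2   6 0.12410155 0.003508414
#> 2        stream  0.182138   1   3 0.01771336 0.698316673
#> 3 seed x stream  6.876587   2   6 0.73824397 0.028024834

res$classify$dorsal_probability
#>   seed dorsal_probability
#> 1  EBA          0.9642857
#> 2  FBA          0.2500000
#> 3  LOC          0.6071429

res$fingerprint$tests
#>   seed_a seed_b observed_d           p n_perm
#> 1    EBA    LOC  2.3007258 0.129740519    500
#> 2    EBA    FBA  2.7782445 0.001996008    500
#> 3    LOC    FBA  0.7164354 0.512974052    500
```

The seed × stream interaction (F(2,6) = 6.88, p = 0.028) says the three
planted seeds couple differently to the dorsal and ventral target
aggregates; the dorsal probabilities show the classifier placing the
EBA-like seed with the dorsal parcels (0.96), the FBA-like seed with the
ventral parcels (0.25), and the LOC-like seed in between (0.61) — the
planted graded dorsal affinity; and the fingerprints of the most dorsal and
most ventral seeds differ reliably under the permutation test (p = 0.002).
Stage outputs
(seed locations, stream strengths, fingerprints and their permutation
tests, classification outcomes, tract strengths and ANOVAs) are written as
TSV files with a JSON manifest under `runs/demo/`.

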