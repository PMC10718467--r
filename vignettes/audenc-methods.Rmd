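---
title: "Methods: encoding models, reliability correction, and representational similarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: encoding models, reliability correction, and representational similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(audenc)
```

`audenc` compares hierarchical stimulus-computable models of auditory
processing against (synthetic) voxel responses to natural sounds. This
vignette documents the statistical model, the assumptions baked into each
module, the default parameter values with their units, and the numerical
decisions that affect results.

## 1. The scientific setting

A listener hears a set of short natural sounds while fMRI records the
response of each voxel in auditory cortex; every sound is presented in three
scanning sessions. A candidate model (a multi-stage feature hierarchy, or
the fixed spectrotemporal filterbank baseline) converts each sound waveform
into one feature vector per stage. Two questions are asked:

1. **Encoding**: how much of each voxel's *reliable* response variance does
   each model stage predict under cross-validated ridge regression?
2. **Representational geometry**: how similar is the model's
   representational dissimilarity matrix (RDM) to the brain's, relative to a
   between-participant noise ceiling?

Because real recordings are not shipped with the package, a synthetic
generator produces hierarchies and voxels with *known ground truth* (true
source stage per voxel, true test-retest reliability), so every estimator
can be validated by parameter recovery.

## 2. Cochleagram front end

`build_erb_filterbank()` constructs `n_filters = 211` half-cosine filters
with centers equally spaced on the ERB-number scale (Glasberg–Moore:
`erb = 9.265 * log(1 + f / (24.7 * 9.265))`) between `f_low = 50` Hz and
`f_high = 10000` Hz. The 203 interior filters are bandpass; 4 lowpass and 4
highpass filters extend the ends so the *squared* frequency responses sum
to a constant (perfect-reconstruction tiling). `f_high` may equal, but not
exceed, the Nyquist frequency.

`compute_cochleagram()` then:

1. filters the waveform in the frequency domain (zero phase, via the real
   FFT),
2. takes Hilbert-envelope magnitudes of each subband (analytic signal),
3. compresses envelopes as `env^0.3` (`compression = 0.3`, simulating
   basilar-membrane compression),
4. lowpass-filters and decimates the envelopes to `env_rate = 200` Hz.

Decimation uses a windowed-sinc (Hamming) FIR kernel of length
`K = 10 q + 1`, where `q = sample_rate / env_rate` is the decimation
factor, applied in "valid" mode with **no zero padding**: the number of
output frames is `floor((L - K) / q) + 1` for an `L`-sample waveform. A
2-second waveform at 20 kHz (`L = 40000`, `q = 100`, `K = 1001`) therefore
yields exactly 390 time points. Valid-mode decimation was chosen over
padded filtering so that no frame mixes signal with artificial zeros; the
cost is a kernel-length worth of samples at the edges.

## 3. Spectrotemporal modulation baseline

`build_modulation_filterbank()` builds the stimulus-computable baseline
model operating on the cochleagram: complex Gabor filters tuned to spectral
modulation (scales, cycles/ERB: 0.0625–2 in octave steps, 6 values) and
temporal modulation (rates, Hz: 0.5–64 in octave steps, 8 values). Joint
spectrotemporal filters come in upward and downward sweep directions
(`6 × 8 × 2 = 96`), plus 6 purely spectral and 8 purely temporal filters:
**110 filters** total (`include_dc = TRUE` adds a DC filter, 111).
Gaussian envelopes use `sigma = 1 / frequency` in each dimension, and the
up/down pair is formed as `Re[g_spectral ⊗ conj(g_temporal)]` versus
`Re[g_spectral ⊗ g_temporal]`. `compute_modulation_features()` convolves
each filter with the cochleagram (FFT, zero-padded to linear convolution),
squares, and averages over time, giving one energy per filter per cochlear
channel — a feature vector of length `110 × 211 = 23210` per sound.

## 4. Synthetic data generator

The generator's defaults *are* the simulated study conditions; they are not
meant to be tuned per analysis.

| function | key defaults | meaning |
|---|---|---|
| `generate_stimuli()` | `n_sounds = 165`, `duration_s = 2`, `sample_rate = 20000` | band-limited noise-plus-tonal stimuli, all normalized to RMS 0.1 |
| `generate_model()` | `n_stages`, `units_per_stage`, rectified linear stages | random linear-rectified hierarchy on top of a feature matrix |
| `generate_voxels()` | `n_scans = 3`, `noise_sd` | each voxel reads one stage through a nonnegative weight vector; i.i.d. Gaussian scan noise |
| `hierarchy_voxel_plan()` | ROIs `primary`, `anterior`, `lateral`, `posterior` | primary voxels read early stages, non-primary read late stages |
| `generate_components()` | 6 components | low-rank "component" responses with known source stages |

With scan noise `sigma_n` and unit-variance signal, the ground-truth
test–retest correlation of single scans is
`rho_true = 1 / (1 + sigma_n^2)` and of the 3-scan average
`rho_avg = 1 / (1 + sigma_n^2 / 3)`; both are stored in the voxel tensor's
`ground_truth` so recovery tests have analytic targets.

**Realism limits.** The generator produces i.i.d. Gaussian noise (no
temporal autocorrelation, no spatially correlated noise across voxels), a
single deterministic source stage per voxel (real voxels mix), rectified
random projections rather than learned features, and stimuli that are
synthetic noise/tone composites rather than natural sounds. It is adequate
for validating estimators, not for simulating realistic fMRI physics.

## 5. Voxelwise encoding

For each (voxel, stage, split) triple, `fit_predict_split()`:

- demeans each regressor column on the **training sounds only** and applies
  the same shift to the test sounds; columns are *not* rescaled (this makes
  the ridge prior non-isotropic in the original feature units, which is
  intentional);
- solves ridge regression `w = (X'X + n λ I)^{-1} X' y` over the grid
  `λ ∈ 10^seq(-50, 49, length.out = 100)`;
- selects `λ` by exact leave-one-out cross-validation using the hat-matrix
  identity `e_i / (1 - h_ii)` computed from one shared thin SVD of the
  training matrix, so the whole grid costs one decomposition. Ties are
  broken toward the **larger** `λ` (more regularization);
- evaluates the Pearson correlation between predicted and observed test
  responses. If the prediction has exactly zero standard deviation the
  correlation is recorded as 0 with an `sd_zero` flag; negative
  correlations are clamped to 0 with a `clamped_negative` flag; a constant
  observed test vector yields 0 with `obs_sd_zero`.

`make_split_plan()` partitions the 165 sounds into 10 random splits of 83
training / 82 testing sounds; `run_encoding()` crosses all voxels × stages
× splits and `median_over_splits()` takes the per-pair median — medians,
not means, so one pathological split cannot dominate.

## 6. Correction for attenuation

Raw test correlations are bounded by measurement noise. The corrected
variance explained is

```
R^2 = r^2 / ( max(r_meas, k_meas) * max(r_pred, k_pred) ),  clipped to <= 1
```

- `measured_reliability()`: `r_meas` is the Spearman–Brown (SB) extrapolation
  to 3 scans of the median of the 3 pairwise scan correlations over the
  test sounds.
- `prediction_reliability()`: `r_pred` is the SB extrapolation of the median
  pairwise correlation among predictions from models fit to each single
  scan.
- `critical_r(n)` supplies the floor `k`: the one-sided critical Pearson
  correlation at `alpha = 0.05` with `df = n - 2`,
  `k = t / sqrt(t^2 + df)`. For the 83 training sounds this is 0.182 and
  for the 82 test sounds 0.183 (3 d.p.). Flooring the reliabilities at
  their critical values keeps the correction from exploding when a
  denominator estimate is itself indistinguishable from noise.

`screen_voxels()` optionally retains only voxels whose measured reliability
exceeds a threshold, mirroring reliability-based voxel selection.

## 7. Component prediction and stage selection

`predict_components()` reuses the identical ridge/LOO/split machinery with
the 6 component responses as targets (no attenuation correction — component
responses are noise-free by construction here).
`best_stage_split_selection()` avoids selection bias: in each of
`n_iter = 10` iterations the 10 splits are randomly partitioned into 5
*select* splits (choose the stage with the best median r²) and 5 *evaluate*
splits (report that stage's median r²); the aggregate is the mean over
iterations with its SEM. Stage ties on the select half go to the **lowest**
stage index. Because selection never sees the evaluate half, corrupting
evaluate-split values cannot change which stage is selected — a property
the test suite checks explicitly.

## 8. Representational similarity

`compute_rdm()` z-scores each feature column across sounds and fills the
RDM with `1 - Pearson r` between sound rows (range [0, 2]); zero-variance
columns are dropped with a warning. `rdm_similarity()` is the Spearman
correlation of the strict upper triangles. `best_stage_rsa()` uses the
split plan: the best stage is chosen on training sounds, and the model–brain
RDM similarity of that stage is evaluated on test sounds; the summary
`model_rho` is the raw mean of Spearman rho over splits (no Fisher z
transform — rho values here are far from ±1 and averaging raw rho matches
the summary convention used throughout the package).
`noise_ceiling()` is leave-one-participant-out: the RDM of each held-out
participant is correlated with the mean RDM of the remainder (requires ≥ 3
participants). `roi_best_stage_rsa()` computes, per participant × ROI, the
stage whose RDM best matches that ROI's RDM over all sounds.

## 9. Summaries and effective dimensionality

- `stage_position(i, n)` maps stage `i` of `n` to `(i - 1) / (n - 1)` in
  [0, 1]; a single-stage model warns and returns 0.
- `best_stage_map()` assigns each voxel its argmax-R² stage (ties → lowest
  stage); all-zero voxels are excluded.
- `roi_best_stage()` takes the median stage position within each
  participant × ROI cell, then the mean across participants.
- `effective_dim()` is the participation ratio `(Σλ)² / Σλ²` of covariance
  eigenvalues, computed via SVD of the column-demeaned (or z-scored)
  feature matrix; an all-constant matrix is flagged and returns 0.

## 10. Resampling statistics

- `bootstrap_model_comparison()`: participant bootstrap of a mean
  difference. Default `direction = "hypothesis"` counts draws at or beyond
  the observed value; `direction = "as-printed"` counts the complementary
  tail.
- `permutation_test_components()`: one-tailed label permutation of
  `mean(A) - mean(B)`, with optional `+1` add-one smoothing of the p-value.
- `wilcoxon_signed_rank()` wraps `stats::wilcox.test()` for paired data and
  flags the degenerate all-zero-differences case with `p = 1`.
- `bonferroni()` is `pmin(1, p * m)`.

All randomness is seeded through `substream_seed(seed, name)` (a
deterministic hash of the analysis name into `[0, 2^31)`) and `with_seed()`
(which restores the caller's RNG state), so pipelines are reproducible from
a single master seed without disturbing user code.

## 11. Problem sizes and runtime

At study scale (165 sounds, 3 scans, 10 splits, grids of 100 λ values) a
3-stage hierarchy with a few hundred voxels runs in seconds to a couple of
minutes on one CPU; the dominant cost is one thin SVD per (stage, split).
The cochleagram of a 2-s, 20 kHz sound (211 × 390) takes well under a
second; the 110-filter modulation feature vector (23210 values per sound)
takes a few seconds per sound and is the most expensive primitive.

## 12. End-to-end demonstration

```{r pipeline}
cfg <- default_config(seed = 1)
bundle <- run_pipeline(cfg)
bundle$summaries$roi
glance(bundle$encoding)
```
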