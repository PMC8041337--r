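---
title: "Methods: imaging structure-function coupling with an intracranial reference"
author: "sfcoupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: imaging structure-function coupling with an intracranial reference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(sfcoupling)
```

## What this package computes

`sfcoupling` asks whether the *structural* connectivity of a deep-brain
structure — how many tractography streamlines link it to each cortical
voxel — predicts its *functional* connectivity — how coherent each cortical
location's activity is with the local field potential (LFP) recorded at
that structure. The pipeline has five stages:

1. **Spectral estimation.** Multitaper cross-spectral densities (CSDs)
   between all sensors and the intracranial reference channel.
2. **DICS beamforming.** A frequency-domain spatial filter per 5 mm grid
   point converts the sensor CSD into a whole-volume image of
   magnitude-squared coherence with the reference, interpolated to 2 mm.
3. **Tract density.** Streamlines seeded at the recording site are counted
   per 2 mm voxel (one count per fibre per voxel).
4. **Voxel-wise GLM.** Per voxel, coherence across observations is
   regressed on tract density at the same voxel — the design matrix is
   *voxel-specific*, unlike the classical mass-univariate GLM — with
   cluster-based permutation control of family-wise error.
5. **Directionality.** At the peak of the structure-function coupling map,
   nonparametric spectral Granger causality with time-reversed surrogates
   decides whether cortex drives the deep structure or vice versa.

Because the corresponding patient data are not redistributable, the
package ships a synthetic-cohort generator with known ground truth; every
stage is validated against it or against closed-form oracles.

## Models and assumptions

### Cross-spectral density and coherence

The estimator is a Welch–multitaper hybrid: non-overlapping windows
(default 1 s, i.e. 1 Hz resolution), per-window demeaning, DPSS tapers
with ±2.5 Hz smoothing (4 tapers at the default), and averaging of
cross-products over windows and tapers. The CSD is stored one-sided with
interior bins doubled, so the diagonal sums over bins to the channel
variance. Coherence is `|S_ij|² / (S_ii S_jj)` in `[0, 1]`, invariant to
per-channel rescaling. Analysis bands are delta/theta 2–8 Hz, low beta
13–22 Hz, and high beta 23–30 Hz; band averages are inclusive at both
edges, so on a 1 Hz grid the 22 Hz bin belongs to low beta and high beta
starts at 23 Hz, keeping the beta bands disjoint.

### DICS beamformer

For band `b`, the filter at grid point `g` with (scalar) leadfield row `l`
is `w = C⁻¹l / (lᵀC⁻¹l)` where `C` is the real part of the band-averaged
sensor CSD plus Tikhonov loading `λ·mean(diag C)·I` (default `λ = 0.05`;
the unit-gain property `wᵀl = 1` holds for any `λ ≥ 0`). Source-reference
coherence is `|wᴴ S_xr|² / ((wᴴ S_xx w) S_rr)` computed from the
band-averaged complex CSD; averaging the CSD *before* filtering (one
filter per band) was chosen over averaging per-frequency coherence — it is
the cheaper and more common convention, and with 1 Hz bins inside narrow
bands the difference is small. Because the band-averaged CSD is an average
of positive-semidefinite matrices, the imaged coherence is guaranteed to
stay in `[0, 1]`. Grid values are interpolated trilinearly onto the 2 mm
mask lattice, `NA` outside the mask; lattice nodes outside the grid are
back-filled from their nearest grid point with a coordinate-ordered
tie-break so the image is invariant to grid ordering.

The toy leadfield is an inverse-square-distance gain with unit-norm rows.
This stands in for a realistic forward model deliberately: the package's
claims concern the *statistical* machinery downstream of the forward
model, and a smooth full-rank gain suffices to validate localization
behaviour on its own terms.

### Mid-sagittal flipping

Volumes use axis-aligned affines whose voxel-centre x coordinates form a
set symmetric about the world plane `x = 0` (no voxel centred on the
midline), so flipping is an exact index permutation and an involution.
Left-referenced observations are flipped (coherence and density alike)
before group statistics so that all observations share one hemisphere
convention.

### Tract density

A streamline contributes **once** to every voxel it traverses, however
long its in-voxel path and however often it re-enters (binary-per-fibre
rule; the alternative per-visit rule was rejected because fibre counts,
not dwell lengths, are the quantity of interest). Traversal is judged on
the polyline densified to ≤ 0.5 mm steps rather than by analytic
voxel-segment intersection; with 2 mm voxels the two differ only for
segments grazing a corner by less than the step, and the densified rule is
exactly the one used for seed-sphere membership, keeping filtering and
counting consistent. Seed filtering retains fibres passing within the seed
radius **and** intersecting the structure-of-interest mask.

### Voxel-wise GLM and cluster permutation

Per voxel `v`: `coherence_i(v) = b0 + b1·density_i(v) + e_i` over
observations `i`, F-tested on `(1, n-2)` degrees of freedom. Voxels where
density has zero variance across observations are undefined and excluded
before clustering, so clusters cannot bridge through undefined space.
Exact fits (zero residual) receive the largest finite F and an
`exact_fit` flag rather than `Inf`, keeping thresholding well-defined.
Coherence enters untransformed by default; `fisher_z = TRUE` applies
`atanh(sqrt(coh))` for users who prefer a variance-stabilized scale.

Inference: suprathreshold voxels at the `1 - p` quantile of `F(1, n-2)`
(default forming threshold `p = 0.01`) are grouped by 26-connectivity;
cluster *extent* is the cluster statistic (mass would also be defensible;
extent matches the most common practice). The null distribution of the
maximal extent comes from permuting the assignment of coherence
observations against density observations — the same permutation at every
voxel, preserving spatial correlation — and the family-wise p of a cluster
of size `s` is `(1 + #{perm max ≥ s}) / (1 + n_perm)`, which includes the
identity permutation and therefore never falls below `1/(1+n_perm)`.

The 2×2 group ANOVA of density images (contact location × disease, with
side and subject covariates) uses the same engine, permuting the tested
factor's labels within subject for within-subject effects and across
subjects for the disease effect. Subject indicators are coded sum-to-zero
*within* each disease group so the between-subject disease effect remains
estimable; this is ordinary-least-squares inference with exchangeability
handled by the permutation scheme, not a random-effects model, and is
flagged as a deviation from parametric SPM-style inference.

### Nonparametric spectral Granger causality

The bivariate CSD on a uniform grid from 0 to Nyquist (0.5 Hz steps via
2 s windows — Wilson's method needs the full half-spectrum even though the
analysis bands stop at 30 Hz) is factorized as `S = H Σ Hᴴ` by Wilson's
iterative algorithm: the spectrum is extended to the full frequency
circle, and each iteration applies the causal-part operator (half of lag
zero, upper-triangularized; positive lags kept; the ambiguous half-circle
lag split evenly — without that split the iteration oscillates on noisy
estimated spectra instead of converging). Convergence is declared when the
relative change of the factor drops below 1e-9 (cap 200 iterations; the
reconstruction `HΣHᴴ` is verified to 1e-6 relative). The Geweke measure
uses the standard normalized transfer function
`H̃_xy = H_xy + (Σ_xy/Σ_xx) H_xx`, which removes the instantaneous
correlation term; with diagonal Σ it reduces to the plain `H_xy`. Bins
where finite-sample noise makes the log argument nonpositive are clamped
to a tiny positive value and counted in `n_clamped`.

The time-reversal test computes band-mean causality per direction on the
original and sample-order-reversed data; a genuine lagged influence gives
a positive original-minus-reversed difference in its own direction and a
negative one opposite. The per-direction mean difference over
observations is tested two-sided against zero and reported as `F = t²`
with df `(1, n-1)` (the raw `t` is also returned); two-sided was chosen
because it reproduces the printed p of the reference F values (e.g.
`F(1,8) = 5.7 → p = 0.044`). Band means are differenced after averaging;
for means the order of differencing and averaging is immaterial.

## The synthetic cohort

The generator emulates 3-minute rest recordings at `fs = 300` Hz (Nyquist
comfortably above 30 Hz). Each cortical source is a band-limited
filtered-noise process sharing an innovation with the reference at a
controlled lag, so both the magnitude-squared coherence
(`coherence_target`) and the direction of Granger causality are known by
construction; sources are projected through the toy leadfield with
Gaussian sensor noise at a chosen SNR (default 1 — the amplitude scale and
SNR of real recordings are free parameters and are exposed in the
config). The reference receives the shared components, broadband noise of
SD 0.1, and a 1 Hz 4th-order zero-phase Butterworth high-pass mirroring
hardware filtering without the phase distortion that would corrupt
directionality ground truth. Every source also carries a small broadband
floor (SD 0.05): a strictly band-limited signal has near-zero innovation
variance and makes Granger measures ill-conditioned, while real signals
always ride on an aperiodic background. Realized in-band source-reference
coherence is verified at generation time (warning beyond ±0.1).

Two known imperfections of this construction are worth stating. First,
the zero-phase band-pass filtering of the shared innovations leaks a weak
acausal component, so the *raw* reverse-direction Granger estimate is
biased above zero; the time-reversal difference suppresses exactly this
class of weak asymmetry, which is why recovery criteria are stated on the
difference, not the raw estimate. Second, with equal lags the
bidirectional mode produces comb-like cross-spectra; it is exercised in
tests only for coherence, not directionality.

Streamlines are straight 1 mm-spaced polylines from the seed sphere to
each target voxel; expected terminal counts equal the target map, plus —
at the designated coupling voxels — a slope times the observation's latent
coherence level, with integer rounded-Gaussian count noise (a Poisson-like
integer model of fibre counting that degenerates to the exact target when
noiseless). Fibres to distant voxels traverse intermediate voxels, as real
fibres do, so pass-through density adds benign structured noise. Coherence
images in cohort mode are baseline 0.2 plus 0.3 times the latent level at
coupling voxels, with Gaussian voxel noise (SD 0.03) — amplitudes chosen
so values stay inside `[0, 1]` without clipping (clipping would break the
exactness of the null F distribution). What passing tests show is that
the *estimators and tests* behave correctly under these idealized
conditions; they do not show robustness to artefacts, head-model error,
nonstationarity, or non-Gaussian noise, none of which the generator
produces.

## Problem sizes and numerical choices

Validation studies use: cohorts of 5 subjects × 2 hemispheres (n = 10
observations, giving the reference df (1, 8)); 60–180 s recordings;
brain spheres of 24–28 mm radius with a 5 mm grid and 2 mm images;
20-replicate power studies and 100–200-cohort calibration studies at
200–500 permutations. These sizes were chosen as the smallest at which
the binomial calibration checks are informative. Other defaults:
regularization `λ = 0.05`; Wilson tolerance 1e-9, 200 iterations;
cluster-forming `p = 0.01`; FWE threshold `p < 0.01` for reporting.

## Limitations

- The forward model is a toy; no claims are made about spatial accuracy
  beyond the synthetic geometry (localization within one grid spacing).
- OLS + label permutation approximates, but is not, a hierarchical model
  of subject effects.
- Bivariate Granger only; conditional/multivariate extensions are out of
  scope, as are artefact rejection, atlas registration, and tractography
  reconstruction (streamlines are inputs).
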