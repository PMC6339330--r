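---
title: "Collateral filtering and automatic parameter selection: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collateral filtering and automatic parameter selection: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(collfilt)
```

This vignette is the package's account of its science: the filter model and
its assumptions, every tunable that matters, what the synthetic phantoms do
and do not emulate, and the numerical and design decisions taken where the
method left room. It states no empirical result that the test suite does
not itself compute.

## The collateral filter

Magnitude MR images carry signal-dependent Rician noise: Gaussian in bright
tissue, Rayleigh in air. A bilateral filter preserves anatomy by weighting
neighbors with a spatial and a radiometric (intensity-similarity) Gaussian,
but its range kernel is itself corrupted by the noise it is supposed to
remove. The collateral filter's remedy is a second range kernel computed on
the median-filtered image \(I^M\) — a robust companion that is nearly
noise-free but blurs edges — and a per-pixel arbiter deciding which kernel
to trust.

The arbiter is the agreement probability
\(p = \tfrac{1}{2}\left(1 - |I - I^M| / \mathrm{MAX}_I\right)^2 + \tfrac12
\in [0.5, 1]\), whose binary entropy, summed over the filter window,

\[
H(\theta) = -\sum_{\mu \in \Psi_\theta}
  \big[p(\mu)\log p(\mu) + (1-p(\mu))\log(1-p(\mu))\big] \ge 0,
\]

is zero exactly when image and median agree over the whole window and grows
where they clash (impulsive noise, thin structure). The ensemble weight

\[
W = W^S\,(W^R)^{1/(1+H)}\,(W^M)^{H}
\]

then shifts mass from the radiometric to the median kernel as \(H\) rises.
The restored value is the \(W\)-weighted window average of the blend
\((1-\beta)I + \beta I^M\).

Assumptions worth stating: the filter is local (a \((2N+1)^2\) window; no
non-local matching), is applied slice-by-slice to volumes, and treats
\(\mathrm{MAX}_I\) as the known acquisition ceiling — \(p\) and all metrics
change if \(\mathrm{MAX}_I\) is mis-declared, which is why `image2d`
carries it explicitly.

### Parameters

| knob | units | default | role |
|---|---|---|---|
| `radius` N | pixels | 1 (3×3) | window size; 3×3 matches the published configuration and keeps the median companion conservative |
| `sigma_s` | pixels | 1 | spatial falloff; beyond ~N/1.5 the window edge is effectively unweighted |
| `sigma_r` | intensity | 25 (≈0.1·255) | radiometric tolerance; of the order of the noise σ |
| `sigma_m` | intensity | 25 | same, for the median-filtered pair |
| `beta` | — | 0.5 | blend toward the median image; 0 = pure input, 1 = pure median |
| `tile_side` S | pixels | 16 | output tile of the buffered backend; 16×16 mirrors the thread-block geometry the scheme targets |

Two blend modes exist. `scalar` (default) treats β as a single tunable —
the form the parameter automation learns. `adaptive` sets
\(\beta(x,y) = 1 - p(x,y)\): the original acceleration scheme buffers a
per-pixel β but never defines it, so this package supplies \(1-p\) as a
documented stand-in — it trusts the median exactly where the pixel looks
like an outlier — without claiming it reconstructs the original.

### Decisions the method left open

- **Median window**: tied to the filter radius N (unstated in the source
  method); one knob instead of two, and consistent with the single stated
  3×3 configuration.
- **Borders**: edge replication for the median, entropy and filter windows,
  so every output pixel sees a full window and the output never shrinks.
- **Entropy conventions**: natural logarithm and \(0\log 0 = 0\). The log
  base only rescales \(H\) and is absorbed by the σ parameters, but it must
  be fixed for results to be comparable.
- **Numerics**: the ensemble weight is evaluated in log space
  (\(\log W = \log W^S + \log W^R/(1+H) + H\log W^M\), weights clamped at
  1e−300) because \((W^M)^H\) underflows for large \(H\); the window
  average accumulates deviations from the center blend value, which makes a
  constant image a *bit-exact* fixed point rather than one up to roundoff.

### The tiled backend

Tiling is an algebraic contract, not a hardware feature: each S×S output
tile stages, once, its (S+2N)² input apron — intensities, median values,
blend values and the per-pixel entropy terms — plus an (N+1)×(N+1) spatial
weight buffer indexed by |d_x|, |d_y|. Per output pixel the windowed
entropy is summed from the staged terms and the ensemble weight is
assembled from the buffers. Every expensive per-pixel term is touched once
per apron, which is exactly the shared-memory schedule of a GPU port; the
acceptance suite requires the two backends to agree to 1e−10·MAX_I on
random images for any tile size, and they agree to ~1e−13 in practice
(the only reordering is one multiply against the buffered spatial weight).

## Texture features

The automation's candidate bank has 95 named entries: 9
statistical/histogram features, 8 co-occurrence (GLCM) features × 4
directions, 11 run-length (GLRLM) features × 4 directions, 3 Tamura
features, 7 noise estimators. Choices made where the source is silent:

- **Quantization**: min–max to L = 32 levels for GLCM/GLRLM (configurable).
  A min–max scheme makes both matrices invariant to adding a constant to
  the image, which the test suite asserts.
- **GLCM**: symmetric bidirectional accumulation, normalized to sum to 1;
  directions 0°=(0,+1), 45°=(−1,+1), 90°=(−1,0), 135°=(−1,−1) in
  (row, column) steps; natural-log entropy; correlation defined as 0 (with
  a warning) when a marginal is degenerate.
- **GLRLM**: Galloway's eleven statistics with gray level indexed from 1,
  so the low/high gray-level emphases are finite on a flat image.
- **Histogram features**: 256 bins over [0, MAX_I]; entropy in bits;
  kurtosis is non-excess (normal ≈ 3). A constant image has undefined
  skewness/kurtosis; they return 0 with a warning rather than NaN.
- **Tamura**: coarseness uses the dyadic averaging pyramid (depth 5) with
  one deliberate refinement: a scale is eligible at a pixel only if both
  shifted averaging windows lie fully inside the image. With replicated
  borders instead, border pixels report spurious contrast at the largest
  scales and a fine checkerboard can grade *coarser* than a coarse one.
  Contrast is σ/kurtosis^(1/4); directionality is 1 − (4/π²)·Σ H(φ)(φ−φ_p)²
  over a 16-bin Prewitt orientation histogram (gradient magnitude threshold
  12 on a 0–255 scale, rescaled by MAX_I/255), normalized so a single
  orientation gives 1.
- **Noise estimators**: all return σ̂/MAX_I. LAP and LOG use the zero-sum
  mask identity E|I∗K| = σ‖K‖₂√(2/π) with the 3×3 Laplacian-difference and
  5×5 Laplacian-of-Gaussian masks. GTFLAP downweights mask responses by a
  generic transfer function g = 1/(1+(|∇I|/τ)²) of gradient magnitude
  (τ = twice the median gradient) before averaging — the cited correction
  is not reproduced in the source, so this is a documented stand-in with
  the right behavior (suppresses structure, unbiased on pure noise). The
  Rayleigh-background family (AJA: mode of the 3×3 local-means
  distribution, ÷√(π/2); BRUM: least-squares Rayleigh fit to the background
  histogram; SIJ: Rayleigh maximum likelihood √(⟨x²⟩/2)) segments
  background by an Otsu threshold and falls back to the whole image, with a
  warning, if either side is nearly empty. ACF subtracts the mean short-lag
  autocovariance from the variance.

## Feature selection

Features are first ranked by paired t-tests: for each feature, one test per
unordered pair of noise levels, pairing observations on anatomy id — the
natural pairing when the same slice exists at every noise level — and the
p-values are averaged; mean p < 0.05 admits a feature to the candidate
pool. Zero-variance differences yield p = 1 (no evidence) with a warning.

Subset search is classic sequential forward floating selection: best single
addition, then conditional removals while they beat the best subset
previously seen at that size; the best subset of size ≤ k_max (default 5,
the published working-subset size) found anywhere is returned, ties broken
lexicographically so the search is deterministic. The subset criterion is
an argument; the default is 5-fold cross-validated accuracy of the stage-1
noise classifier restricted to the subset, run with a reduced network
(fewer hidden units, capped iterations) because the criterion is evaluated
hundreds of times inside the search.

The selection acceptance test builds a synthetic table where five features
equal the noise level plus N(0, 3) jitter and ninety are pure N(0, 1)
noise. The jitter scale is chosen so that each informative feature is
individually *weak* — no single feature separates the classes, so accuracy
keeps improving as informative features accumulate and the search has
something to find — yet strong enough that all five clear the t-test gate
(at 60 anatomies, an adjacent-level paired t on N(0,3) jitter has p ≈ 5e−4).
A world with near-perfect single features would make the recovery target
unreachable for a reason that has nothing to do with the search: the
criterion saturates at subset size one.

## Parameter automation

Brute force filters the noisy image at every grid point and scores PSNR
against the clean reference; ties go to the first grid point. The default
grid spans under- to over-smoothing on 8-bit-normalized data: σ_S ∈
{0.5, 1, 1.5, 2} px, σ_R and σ_M ∈ {0.05, 0.1, 0.2, 0.4}·MAX_I, β ∈
{0, 0.25, 0.5, 0.75, 1}; N stays fixed at 1. The grid kernel precomputes,
per image, everything that does not depend on the σ's — the median image,
the entropy map, the per-offset squared differences — so a 320-point search
costs ~320 single-exponential passes.

The two-stage predictor: features are z-normalized with training
statistics; stage 1 is a 3-class single-hidden-layer tanh/linear network;
stage 2 is one regressor per class, trained only on that class's samples,
predicting (σ_S, σ_R, σ_M, β) scaled to the unit hypercube of the grid's
hull and clipped back into it at prediction time. Predicting these four
continuous knobs (with N fixed) is a design decision — the source never
enumerates its outputs. Hidden width defaults to 10 (unstated in the
source; configurable), one hidden layer per network.

Training is Levenberg–Marquardt on the sum of squared errors: analytic
Jacobian, λ starting at 1e−3, ×10 on a rejected step, ÷10 on an accepted
one, stopping at 200 iterations or gradient ∞-norm < 1e−8, with early
stopping on a 20% held-out split (patience 15). Everything is seeded;
retraining with the same seed reproduces the model bit for bit, and models
serialize to JSON with 17 significant digits, which round-trips IEEE
doubles exactly.

The class boundaries are low = {1, 3}%, median = {5, 7}%, high = {9}%. The
train/test split is 2:1 by anatomy id, which stratifies exactly by class
because every anatomy carries all noise levels.

## The phantom generator

The generator emulates the regimes of the simulated brain database the
original system was trained on: piecewise-constant tissue anatomy
(background 0.02, CSF 0.15, GM 0.45, WM 0.75 of MAX_I = 255, by default),
Fourier-perturbed nested boundaries so no two anatomies are congruent,
optional lesion blobs, in-plane Gaussian smoothing of thickness/2 px
standing in for 1/3/5 mm slice thickness, a multiplicative bias field, and
Rician noise `sqrt((I+g₁)² + g₂²)` with σ = level·MAX_I for levels
1/3/5/7/9% — the percent-of-maximum convention, with MAX_I playing the role
of the brightest tissue. Output is clipped to [0, MAX_I] so the image
invariants hold.

The bias field is a seeded random 2-D quadratic whose profile is
rank-equalized (a monotone remap), fixing the field mean at 1 and its range
at the declared amplitude (0/20/40%) while keeping the shading smooth and
low-order.

What the phantoms do **not** emulate: real cortical geometry, partial
volume beyond isotropic blur, spatially correlated (reconstruction-filtered)
noise, motion/ghosting, and multi-coil noise statistics. A green end-to-end
test therefore establishes that the pipeline — optimization, features,
selection, networks — is internally consistent and learnable on
Rician-corrupted piecewise-smooth images; it does not certify performance
on clinical data, and the headline numbers published for the original
system (classification rate, per-slice dB values, GPU speed-ups) are not
reproducible here because they depend on external corpora and hardware.

## Known limitations

- File I/O is plain text (ASCII PGM, CSV): no PNG/TIFF/NIfTI reader exists
  in the dependency budget. Volumes are supported in memory
  (`collateral_filter_volume`) and as per-slice files.
- The filter is 2-D; no 26-neighborhood volumetric window.
- SFFS with a cross-validated criterion is a heuristic; it is exact on the
  structured tables the acceptance suite checks, not in general.
- The global SSIM form follows the single-statistic definition; windowed
  mean-SSIM (7×7 uniform windows, population statistics) is the reporting
  default, and the two can differ substantially on structured images.
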