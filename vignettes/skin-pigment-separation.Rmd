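---
title: "Separating melanin and hemoglobin from RGB skin images"
author: "skinICA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating melanin and hemoglobin from RGB skin images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skinICA)
```

## The model

Skin color is dominated by two chromophores: melanin in the epidermis and
hemoglobin in the dermis. Under a layered Lambert–Beer view of skin
reflectance, the log of a camera channel value at pixel $(x, y)$ is a
linear mixture of the two concentration fields plus illumination terms:

$$
\log C_i(x,y) \;=\; -v_m(i)\,c_m(x,y) \;-\; v_h(i)\,c_h(x,y)
\;+\; \log p(x,y) \;+\; \bar{E}_i^{\log},
\qquad i \in \{R, G, B\},
$$

where $v_m(i), v_h(i)$ fold each pigment's extinction coefficient and mean
photon path length into a single per-channel constant, $p(x,y)$ is the
multiplicative shading induced by surface shape, and $\bar{E}_i^{\log}$ is
the baseline log irradiance. Taking log **channel differences**

$$
H(x,y) = \begin{pmatrix} \ln B - \ln R \\ \ln G - \ln R \end{pmatrix}
 = V\,c(x,y) + \bar{E}^{\mathrm{diff}},
\qquad
V = \begin{pmatrix}
v_m(R)-v_m(B) & v_h(R)-v_h(B)\\
v_m(R)-v_m(G) & v_h(R)-v_h(G)
\end{pmatrix}
$$

cancels the shading term exactly (it adds the same value to every channel
of a pixel) along with any global exposure factor. Estimating $V$ and the
per-pixel concentrations $c = (c_m, c_h)$ from $H$ alone is a 2-D blind
source separation problem, solved here by negentropy FastICA: after
centering and whitening ($Z = \Lambda^{-1/2}U^{T}\tilde H$), unit vectors
$w$ are found by the fixed-point iteration

$$
w^{+} = E\{z\,g(w^{T}z)\} - E\{g'(w^{T}z)\}\,w,
\qquad g = \tanh,
$$

with deflation (the second vector Gram–Schmidt-orthogonalized against the
first). A component converges when $|1-|w_{k+1}\cdot w_k|| < \mathrm{tol}$;
a *run* succeeds only if **both** components converge within the iteration
budget. The coefficient matrix is recovered as
$V = |(\Lambda^{-1/2}U^T)^{-1} W^{-1}|$ with unit-norm columns; the
absolute value and normalization absorb ICA's sign/scale ambiguity, and
the column order is fixed afterwards by the ratio rules below.

## The two stabilising stages

FastICA's random initialisation makes it stochastically unstable: on some
inputs the fixed-point map has stable period-2 limit cycles, and a run
that lands in such a basin oscillates forever between two directions
without meeting the tolerance. Two preprocessing stages reduce how often
this happens and shrink the data volume:

**Sub-block selection.** The region is tiled into $q \times q$ blocks; per
block the means $\bar d_{B-R}$, $\bar d_{G-R}$ of the two log differences
give the score $d_{B,G-R} = |\bar d_{B-R}| + |\bar d_{G-R}|$. Blocks with
nearly equal channels score low — exactly the regime where residual
shading errors dominate the observables — and only the top fraction
(default 25%) is retained, removing 75% of the pixels. Ties break toward
raster order; partial border tiles are discarded (the default analysis
window divides evenly).

**Local clustering.** The whitened samples are sparsified by a clustering
that exploits their raster order: $k$ centers are seeded as means of
contiguous windows of stride $\lfloor n/k \rfloor$ (leftovers appended to
the last window), each sample is reassigned only among the centers within
$\pm r$ of its current center index, centers are updated to member means
(empty clusters keep their position), and iteration stops when fewer than
1% of labels change. From each cluster $m$ members are drawn uniformly
without replacement (all of them if the cluster is smaller), giving at
most $k \cdot m$ feature points as the FastICA input.

## Synthesis

The melanin/hemoglobin identity of $V$'s columns is decided by the row
ratios: if $v_{21}/v_{11} \in (1, 6.33]$ and $v_{22}/v_{12} \in [0.48, 1)$
the order stands, otherwise the columns are swapped; if neither order
satisfies both conditions (a degenerate estimate) the order closest to the
intervals is kept with a warning. Concentrations are inverted on **every**
pixel of the original region, $c = (V^{*})^{-1} H$ (the baseline term is
taken as zero at analysis time), while $V$ itself comes from the
selected/clustered subsample — that split is deliberate. Each pigment
image keeps only its own contribution to the log differences,

$$
L_m = \exp\!\big(V^{*}\,\mathrm{diag}(1,0)\,c + (H_R^{\log}, H_R^{\log})^{T}\big),
$$

with row 1 of $V^*$ feeding the B channel and row 2 the G channel, and the
R channel copied bit-identically from the input. Before clipping into
$(0,1]$, the log differences of the two pigment images sum back exactly to
$H$ — the defining identity of the decomposition, asserted per pixel in
the tests at $10^{-10}$.

## The synthetic-scene generator

No public dataset exists for this problem, so every stage is exercised
against a forward simulator with known ground truth. A scene holds
nonnegative concentration fields, a log-shading field, the 3×2 per-channel
coefficients and baseline irradiances; rendering applies the log-linear
model exactly and rescales intensities into $(0,1]$ by one global factor
(recorded, and invisible to the channel differences).

Choices a user should know about, with rationale:

- **Scene size 600 × 300 px**: the size of a typical rectangular forehead
  analysis window for this kind of imagery; with the default q = 5 it
  tiles into 7,200 blocks, and 25% retention leaves a 45,000-pixel pool.
- **Melanin: 200 Gaussian spots, sd 3 px, amplitudes 0.5–1.5; hemoglobin:
  160 blobs, sd 6 px, amplitudes 0.3–0.9; baseline 0.3.** Melanin appears
  as compact spots, hemoglobin as broader diffuse regions. The *density*
  matters statistically: the two fields are drawn independently, but a
  field with few large features has few effective degrees of freedom, and
  the chance empirical correlation between the fields biases any ICA
  estimator. At these densities the empirical correlation is typically
  below 0.05, so parameter-recovery error is dominated by the estimator,
  not the scene.
- **Shading**: a sum of six random plane waves at spatial scale
  ~60 px, centered and scaled to a peak-to-peak range of exactly twice the
  amplitude parameter (default 0.3 log-units).
- **Coefficients**: per-channel values are chosen so the derived 2×2
  difference matrix has column ratios 3.0 and 0.7 — inside the ordering
  intervals, making melanin/hemoglobin identification on synthetic scenes
  deterministic. Camera gain and spectral response are not modeled
  separately: only the channel differences are observable to the
  pipeline, so the simulator works directly in the log-linear form.
- **Baseline irradiance** $(-0.2, -0.35, -0.5)$ for (R, G, B) gives a
  mildly warm cast; the resulting constant offset in $H$ is removed by
  centering and only shifts the recovered concentration maps by a
  constant.

What the simulator does **not** emulate: sensor noise and 8-bit
quantization, specular residue, non-skin structures, and any wavelength
dependence of shading. Consequences are discussed below.

## Numerical and design choices

- Natural logarithms throughout; the synthesis equations use `exp`, which
  forces this choice for internal consistency.
- Zero intensities are clamped to half a code value,
  $1/(2 \cdot \mathrm{maxcode})$, before any log.
- Coordinates are 1-based; samples are kept in raster (row-major) order.
  The order is load-bearing: cluster seeding windows are defined over it.
- Whitening fixes eigenvector signs by making each eigenvector's
  largest-magnitude entry positive; covariance condition numbers above
  $10^{12}$ are rejected as degenerate (one silent source makes the two
  observables collinear — the failure mode selection exists to prevent).
- "Absolute difference equals zero" is not attainable in floating point;
  convergence is $|1-|w_{k+1}\cdot w_k|| < 10^{-6}$ with a budget of 200
  iterations per component. Both knobs are configurable and logged —
  together they *define* what a convergence-rate experiment counts.
- The neighbor radius is $r = 2$ center indices: small windows preserve
  the local character and the cost profile of the clustering.
- Defaults $q = 5$, fraction $= 0.25$, $k = 1200$, $m = 3$; warnings are
  emitted outside the empirically recommended bands $q \in [3, 8]$,
  fraction $\in [0.2, 0.3]$, $k \in [900, 1500]$.
- In the benchmark, "input size" is the number of samples entering the
  ICA stage before clustering; subsampling takes a contiguous raster
  prefix of the (selected) pool, and feature points are drawn once per
  (scene, size) so that repeats isolate the FastICA initialisation as the
  only source of run-to-run variation.

## What the experiments show — and what they cannot

`convergenceRate()` benchmarks three variants: `plain_dlica` (all pixels
straight to FastICA), `subblock_only`, and the full
`subblock_plus_cluster`. The desk-scale grid (five seeded scenes, sizes
4,000–20,000 in steps of 4,000, 20 repeats) runs in well under a minute;
the full protocol grid (sizes to 75,000 in steps of 500, 100 repeats)
remains available through the same arguments.

Two things reproduce robustly on synthetic scenes: the full method's mean
success rate lands in the low-to-mid 90s in percent (the package's
acceptance script recomputes this number from scratch), and clustering
improves on sub-block selection alone — the step that motivates the
method. One thing does not: *plain DL-ICA barely ever fails on synthetic
scenes*. This is a modelling gap, not an implementation artifact: in the
forward model above, shading cancels *exactly* in the channel differences
and no sensor noise exists, so the plain variant sees a pristine two-source
linear mixture. On real 8-bit camera images, quantization noise dominates
the observables wherever the channels are nearly equal — precisely the
low-score blocks that selection discards — which is the plausible
mechanism behind the instability of unfiltered inputs reported for real
data. The failures that *do* occur here were verified to be stable
period-2 limit cycles of the tanh fixed-point map (a reference FastICA
implementation exhausts its budget on the identical inputs), concentrated
in a few scene/size cells whose truncated sample distributions flatten the
negentropy landscape.

## Limitations

- Two components only; no oxy/deoxy-hemoglobin split or oxygen-saturation
  estimation.
- Inputs are assumed linear RGB from cross-polarized capture: no gamma
  removal, white balance, or specular-reflection handling.
- Concentrations are relative (unit-norm columns leave a per-column
  scale); maps are comparable within an image, not across images.
- Passing synthetic tests demonstrates correctness of the machinery and
  the estimator under the stated forward model; it does not certify
  separation quality on real skin, where the model's omissions (noise,
  quantization, non-skin structure) matter.

## Problem sizes used by the shipped checks

The unit suite runs on scenes from 32 × 32 to 240 × 240 pixels; oracle
comparisons use 20,000–30,000-sample mixtures; the acceptance computation
uses five default-size (600 × 300) scenes, sizes 4,000–20,000 step 4,000,
20 repeats — 500 FastICA runs in total, a few seconds of compute.
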