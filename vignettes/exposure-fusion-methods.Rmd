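---
title: "Multi-exposure multispectral fusion for NIR imaging through scattering tissue"
author: "NIRfuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-exposure multispectral fusion for NIR imaging through scattering tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(NIRfuse)
```

## The problem

Dense structures (tumor phantoms, blood vessels) buried under a few
millimetres of biological tissue are invisible to a conventional visible-light
camera: visible photons scatter and are absorbed before they reach the object
and return. Near-infrared light penetrates deeper, and a spectral camera can
sample the 700–950 nm window in narrow bands. But no single (band, exposure)
frame is well exposed everywhere — the illumination spectrum and the detector
sensitivity vary strongly across bands — and each band carries slightly
different information about the buried object. Exposure fusion condenses such
an acquisition, here 10 bands × 10 exposures = 100 co-registered frames, into
one well-exposed composite in which the buried object is maximally visible,
without ever estimating HDR radiance.

## The model

For each frame $I_k$ (normalized gray levels in $[0,1]$) two per-pixel
quality measures are computed:

* **Contrast** $C_k = |\nabla^2 I_k|$, the absolute response of a discrete
  Laplacian filter. Edges and texture score high; flat (including flat
  because saturated) regions score zero.
* **Exposedness** $E_k = \exp\!\big(-(I_k - 0.5)^2 / 2\sigma^2\big)$, a
  Gaussian affinity to mid-gray that penalizes under- and overexposed pixels.

The raw weight is the product $W_k = C_k \cdot E_k$, normalized across the
stack, $\hat W_k = W_k \big/ \sum_n W_n$, so the weights form a per-pixel
convex combination. The simple fused image is the weighted average
$\hat R = \sum_n \hat W_n I_n$. Because the weights can fluctuate rapidly
from pixel to pixel (the contrast term responds to noise), this average
shows stitch-line artifacts. The remedy is multi-resolution blending: build
the Laplacian pyramid $L\{I_n\}$ of every frame and the Gaussian pyramid
$G\{\hat W_n\}$ of every weight map, blend level by level,

$$L\{R\}_l = \sum_{n=1}^{N} G\{\hat W_n\}_l \, L\{I_n\}_l,$$

and collapse $L\{R\}$ to obtain the fused image. Smoothing the weights at
every scale removes the seams while the band-pass image content keeps detail
sharp. `fuseStack()` exposes both engines (`mode = "naive"` / `"pyramid"`).

## Pyramid machinery and numerical choices

* **Generating kernel.** The separable 5-tap binomial kernel
  $[1,4,6,4,1]/16$. Its weights sum to 1 (asserted at every call), so
  constants pass through unchanged. Configurable via the `kernel` argument.
* **Borders.** Whole-sample mirror reflection everywhere (no edge
  darkening, constants preserved); the index folding has period $2n-2$ and
  degenerates gracefully down to 1-pixel axes.
* **Odd sizes.** Level $l{+}1$ has dimensions $\lceil \cdot/2 \rceil$ of
  level $l$; `upsampleTo()` targets the exact parent shape (zero insertion
  followed by the kernel scaled ×2 per axis — the transpose of the
  reducer), so arbitrary sizes round-trip.
* **Exactness.** Residual levels are defined against the same upsampling
  operator used at collapse, so `collapsePyramid(buildLaplacian(x))`
  reconstructs `x` to floating-point round-off (the suite asserts
  $<10^{-10}$ up to 257×257 including odd sizes; in practice the error is
  exactly 0).
* **Depth.** Default `floor(log2(min(h, w)))` levels (coarsest level about
  2 px on the short side); the feasible maximum is
  `1 + ceiling(log2(max(h, w)))`, and infeasible requests fail naming it.
* **Clipping.** Pyramid blending can overshoot $[0,1]$ after collapse.
  Only the final fused image is clipped; the pre-clip range is recorded in
  the result's provenance. Intermediate levels are never clipped.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `sigma` | 2 | exposedness width (dimensionless, on $[0,1]$ gray levels) |
| `depth` | `floor(log2(min(h,w)))` | pyramid levels |
| `neighbors` | 4 | Laplacian stencil for contrast (4- or 8-neighbor) |
| `mode` | `"pyramid"` | blending engine |
| `strategy` | `"flat"` | one fusion over all N frames vs per-band first |
| `floor` (flat-field) | `1e-3` | gain guard against near-black reference pixels |

Two defaults deserve comment. First, $\sigma = 2$ makes the exposedness
weight nearly flat over $[0,1]$ (range $\approx [0.969, 1]$), so in practice
the contrast term dominates; the value is kept as the method's stated
operating point rather than silently replaced, and `sigma` is a knob for
users who want a sharper exposure preference (values around 0.2 make $E$
decisive). Second, two orchestration strategies exist because both are
defensible readings of the acquisition protocol: `"flat"` fuses all 100
frames in one pass with the fully specified weight model, while
`"two_stage"` merges each band's exposure ladder first and then fuses the
10 per-band results. Both are provided; `"flat"` is the default because it
is the completely specified path. `"two_stage"` requires a complete
factorial (band × exposure) stack and fails at validation otherwise.

Weight normalization guards the all-zero-weight case (a pixel flat and
ill-exposed in every frame): where $\sum_n W_n < 10^{-12}$ the weights fall
back to exactly uniform $1/N$, which is deterministic and keeps the
per-pixel sum exactly 1.

## Flat-field calibration

The acquisition protocol images a gray uniform patch before the samples,
because the off-axis lamp illuminates the frame non-uniformly. The
correction is multiplicative — `gain = mean(ref) / max(ref, floor)` — the
standard choice for illumination non-uniformity (it preserves zero and
turns the reference into its own mean). One global reference or one per
band may be supplied; the pipeline applies the correction before weight
computation, matching the protocol order. Division-by-near-zero is guarded
by `floor` (default $10^{-3}$, capping gain near 1000×).

## The synthetic phantom: what it emulates, and what it does not

The simulator (`defaultScene()`, `generateStack()`) reproduces the
acquisition design so the whole pipeline can be exercised with known ground
truth: a dense disk of 125 px diameter under a diffusive layer, 10 bands at
713–920 nm, 10 exposures from under- to overexposed, sensor saturation and
noise, plus a gray-patch reference and a "white-light proxy" frame standing
in for a conventional RGB photograph.

The optical model is deliberately minimal — per-band Beer–Lambert-style
attenuation of the disk's contrast, a Gaussian point-spread function for
scattering, a smooth illumination field, shot + read noise — chosen as the
simplest model producing the qualitative phenomenology of imaging through
scattering tissue: the object is invisible in the white-light proxy, faint
in single NIR frames, and clear after calibrated fusion. It is a test
fixture, not a claim about tissue optics. Default choices, fixed once:

* **Band brightness** ramps 1.0 → 0.35 across 713 → 920 nm (frames are
  brighter at lower wavelengths, as source spectrum × detector sensitivity
  dictates).
* **Scattering blur** 12 → 4 px and **disk-contrast transmission**
  0.15 → 0.75 across the bands: longer NIR wavelengths penetrate deeper
  and scatter less, so they carry most of the disk signal.
* **Illumination** falls off smoothly by 30% toward the far corner, peak
  offset toward the lamp side — the non-uniformity the gray-patch
  calibration exists to remove. Uniform illumination would make
  saturation all-or-nothing (whole frames clipping to a constant), which
  neither resembles a real acquisition nor leaves the flat-field stage
  anything to do.
* **Exposure ladder**: 10 log-even times, 30 → 240 ms about the 100 ms
  reference. The 8× span equals the acquisition's dynamic range (band
  brightness × illumination falloff), so the shortest exposure
  underexposes every band (mean < 0.2) and the longest partially
  saturates the brightest bands (> 1% of pixels at 1.0) while the dark
  disk and dim corners clip last.
* **Noise**: Gaussian-approximated shot noise
  (sd $= 0.01\sqrt{\text{signal}}$) plus read noise (sd 0.01), drawn from
  the scene's own seed; a fixed seed reproduces the stack bit for bit.

What the phantom does **not** emulate: real tissue optical constants,
depth-dependent radiative transfer, inter-frame misregistration, spectral
cross-talk between bands, and structured background texture. Passing the
suite therefore demonstrates the correctness and the qualitative behavior
of the fusion machinery, not clinical performance on real tissue.

## Detectability metrics

`cnr(img, mask)` quantifies how visible the buried object is:
$|\mu_{\text{mask}} - \mu_{\text{bg}}| / \sigma_{\text{bg}}$, invariant
under positive affine intensity transforms and undefined (an error) on a
constant background. Cross-sections (`crossSection()`, `profileReport()`)
extract the row/column traces through a stated point, the standard way to
display the dark dip at the object location. Coordinates are 1-based
(row = vertical/y, col = horizontal/x) and ROIs are inclusive
`c(row0, row1, col0, col1)` — the native R convention, stated here to
avoid axis ambiguity.

On the default seeded phantom the suite asserts the headline behavior: the
calibrated pyramid-fused image has a higher disk CNR than the white-light
proxy and than 90% of the best raw single frame, and a hard weight seam
that survives naive averaging is removed by pyramid blending. Problem
sizes used throughout the suite — 256×256 frames for the end-to-end
phantom runs, up to 257×257 for the reconstruction fuzz, 64×64 for IO and
pipeline round-trips — are the package's chosen balance between coverage
of odd/even size edge cases and a suite that runs in well under a minute.

## Known limitations

* Frames are assumed co-registered; no alignment is attempted.
* The contrast weight responds to noise as readily as to real texture, so
  in texture-free scenes the weights are noise-driven; pyramid blending
  (not the weights) is what keeps the result smooth. This mirrors the
  method's stated design.
* With `sigma = 2`, exposure selection is weak (see above).
* Saturated regions are excluded only implicitly (zero contrast weight,
  mildly reduced exposedness); heavily clipped acquisitions should extend
  the ladder downward rather than rely on the weights.
* `cnr` requires a ground-truth or user mask; no segmentation is provided.
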