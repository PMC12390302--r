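# NIRfuse

Exposure fusion for near-infrared (NIR) multispectral image stacks acquired
through scattering tissue.

## The problem

Dense objects buried under a few millimetres of tissue — tumor phantoms,
vessels — are invisible to a visible-light camera: visible photons scatter
before reaching the object. NIR light (here 10 spectral bands, 713–920 nm)
penetrates deeper, but no single (band, exposure) frame is well exposed
everywhere, and each band carries different information. NIRfuse condenses a
bracketed multispectral acquisition (10 bands × 10 exposures = 100
co-registered frames) into one composite in which the buried object is
maximally visible, without estimating HDR radiance.

## The method

Per frame *k*, two per-pixel quality measures:

* contrast — absolute Laplacian response, `C_k = |∇²I_k|`;
* exposedness — Gaussian affinity to mid-gray,
  `E_k = exp(−(I_k − 0.5)² / 2σ²)`, default σ = 2.

Raw weights `W_k = C_k · E_k` are normalized across the stack,
`Ŵ_k = W_k / Σ_n W_n`, giving a per-pixel convex combination. The naive
fusion `R̂ = Σ_n Ŵ_n I_n` shows stitch-line artifacts where weights
fluctuate; the pyramid engine instead blends each Laplacian level of the
frames with the matching Gaussian level of the weight maps,

```
L{R}_l = Σ_n G{Ŵ_n}_l · L{I_n}_l
```

and collapses `L{R}` into the fused image. A multiplicative flat-field
built from a gray-patch reference removes illumination non-uniformity
before weighting; cross-section profiles and a contrast-to-noise ratio
(CNR) quantify how detectable the hidden object is. Because the original
tissue acquisitions are not publicly available, the package ships a seeded
synthetic phantom — a dense 125 px disk under a diffusive layer, imaged
with the same 10 × 10 design, with saturation, noise and an off-axis
illumination field — so the whole pipeline is testable with ground truth.

## Worked example

```r
library(NIRfuse)

scene <- defaultScene(seed = 0)
scene
#> PhantomScene: 256x256 px, disk 125 px dia at (128, 128)
#>   10 bands 713-920 nm x 10 exposures 30-240 ms (seed 0)

ph <- generateStack(scene)
ph$stack
#> ImageStack: 100 frames of 256x256 px
#>   bands (nm): 713, 736, 759, 782, 805, 828, 851, 874, 897, 920
#>   exposures (ms): 30, 37.8, 47.6, 60, 75.6, 95.2, 120, 151.2, 190.5, 240
#>   factorial design: TRUE

out <- runPipeline(list(phantom = list(seed = 0)))   # calibrate -> weights -> fuse -> profile
out$result
#> FusionResult: 256x256 px, mode = pyramid, strategy = flat, depth = 8
#>   pre-clip range: [0.2665, 0.3628]

cnr(fusedImage(out$result), ph$truth)                # 11.30
cnr(whiteLightProxy(scene), ph$truth)                # 1.34
max(vapply(frames(ph$stack), function(f)
  tryCatch(cnr(f, ph$truth), error = function(e) NA_real_), 0),
  na.rm = TRUE)                                      # 4.93
```

The three CNR values tell the story: the buried disk is essentially
invisible in the white-light view (CNR 1.3), faintly visible in the best
single raw NIR frame (4.9), and clearly resolved in the calibrated
pyramid-fused image (11.3). `out$report` carries the X/Y cross-section
traces through the disk center, which dip over an interval matching the
disk diameter.

A command-line front end with the same stages lives at
`inst/cli/nirfuse.R`:

```sh
Rscript inst/cli/nirfuse.R phantom --seed 0 --out frames/
Rscript inst/cli/nirfuse.R fuse --input frames/ --flat frames/flat_reference.tiff --output fused.tiff
Rscript inst/cli/nirfuse.R profile --input fused.tiff --row 128 --col 128 --mask frames/truth_mask.png --out report.json
Rscript inst/cli/nirfuse.R pipeline --seed 0 --out results/
```

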