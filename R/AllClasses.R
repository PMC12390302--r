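#' @import methods
NULL

## Images throughout the package are plain numeric matrices: rows index the
## vertical (y) axis, columns the horizontal (x) axis, and values are
## normalized gray levels. Frames of an acquisition live in [0,1]; pyramid
## residual layers and unclipped fusion output may leave that range.

.checkImage <- function(x, what = "image", unit = FALSE) {
  if (!is.matrix(x) || !is.numeric(x))
    return(sprintf("%s must be a numeric matrix", what))
  if (nrow(x) < 1L || ncol(x) < 1L)
    return(sprintf("%s must have at least one row and one column", what))
  if (anyNA(x) || any(!is.finite(x)))
    return(sprintf("%s contains non-finite values", what))
  if (unit && (min(x) < 0 || max(x) > 1))
    return(sprintf("%s has values outside [0,1]", what))
  NULL
}

#' ImageStack: an ordered, co-registered multi-exposure multispectral stack
#'
#' Holds the frame sequence \eqn{I_n, n = 1..N} of an acquisition together
#' with per-frame labels: the center wavelength of the spectral band (nm)
#' and the exposure time (ms). All frames must share identical dimensions
#' and hold normalized intensities in \eqn{[0,1]}. A full factorial
#' acquisition (every band captured at every exposure) is required by the
#' two-stage fusion strategy; [isFactorial()] reports whether the stack
#' qualifies.
#'
#' @slot frames list of numeric matrices, all with identical dimensions.
#' @slot wavelengthNm numeric, per-frame band center wavelength in nm.
#' @slot exposureMs numeric, per-frame exposure time in ms.
#' @slot metadata list of free-form provenance (scene echo, source paths).
#'
#' @seealso [imageStack()], [generateStack()], [readStack()]
#' @export
setClass("ImageStack",
  representation(frames = "list", wavelengthNm = "numeric",
                 exposureMs = "numeric", metadata = "list"),
  prototype(metadata = list()))

setValidity("ImageStack", function(object) {
  n <- length(object@frames)
  if (n < 1L) return("stack must contain at least one frame")
  if (length(object@wavelengthNm) != n || length(object@exposureMs) != n)
    return("labels must match the number of frames")
  d <- dim(object@frames[[1L]])
  for (i in seq_len(n)) {
    msg <- .checkImage(object@frames[[i]], sprintf("frame %d", i), unit = TRUE)
    if (!is.null(msg)) return(msg)
    if (!identical(dim(object@frames[[i]]), d))
      return(sprintf("frame %d (%gnm, %gms) has dimensions %dx%d, expected %dx%d",
                     i, object@wavelengthNm[i], object@exposureMs[i],
                     nrow(object@frames[[i]]), ncol(object@frames[[i]]),
                     d[1L], d[2L]))
  }
  if (anyDuplicated(paste(object@wavelengthNm, object@exposureMs)))
    return("duplicate (wavelength, exposure) labels")
  TRUE
})

#' WeightStack: per-frame, per-pixel fusion quality weights
#'
#' Stores both the raw weights \eqn{W_k = C_k \cdot E_k} (contrast times
#' exposedness, always non-negative) and the normalized weights
#' \eqn{\hat W_k = W_k / \sum_n W_n}, which sum to one at every pixel.
#'
#' @slot raw list of non-negative numeric matrices, one per frame.
#' @slot normalized list of matrices summing to 1 per pixel across frames.
#' @slot sigma the exposedness Gaussian width used (dimensionless).
#'
#' @seealso [computeWeightStack()], [normalizeWeights()]
#' @export
setClass("WeightStack",
  representation(raw = "list", normalized = "list", sigma = "numeric"))

setValidity("WeightStack", function(object) {
  n <- length(object@raw)
  if (n < 1L) return("weight stack must contain at least one frame")
  if (length(object@normalized) != n)
    return("raw and normalized lists differ in length")
  d <- dim(object@raw[[1L]])
  for (i in seq_len(n)) {
    if (!identical(dim(object@raw[[i]]), d) ||
        !identical(dim(object@normalized[[i]]), d))
      return(sprintf("weight grid %d has inconsistent dimensions", i))
    if (min(object@raw[[i]]) < 0 || min(object@normalized[[i]]) < 0)
      return(sprintf("negative weights in grid %d", i))
  }
  tot <- Reduce(`+`, object@normalized)
  if (max(abs(tot - 1)) > 1e-9)
    return("normalized weights do not sum to 1 at every pixel")
  TRUE
})

#' ImagePyramid: Gaussian or Laplacian multi-resolution representation
#'
#' Level 1 is full resolution; each subsequent level has ceiling-halved
#' dimensions. A `"gaussian"` pyramid holds progressively low-passed
#' images; a `"laplacian"` pyramid holds band-pass residuals plus the
#' low-pass residue at the coarsest level and can be collapsed back to the
#' source image exactly (see [collapsePyramid()]).
#'
#' @slot levels list of numeric matrices, finest first.
#' @slot variant `"gaussian"` or `"laplacian"`.
#'
#' @seealso [buildGaussian()], [buildLaplacian()], [collapsePyramid()]
#' @export
setClass("ImagePyramid",
  representation(levels = "list", variant = "character"))

setValidity("ImagePyramid", function(object) {
  if (!(object@variant %in% c("gaussian", "laplacian")))
    return("variant must be 'gaussian' or 'laplacian'")
  d <- length(object@levels)
  if (d < 1L) return("pyramid must have at least one level")
  for (l in seq_len(d)) {
    msg <- .checkImage(object@levels[[l]], sprintf("level %d", l))
    if (!is.null(msg)) return(msg)
    if (l > 1L) {
      up <- dim(object@levels[[l - 1L]])
      if (!identical(dim(object@levels[[l]]),
                     as.integer(c(ceiling(up[1L] / 2), ceiling(up[2L] / 2)))))
        return(sprintf("level %d dimensions are not ceil(level %d / 2)", l, l - 1L))
    }
  }
  TRUE
})

#' FusionResult: a fused image with its provenance
#'
#' @slot fused numeric matrix in \eqn{[0,1]} (clipped as the final step).
#' @slot mode `"naive"` (per-pixel weighted average) or `"pyramid"`
#'   (Laplacian-pyramid blending).
#' @slot strategy `"flat"` (one fusion over all frames) or `"two_stage"`
#'   (exposures merged within each band first, then bands merged).
#' @slot depth pyramid depth used (1 for naive mode).
#' @slot preClipRange numeric length 2, the pre-clip min and max.
#' @slot provenance list echoing labels and parameters of the run.
#' @export
setClass("FusionResult",
  representation(fused = "matrix", mode = "character", strategy = "character",
                 depth = "integer", preClipRange = "numeric",
                 provenance = "list"))

setValidity("FusionResult", function(object) {
  msg <- .checkImage(object@fused, "fused image", unit = TRUE)
  if (!is.null(msg)) return(msg)
  if (!(object@mode %in% c("naive", "pyramid"))) return("unknown mode")
  if (!(object@strategy %in% c("flat", "two_stage"))) return("unknown strategy")
  if (length(object@preClipRange) != 2L) return("preClipRange must be length 2")
  TRUE
})

#' PhantomScene: parametric synthetic scattering-tissue scene
#'
#' Describes the simulated acquisition: a uniform background layer with an
#' embedded dense disk, imaged at `length(bandCwlNm)` NIR bands and
#' `length(exposureTimesMs)` exposures. The disk's contrast against the
#' background is scaled per band by `attenuation` (transmission of the
#' disk signal through the diffusive layer) and blurred by a Gaussian
#' point-spread function of `scatterSigmaPx` pixels; the whole radiance is
#' scaled by `bandRelativeIntensity` (source spectrum times detector
#' sensitivity). See [defaultScene()] for the default acquisition design.
#'
#' @slot imageH,imageW frame size in pixels.
#' @slot diskCenter numeric length 2, (row, col) of the disk center in px.
#' @slot diskDiameterPx disk diameter in pixels.
#' @slot diskReflectance,backgroundReflectance reflectances in \eqn{[0,1]}.
#' @slot bandCwlNm band center wavelengths in nm.
#' @slot bandRelativeIntensity per-band source-times-detector factor.
#' @slot scatterSigmaPx per-band PSF sigma in pixels.
#' @slot attenuation per-band disk-contrast transmission in \eqn{[0,1]}.
#' @slot exposureTimesMs exposure times in ms (reference exposure = 100 ms).
#' @slot illuminationFalloff fractional brightness loss at the far corner
#'   of the smooth illumination field (0 = perfectly uniform lighting).
#' @slot noiseGaussianSd additive read-noise standard deviation.
#' @slot noisePoissonScale shot-noise scale (sd = scale * sqrt(signal)).
#' @slot seed integer RNG seed; a fixed seed gives bit-identical stacks.
#' @export
setClass("PhantomScene",
  representation(imageH = "integer", imageW = "integer",
                 diskCenter = "numeric", diskDiameterPx = "numeric",
                 diskReflectance = "numeric", backgroundReflectance = "numeric",
                 bandCwlNm = "numeric", bandRelativeIntensity = "numeric",
                 scatterSigmaPx = "numeric", attenuation = "numeric",
                 exposureTimesMs = "numeric", illuminationFalloff = "numeric",
                 noiseGaussianSd = "numeric", noisePoissonScale = "numeric",
                 seed = "integer"))

setValidity("PhantomScene", function(object) {
  if (object@imageH < 8L || object@imageW < 8L)
    return("frame must be at least 8x8")
  nb <- length(object@bandCwlNm)
  if (nb < 1L) return("at least one band required")
  if (length(object@bandRelativeIntensity) != nb ||
      length(object@scatterSigmaPx) != nb || length(object@attenuation) != nb)
    return("per-band vectors must all have length(bandCwlNm)")
  if (any(object@exposureTimesMs <= 0)) return("exposure times must be > 0")
  if (any(object@attenuation < 0 | object@attenuation > 1))
    return("attenuation must lie in [0,1]")
  if (object@illuminationFalloff < 0 || object@illuminationFalloff >= 1)
    return("illuminationFalloff must lie in [0,1)")
  r <- object@diskDiameterPx / 2
  if (object@diskCenter[1L] - r < 1 || object@diskCenter[1L] + r > object@imageH ||
      object@diskCenter[2L] - r < 1 || object@diskCenter[2L] + r > object@imageW)
    return("disk must lie fully inside the frame")
  TRUE
})

#' FlatField: multiplicative illumination-uniformity correction
#'
#' Built from a gray uniform reference patch: the per-pixel gain is the
#' reference mean divided by the reference value, guarded by `floor`
#' against near-zero pixels. Applying the gain to the reference itself
#' yields a constant image at the reference mean (where the guard is
#' inactive).
#'
#' @slot reference the gray-patch capture used.
#' @slot gain per-pixel multiplicative correction, finite and positive.
#' @slot floor the guard value used (on the \eqn{[0,1]} scale).
#' @seealso [buildFlatField()], [applyFlatField()]
#' @export
setClass("FlatField",
  representation(reference = "matrix", gain = "matrix", floor = "numeric"))

setValidity("FlatField", function(object) {
  if (!identical(dim(object@reference), dim(object@gain)))
    return("reference and gain dimensions differ")
  if (any(!is.finite(object@gain)) || min(object@gain) <= 0)
    return("gain must be finite and positive everywhere")
  TRUE
})

#' ProfileReport: cross-section traces and detectability metrics
#'
#' @slot rowProfile full pixel row at `row` (length = image width).
#' @slot colProfile full pixel column at `col` (length = image height).
#' @slot row,col 1-based coordinates of the cross-section.
#' @slot cnr contrast-to-noise ratio against a mask, or `NA` if no mask.
#' @slot stats list of min/max/mean per trace.
#' @seealso [profileReport()], [crossSection()], [cnr()]
#' @export
setClass("ProfileReport",
  representation(rowProfile = "numeric", colProfile = "numeric",
                 row = "integer", col = "integer", cnr = "numeric",
                 stats = "list"))
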