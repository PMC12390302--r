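#' Accessors for NIRfuse containers
#'
#' Small accessor generics so user code never touches slots directly:
#' `frames()` returns the list of frame matrices, `wavelengths()` and
#' `exposures()` the per-frame labels, `nFrames()` the stack length,
#' `frameDim()` the common frame dimensions, `rawWeights()` and
#' `normalizedWeights()` the weight grids, `pyramidLevels()` and
#' `pyramidDepth()` the pyramid contents, `fusedImage()` the fused matrix
#' and `preClipRange()` its pre-clip extrema, `gainMap()` the flat-field
#' gain.
#'
#' @param x the object.
#' @return See each generic's description.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))
#' @rdname accessors
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))
#' @rdname accessors
#' @export
setGeneric("exposures", function(x) standardGeneric("exposures"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("frameDim", function(x) standardGeneric("frameDim"))
#' @rdname accessors
#' @export
setGeneric("rawWeights", function(x) standardGeneric("rawWeights"))
#' @rdname accessors
#' @export
setGeneric("normalizedWeights", function(x) standardGeneric("normalizedWeights"))
#' @rdname accessors
#' @export
setGeneric("pyramidLevels", function(x) standardGeneric("pyramidLevels"))
#' @rdname accessors
#' @export
setGeneric("pyramidDepth", function(x) standardGeneric("pyramidDepth"))
#' @rdname accessors
#' @export
setGeneric("fusedImage", function(x) standardGeneric("fusedImage"))
#' @rdname accessors
#' @export
setGeneric("preClipRange", function(x) standardGeneric("preClipRange"))
#' @rdname accessors
#' @export
setGeneric("gainMap", function(x) standardGeneric("gainMap"))

#' @rdname accessors
setMethod("frames", "ImageStack", function(x) x@frames)
#' @rdname accessors
setMethod("wavelengths", "ImageStack", function(x) x@wavelengthNm)
#' @rdname accessors
setMethod("exposures", "ImageStack", function(x) x@exposureMs)
#' @rdname accessors
setMethod("nFrames", "ImageStack", function(x) length(x@frames))
#' @rdname accessors
setMethod("frameDim", "ImageStack", function(x) dim(x@frames[[1L]]))
#' @rdname accessors
setMethod("nFrames", "WeightStack", function(x) length(x@raw))
#' @rdname accessors
setMethod("frameDim", "WeightStack", function(x) dim(x@raw[[1L]]))
#' @rdname accessors
setMethod("rawWeights", "WeightStack", function(x) x@raw)
#' @rdname accessors
setMethod("normalizedWeights", "WeightStack", function(x) x@normalized)
#' @rdname accessors
setMethod("pyramidLevels", "ImagePyramid", function(x) x@levels)
#' @rdname accessors
setMethod("pyramidDepth", "ImagePyramid", function(x) length(x@levels))
#' @rdname accessors
setMethod("fusedImage", "FusionResult", function(x) x@fused)
#' @rdname accessors
setMethod("preClipRange", "FusionResult", function(x) x@preClipRange)
#' @rdname accessors
setMethod("gainMap", "FlatField", function(x) x@gain)

setMethod("show", "ImageStack", function(object) {
  d <- frameDim(object)
  cat(sprintf("ImageStack: %d frames of %dx%d px\n",
              nFrames(object), d[1L], d[2L]))
  cat(sprintf("  bands (nm): %s\n",
              paste(sort(unique(object@wavelengthNm)), collapse = ", ")))
  cat(sprintf("  exposures (ms): %s\n",
              paste(signif(sort(unique(object@exposureMs)), 4), collapse = ", ")))
  cat(sprintf("  factorial design: %s\n", isFactorial(object)))
})

setMethod("show", "WeightStack", function(object) {
  d <- frameDim(object)
  cat(sprintf("WeightStack: %d weight grids of %dx%d px (sigma = %g)\n",
              nFrames(object), d[1L], d[2L], object@sigma))
})

setMethod("show", "ImagePyramid", function(object) {
  dims <- vapply(object@levels, function(l) sprintf("%dx%d", nrow(l), ncol(l)), "")
  cat(sprintf("ImagePyramid (%s): depth %d [%s]\n",
              object@variant, pyramidDepth(object), paste(dims, collapse = " > ")))
})

setMethod("show", "FusionResult", function(object) {
  cat(sprintf("FusionResult: %dx%d px, mode = %s, strategy = %s, depth = %d\n",
              nrow(object@fused), ncol(object@fused),
              object@mode, object@strategy, object@depth))
  cat(sprintf("  pre-clip range: [%.4g, %.4g]\n",
              object@preClipRange[1L], object@preClipRange[2L]))
})

setMethod("show", "PhantomScene", function(object) {
  cat(sprintf("PhantomScene: %dx%d px, disk %.3g px dia at (%.4g, %.4g)\n",
              object@imageH, object@imageW, object@diskDiameterPx,
              object@diskCenter[1L], object@diskCenter[2L]))
  cat(sprintf("  %d bands %g-%g nm x %d exposures %.4g-%.4g ms (seed %d)\n",
              length(object@bandCwlNm), min(object@bandCwlNm),
              max(object@bandCwlNm), length(object@exposureTimesMs),
              min(object@exposureTimesMs), max(object@exposureTimesMs),
              object@seed))
})

setMethod("show", "FlatField", function(object) {
  cat(sprintf("FlatField: %dx%d px, gain range [%.4g, %.4g], floor %g\n",
              nrow(object@gain), ncol(object@gain),
              min(object@gain), max(object@gain), object@floor))
})

setMethod("show", "ProfileReport", function(object) {
  cat(sprintf("ProfileReport at (row %d, col %d): traces %d (row) / %d (col)\n",
              object@row, object@col, length(object@rowProfile),
              length(object@colProfile)))
  if (!is.na(object@cnr)) cat(sprintf("  CNR vs mask: %.4g\n", object@cnr))
})

#' Construct an ImageStack
#'
#' @param frames list of numeric matrices in \eqn{[0,1]}, identical dims.
#' @param wavelengthNm per-frame band center wavelength (nm).
#' @param exposureMs per-frame exposure time (ms).
#' @param metadata optional provenance list.
#' @return An [ImageStack-class] object, frames sorted by
#'   (wavelength, exposure).
#' @examples
#' s <- imageStack(list(matrix(0.2, 4, 4), matrix(0.8, 4, 4)),
#'                 wavelengthNm = c(713, 713), exposureMs = c(10, 20))
#' nFrames(s)
#' @export
imageStack <- function(frames, wavelengthNm, exposureMs, metadata = list()) {
  ord <- order(wavelengthNm, exposureMs)
  new("ImageStack", frames = frames[ord],
      wavelengthNm = as.numeric(wavelengthNm)[ord],
      exposureMs = as.numeric(exposureMs)[ord], metadata = metadata)
}

#' Is a stack a complete factorial (band x exposure) acquisition?
#'
#' TRUE when every band was captured at the same full set of exposure
#' times, so that `nFrames = n_bands * n_exposures`. Required by the
#' two-stage fusion strategy.
#'
#' @param stack an [ImageStack-class].
#' @return logical.
#' @export
isFactorial <- function(stack) {
  stopifnot(is(stack, "ImageStack"))
  tab <- table(stack@wavelengthNm, stack@exposureMs)
  all(tab == 1L)
}
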