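#' Build a flat-field correction from a gray uniform patch
#'
#' Illumination and detector response are rarely uniform across the
#' frame; imaging a gray uniform patch records that non-uniformity per
#' band. The correction is multiplicative:
#' `gain(p) = mean(reference) / max(reference(p), floor)`, so applying it
#' to the reference itself yields a constant image at the reference mean
#' wherever the guard is inactive. The `floor` guard caps the gain at
#' `mean / floor` so dead or near-black reference pixels cannot explode
#' the correction.
#'
#' @param reference numeric matrix in \eqn{[0,1]}: the gray-patch capture.
#' @param floor positive guard on the \eqn{[0,1]} scale (default 1e-3,
#'   capping gain near 1000x).
#' @return A [FlatField-class].
#' @examples
#' ff <- buildFlatField(matrix(0.5, 4, 4))
#' range(gainMap(ff))  # 1 1
#' @export
buildFlatField <- function(reference, floor = 1e-3) {
  reference <- .asImage(reference, "reference")
  if (!is.numeric(floor) || length(floor) != 1L || floor <= 0)
    stop("floor must be a positive number", call. = FALSE)
  m <- mean(reference)
  if (m <= floor)
    stop(sprintf("reference patch too dark to calibrate: mean %.3g <= floor %.3g",
                 m, floor), call. = FALSE)
  gain <- m / pmax(reference, floor)
  new("FlatField", reference = reference, gain = gain, floor = floor)
}

#' Apply a flat-field correction
#'
#' Multiplies each pixel by the flat-field gain and clips to \eqn{[0,1]}.
#' For an [ImageStack-class], `ff` may be a single [FlatField-class]
#' (one global reference applied to all bands) or a list of flat fields
#' named by band center wavelength (`"713"`, ...), applied per band.
#'
#' @param x numeric matrix or [ImageStack-class].
#' @param ff a [FlatField-class], or for stacks optionally a named list
#'   of them keyed by wavelength.
#' @return corrected object of the same class as `x`.
#' @export
setGeneric("applyFlatField", function(x, ff) standardGeneric("applyFlatField"))

#' @rdname applyFlatField
setMethod("applyFlatField", signature("matrix", "FlatField"), function(x, ff) {
  x <- .asImage(x)
  if (!identical(dim(x), dim(ff@gain)))
    stop(sprintf("image is %dx%d but flat field is %dx%d",
                 nrow(x), ncol(x), nrow(ff@gain), ncol(ff@gain)), call. = FALSE)
  .clip01(x * ff@gain)
})

#' @rdname applyFlatField
setMethod("applyFlatField", signature("ImageStack", "FlatField"), function(x, ff) {
  initialize(x, frames = lapply(frames(x), applyFlatField, ff = ff))
})

#' @rdname applyFlatField
setMethod("applyFlatField", signature("ImageStack", "list"), function(x, ff) {
  keys <- as.character(wavelengths(x))
  missing <- setdiff(unique(keys), names(ff))
  if (length(missing))
    stop(sprintf("no flat field supplied for band(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  corrected <- Map(function(f, k) applyFlatField(f, ff[[k]]), frames(x), keys)
  initialize(x, frames = corrected)
})
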