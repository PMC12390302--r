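#' Contrast weight: absolute Laplacian-filter response
#'
#' Applies a discrete Laplacian to the (grayscale) image and takes the
#' per-pixel absolute value, so edges and texture receive high weight and
#' flat regions zero. The default stencil is the 4-neighbor Laplacian
#' `[[0,1,0],[1,-4,1],[0,1,0]]` with mirror border; an 8-neighbor variant
#' is selectable. Arrays with a third (channel) dimension are reduced to
#' luminance (Rec. 601) first.
#'
#' @param img numeric matrix in \eqn{[0,1]}, or an `h x w x 3` array.
#' @param neighbors 4 (default) or 8, the Laplacian stencil.
#' @return non-negative numeric matrix of the same dimensions.
#' @examples
#' contrastWeight(matrix(0.5, 4, 4))  # all zero: constants have no contrast
#' @export
contrastWeight <- function(img, neighbors = 4L) {
  if (is.array(img) && length(dim(img)) == 3L) img <- toLuminance(img)
  img <- .asImage(img)
  lap <- .shiftReflect(img, -1L, 0L) + .shiftReflect(img, 1L, 0L) +
         .shiftReflect(img, 0L, -1L) + .shiftReflect(img, 0L, 1L) - 4 * img
  if (neighbors == 8L) {
    lap <- lap + .shiftReflect(img, -1L, -1L) + .shiftReflect(img, -1L, 1L) +
           .shiftReflect(img, 1L, -1L) + .shiftReflect(img, 1L, 1L) - 4 * img
  } else if (neighbors != 4L) {
    stop("neighbors must be 4 or 8", call. = FALSE)
  }
  abs(lap)
}

#' Rec. 601 luminance of an RGB array
#'
#' @param img `h x w x 3` numeric array.
#' @return numeric matrix `0.299 R + 0.587 G + 0.114 B`.
#' @export
toLuminance <- function(img) {
  stopifnot(is.array(img), length(dim(img)) == 3L, dim(img)[3L] >= 3L)
  0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L]
}

#' Exposedness weight: Gaussian affinity to mid-gray
#'
#' Per-pixel \eqn{E(i) = \exp(-(i - 0.5)^2 / (2\sigma^2))} on normalized
#' intensities, favoring pixels that are neither underexposed (near 0)
#' nor saturated (near 1). The weight peaks at exactly 1 for `i = 0.5`
#' and is symmetric about it. The default `sigma = 2` keeps E close to
#' flat across \eqn{[0,1]} (range about 0.969 to 1), so contrast
#' dominates the combined weight; `sigma` is exposed for stacks where a
#' sharper exposure preference is wanted.
#'
#' @param img numeric matrix in \eqn{[0,1]}.
#' @param sigma positive width of the Gaussian (dimensionless, default 2).
#' @return numeric matrix with values in \eqn{(0, 1]}.
#' @examples
#' exposednessWeight(matrix(0.5, 2, 2))       # exactly 1
#' exposednessWeight(matrix(0, 1, 1), 2)      # exp(-0.03125)
#' @export
exposednessWeight <- function(img, sigma = 2) {
  img <- .asImage(img)
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop("sigma must be a positive number", call. = FALSE)
  exp(-(img - 0.5)^2 / (2 * sigma^2))
}

#' Combine contrast and exposedness into a raw quality weight
#'
#' Element-wise product \eqn{W = C \cdot E}.
#'
#' @param contrast,exposedness numeric matrices of identical dimensions.
#' @return non-negative numeric matrix.
#' @export
combineWeights <- function(contrast, exposedness) {
  if (!identical(dim(contrast), dim(exposedness)))
    stop(sprintf("weight grids differ in dimensions: %dx%d vs %dx%d",
                 nrow(contrast), ncol(contrast),
                 nrow(exposedness), ncol(exposedness)), call. = FALSE)
  contrast * exposedness
}

#' Normalize raw weights across a stack
#'
#' Divides each raw grid by the per-pixel sum over the stack,
#' \eqn{\hat W_k = W_k / \sum_n W_n}, so the normalized weights form a
#' per-pixel convex combination. At pixels where every frame has
#' (numerically) zero weight — flat and ill-exposed in all frames — the
#' sum is below `eps` and the weights fall back to the uniform `1/N`,
#' which keeps normalization exact and the result deterministic.
#'
#' @param raw list of non-negative numeric matrices, identical dims.
#' @param eps zero-sum guard (default 1e-12).
#' @return list of matrices summing to 1 at every pixel.
#' @examples
#' normalizeWeights(list(matrix(1, 2, 2), matrix(3, 2, 2)))  # 0.25 / 0.75
#' @export
normalizeWeights <- function(raw, eps = 1e-12) {
  if (!is.list(raw) || length(raw) < 1L)
    stop("raw must be a nonempty list of weight grids", call. = FALSE)
  d <- dim(raw[[1L]])
  for (i in seq_along(raw)) {
    if (!identical(dim(raw[[i]]), d))
      stop(sprintf("weight grid %d has inconsistent dimensions", i), call. = FALSE)
    if (min(raw[[i]]) < 0)
      stop(sprintf("weight grid %d has negative entries", i), call. = FALSE)
  }
  n <- length(raw)
  tot <- Reduce(`+`, raw)
  dead <- tot < eps
  tot[dead] <- 1  # denominator placeholder; overwritten below
  lapply(raw, function(w) {
    h <- w / tot
    h[dead] <- 1 / n
    h
  })
}

#' Compute the full weight stack for an image stack
#'
#' Runs the weight pipeline per frame — contrast ([contrastWeight()])
#' times exposedness ([exposednessWeight()]) — then normalizes across
#' frames with [normalizeWeights()]. Frame order is preserved, so
#' permuting the stack permutes the weight grids identically.
#'
#' @param stack an [ImageStack-class].
#' @param sigma exposedness width (default 2).
#' @param neighbors Laplacian stencil for the contrast weight (4 or 8).
#' @param eps zero-sum guard for normalization.
#' @return A [WeightStack-class].
#' @export
computeWeightStack <- function(stack, sigma = 2, neighbors = 4L, eps = 1e-12) {
  stopifnot(is(stack, "ImageStack"))
  raw <- lapply(frames(stack), function(f)
    combineWeights(contrastWeight(f, neighbors), exposednessWeight(f, sigma)))
  new("WeightStack", raw = raw, normalized = normalizeWeights(raw, eps),
      sigma = sigma)
}

#' Dump weight grids to a multi-page float TIFF for inspection
#'
#' @param wstack a [WeightStack-class].
#' @param path output TIFF path.
#' @param which `"normalized"` (default) or `"raw"`; raw grids are
#'   rescaled by their global maximum to fit the TIFF \eqn{[0,1]} range.
#' @return `path`, invisibly.
#' @export
writeWeightDump <- function(wstack, path, which = c("normalized", "raw")) {
  stopifnot(is(wstack, "WeightStack"))
  which <- match.arg(which)
  grids <- if (which == "raw") {
    m <- max(vapply(wstack@raw, max, 0), 1e-12)
    lapply(wstack@raw, function(w) w / m)
  } else wstack@normalized
  tiff::writeTIFF(grids, path, bits.per.sample = 32L)
  invisible(path)
}
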