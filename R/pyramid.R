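#' The pyramid generating kernel
#'
#' The separable 5-tap binomial kernel `c(1, 4, 6, 4, 1) / 16` — the
#' classical generating kernel for Gaussian/Laplacian pyramids. Its
#' weights sum to 1, so smoothing preserves constant images. All pyramid
#' operations accept an alternative odd-length kernel; a kernel whose
#' weights do not sum to 1 is rejected.
#'
#' @return numeric vector of length 5 summing to 1.
#' @export
pyramidKernel <- function() c(1, 4, 6, 4, 1) / 16

.checkKernel <- function(kernel) {
  if (length(kernel) %% 2L == 0L)
    stop("smoothing kernel must have odd length", call. = FALSE)
  if (abs(sum(kernel) - 1) > 1e-12)
    stop("smoothing kernel weights must sum to 1", call. = FALSE)
  kernel
}

#' Maximum feasible pyramid depth for an image size
#'
#' Levels shrink by ceiling division until the 1x1 level is reached;
#' beyond that further levels would be degenerate copies. For an `h x w`
#' image the maximum depth is `1 + ceiling(log2(max(h, w)))` (1 for a
#' 1x1 image).
#'
#' @param h,w image dimensions.
#' @return integer, the largest valid `depth`.
#' @export
maxPyramidDepth <- function(h, w) {
  m <- max(h, w)
  if (m <= 1L) return(1L)
  1L + as.integer(ceiling(log2(m)))
}

#' Default pyramid depth
#'
#' `floor(log2(min(h, w)))`, so the coarsest level is about 2 px on the
#' short side (never less than 1, never more than the feasible maximum).
#'
#' @param h,w image dimensions.
#' @return integer depth.
#' @export
defaultPyramidDepth <- function(h, w) {
  d <- max(1L, as.integer(floor(log2(min(h, w)))))
  min(d, maxPyramidDepth(h, w))
}

.checkDepth <- function(depth, h, w) {
  depth <- as.integer(depth)
  if (is.na(depth) || depth < 1L)
    stop("depth must be a positive integer", call. = FALSE)
  mx <- maxPyramidDepth(h, w)
  if (depth > mx)
    stop(sprintf("depth %d infeasible for a %dx%d image: maximum depth is %d",
                 depth, h, w, mx), call. = FALSE)
  depth
}

#' Low-pass filter and downsample an image by two
#'
#' Smooths with the separable generating kernel (mirror border) and
#' decimates by keeping every other row and column starting from the
#' first, so an `h x w` image becomes `ceil(h/2) x ceil(w/2)`. A 1x1
#' image is returned unchanged.
#'
#' @param img numeric matrix.
#' @param kernel odd-length smoothing kernel summing to 1.
#' @return numeric matrix of dimensions `ceiling(dim(img) / 2)`.
#' @examples
#' dim(smoothDownsample(matrix(runif(25), 5, 5)))  # 3 x 3
#' @export
smoothDownsample <- function(img, kernel = pyramidKernel()) {
  img <- .asImage(img)
  .checkKernel(kernel)
  s <- .convSeparable(img, kernel)
  s[seq.int(1L, nrow(s), by = 2L), seq.int(1L, ncol(s), by = 2L), drop = FALSE]
}

#' Upsample an image to the exact dimensions of its parent level
#'
#' The transpose of [smoothDownsample()]: zeros are inserted at the
#' decimated positions and the result is smoothed with the generating
#' kernel scaled by 2 per axis (mirror border), which preserves constants
#' and interpolates the missing samples. The target dimensions must be
#' consistent with the input (`dim(img) == ceiling(target / 2)`), so any
#' image size — odd or even — round-trips through the pyramid.
#'
#' @param img numeric matrix (the coarser level).
#' @param targetH,targetW dimensions of the finer level.
#' @inheritParams smoothDownsample
#' @return numeric `targetH x targetW` matrix.
#' @export
upsampleTo <- function(img, targetH, targetW, kernel = pyramidKernel()) {
  img <- .asImage(img)
  .checkKernel(kernel)
  targetH <- as.integer(targetH); targetW <- as.integer(targetW)
  if (nrow(img) != ceiling(targetH / 2) || ncol(img) != ceiling(targetW / 2))
    stop(sprintf("cannot upsample %dx%d to %dx%d: source must be ceil(target/2)",
                 nrow(img), ncol(img), targetH, targetW), call. = FALSE)
  u <- matrix(0, targetH, targetW)
  u[seq.int(1L, targetH, by = 2L), seq.int(1L, targetW, by = 2L)] <- img
  # along a length-1 axis zero-insertion is the identity; skip its pass
  if (targetH > 1L) u <- .convAxis(u, 2 * kernel, 1L)
  if (targetW > 1L) u <- .convAxis(u, 2 * kernel, 2L)
  u
}

#' Build a Gaussian pyramid
#'
#' Level 1 is the input; each further level is
#' `smoothDownsample(previous)`.
#'
#' @param img numeric matrix.
#' @param depth number of levels (default [defaultPyramidDepth()]).
#' @inheritParams smoothDownsample
#' @return An [ImagePyramid-class] with `variant = "gaussian"`.
#' @examples
#' p <- buildGaussian(matrix(runif(64), 8, 8), depth = 3)
#' pyramidDepth(p)
#' @export
buildGaussian <- function(img, depth = defaultPyramidDepth(nrow(img), ncol(img)),
                          kernel = pyramidKernel()) {
  img <- .asImage(img)
  depth <- .checkDepth(depth, nrow(img), ncol(img))
  levels <- vector("list", depth)
  levels[[1L]] <- img
  for (l in seq_len(depth - 1L))
    levels[[l + 1L]] <- smoothDownsample(levels[[l]], kernel)
  new("ImagePyramid", levels = levels, variant = "gaussian")
}

#' Build a Laplacian pyramid
#'
#' Levels `1 .. depth-1` store the band-pass residuals
#' `G_l - upsampleTo(G_{l+1})`; the coarsest level stores the low-pass
#' residue `G_depth` itself. Because the residuals are defined against
#' the same upsampling operator used by [collapsePyramid()], the
#' reconstruction is exact to floating-point round-off. Residual layers
#' may be negative or exceed 1; only final fused output is clipped.
#'
#' @inheritParams buildGaussian
#' @return An [ImagePyramid-class] with `variant = "laplacian"`.
#' @examples
#' x <- matrix(runif(15 * 17), 15, 17)
#' max(abs(collapsePyramid(buildLaplacian(x, 4)) - x))  # ~1e-16
#' @export
buildLaplacian <- function(img, depth = defaultPyramidDepth(nrow(img), ncol(img)),
                           kernel = pyramidKernel()) {
  g <- buildGaussian(img, depth, kernel)
  depth <- pyramidDepth(g)
  levels <- vector("list", depth)
  for (l in seq_len(depth - 1L)) {
    gl <- g@levels[[l]]
    levels[[l]] <- gl - upsampleTo(g@levels[[l + 1L]], nrow(gl), ncol(gl), kernel)
  }
  levels[[depth]] <- g@levels[[depth]]
  new("ImagePyramid", levels = levels, variant = "laplacian")
}

#' Collapse a Laplacian pyramid back to an image
#'
#' Starting from the coarsest (low-pass) level, repeatedly upsample and
#' add the next residual until the finest level is consumed. Output is
#' not clipped: clipping is the fusion pipeline's final step, so fused
#' pyramids can overshoot \eqn{[0,1]} here without information loss.
#'
#' @param pyr an [ImagePyramid-class] with `variant = "laplacian"`.
#' @inheritParams smoothDownsample
#' @return numeric matrix with the dimensions of level 1.
#' @export
collapsePyramid <- function(pyr, kernel = pyramidKernel()) {
  stopifnot(is(pyr, "ImagePyramid"))
  if (pyr@variant != "laplacian")
    stop("collapse is defined only for Laplacian pyramids", call. = FALSE)
  depth <- pyramidDepth(pyr)
  acc <- pyr@levels[[depth]]
  for (l in rev(seq_len(depth - 1L))) {
    target <- pyr@levels[[l]]
    acc <- upsampleTo(acc, nrow(target), ncol(target), kernel) + target
  }
  acc
}
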