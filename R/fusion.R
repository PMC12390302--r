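.checkAligned <- function(stack, wstack) {
  if (nFrames(stack) != nFrames(wstack))
    stop(sprintf("stack has %d frames but weight stack has %d",
                 nFrames(stack), nFrames(wstack)), call. = FALSE)
  if (!identical(frameDim(stack), frameDim(wstack)))
    stop("stack and weight stack dimensions differ", call. = FALSE)
}

.provenance <- function(stack, sigma, depth, mode, strategy, preClip) {
  list(wavelengthNm = wavelengths(stack), exposureMs = exposures(stack),
       nFrames = nFrames(stack), sigma = sigma, depth = depth,
       mode = mode, strategy = strategy, preClipRange = preClip)
}

## Unclipped naive weighted average; shared by both public engines.
.fuseNaiveCore <- function(stack, wstack) {
  Reduce(`+`, Map(`*`, normalizedWeights(wstack), frames(stack)))
}

## Unclipped pyramid blend: fused Laplacian level l is the per-pixel sum
## over frames of (Gaussian level l of the normalized weight) times
## (Laplacian level l of the frame); collapse afterwards. No per-level
## renormalization: the Gaussian smoothing of weights that sum to 1
## pixel-wise keeps the level sums equal to 1 by linearity.
.fusePyramidCore <- function(stack, wstack, depth, kernel) {
  ipyrs <- lapply(frames(stack), buildLaplacian, depth = depth, kernel = kernel)
  wpyrs <- lapply(normalizedWeights(wstack), buildGaussian, depth = depth,
                  kernel = kernel)
  fusedLevels <- lapply(seq_len(depth), function(l)
    Reduce(`+`, Map(function(ip, wp) wp@levels[[l]] * ip@levels[[l]],
                    ipyrs, wpyrs)))
  collapsePyramid(new("ImagePyramid", levels = fusedLevels,
                      variant = "laplacian"), kernel)
}

#' Naive per-pixel weighted-average fusion
#'
#' Fuses the stack as \eqn{\hat R = \sum_n \hat W_n I_n}: a per-pixel
#' convex combination of the frames with the normalized weights. The
#' result is therefore bounded by the per-pixel min and max over frames
#' and needs no clipping; the simple average is prone to visible seams
#' where weights fluctuate rapidly — see [fusePyramid()].
#'
#' @param stack an [ImageStack-class].
#' @param wstack an aligned [WeightStack-class] (same N, same dims).
#' @return A [FusionResult-class] with `mode = "naive"`.
#' @export
fuseNaive <- function(stack, wstack) {
  stopifnot(is(stack, "ImageStack"), is(wstack, "WeightStack"))
  .checkAligned(stack, wstack)
  r <- .fuseNaiveCore(stack, wstack)
  pre <- range(r)
  new("FusionResult", fused = .clip01(r), mode = "naive", strategy = "flat",
      depth = 1L, preClipRange = pre,
      provenance = .provenance(stack, wstack@sigma, 1L, "naive", "flat", pre))
}

#' Laplacian-pyramid blended fusion
#'
#' Blends each Laplacian level of the frames with the corresponding
#' Gaussian level of the normalized weight maps (used as alpha masks) and
#' collapses the fused pyramid. Smoothing the weights at every scale
#' removes the stitch-line artifacts of the naive average while the
#' band-pass frame content keeps detail sharp. With `depth = 1` the
#' pyramid degenerates to a single level and the result equals
#' [fuseNaive()]. The collapsed image can slightly overshoot
#' \eqn{[0,1]}; the final result is clipped and the pre-clip range is
#' recorded in the provenance.
#'
#' @inheritParams fuseNaive
#' @param depth pyramid depth (default [defaultPyramidDepth()]).
#' @param kernel pyramid generating kernel.
#' @return A [FusionResult-class] with `mode = "pyramid"`.
#' @export
fusePyramid <- function(stack, wstack,
                        depth = defaultPyramidDepth(frameDim(stack)[1L],
                                                    frameDim(stack)[2L]),
                        kernel = pyramidKernel()) {
  stopifnot(is(stack, "ImageStack"), is(wstack, "WeightStack"))
  .checkAligned(stack, wstack)
  d <- frameDim(stack)
  depth <- .checkDepth(depth, d[1L], d[2L])
  r <- .fusePyramidCore(stack, wstack, depth, kernel)
  pre <- range(r)
  new("FusionResult", fused = .clip01(r), mode = "pyramid", strategy = "flat",
      depth = depth, preClipRange = pre,
      provenance = .provenance(stack, wstack@sigma, depth, "pyramid", "flat", pre))
}

#' Fuse a multi-exposure multispectral stack
#'
#' The top-level fusion orchestration. `strategy = "flat"` computes one
#' weight stack over all N frames and fuses them in a single pass (the
#' default: with the 10-band x 10-exposure acquisition design, N = 100).
#' `strategy = "two_stage"` first merges the exposure series within each
#' band, then fuses the per-band results — the iterative variant; it
#' requires a complete factorial (band x exposure) stack and fails at
#' validation otherwise. Both strategies use the selected `mode`
#' ([fuseNaive()] or [fusePyramid()]) throughout.
#'
#' @param stack an [ImageStack-class].
#' @param sigma exposedness width passed to [computeWeightStack()].
#' @param depth pyramid depth, or `NULL` for [defaultPyramidDepth()];
#'   ignored by `mode = "naive"`.
#' @param mode `"pyramid"` (default) or `"naive"`.
#' @param strategy `"flat"` (default) or `"two_stage"`.
#' @param neighbors Laplacian stencil for the contrast weight.
#' @param kernel pyramid generating kernel.
#' @return A [FusionResult-class] carrying full provenance.
#' @examples
#' sc <- defaultScene(seed = 1)
#' ph <- generateStack(sc)
#' res <- fuseStack(ph$stack, mode = "pyramid", strategy = "flat")
#' res
#' @export
fuseStack <- function(stack, sigma = 2, depth = NULL,
                      mode = c("pyramid", "naive"),
                      strategy = c("flat", "two_stage"),
                      neighbors = 4L, kernel = pyramidKernel()) {
  stopifnot(is(stack, "ImageStack"))
  mode <- match.arg(mode)
  strategy <- match.arg(strategy)
  d <- frameDim(stack)
  if (is.null(depth)) depth <- defaultPyramidDepth(d[1L], d[2L])
  if (mode == "pyramid") depth <- .checkDepth(depth, d[1L], d[2L])

  fuseOnce <- function(s) {
    w <- computeWeightStack(s, sigma = sigma, neighbors = neighbors)
    if (mode == "naive") .fuseNaiveCore(s, w)
    else .fusePyramidCore(s, w, depth, kernel)
  }

  if (strategy == "flat") {
    r <- fuseOnce(stack)
  } else {
    if (!isFactorial(stack))
      stop("two_stage strategy requires a complete factorial (band x exposure) stack",
           call. = FALSE)
    bands <- sort(unique(wavelengths(stack)))
    perBand <- lapply(bands, function(b) {
      sel <- which(wavelengths(stack) == b)
      sub <- imageStack(frames(stack)[sel], wavelengths(stack)[sel],
                        exposures(stack)[sel])
      # stage-1 result may overshoot [0,1] before the final clip; clip here
      # so the stage-2 stack is a valid acquisition-range ImageStack
      .clip01(fuseOnce(sub))
    })
    bandStack <- imageStack(perBand, wavelengthNm = bands,
                            exposureMs = rep(0, length(bands)))
    r <- fuseOnce(bandStack)
  }
  depthUsed <- if (mode == "naive") 1L else as.integer(depth)
  pre <- range(r)
  new("FusionResult", fused = .clip01(r), mode = mode, strategy = strategy,
      depth = depthUsed, preClipRange = pre,
      provenance = .provenance(stack, sigma, depthUsed, mode, strategy, pre))
}
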