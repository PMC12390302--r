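## Run expr under a fixed seed without disturbing the caller's RNG state.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Default synthetic acquisition scene
#'
#' Encodes the reference acquisition design the simulator emulates: a
#' 256x256 frame; a dense disk of 125 px diameter centered in the frame
#' under a diffusive layer; 10 NIR bands at center wavelengths 713, 736,
#' 759, 782, 805, 828, 851, 874, 897 and 920 nm; and 10 exposures evenly
#' log-spaced from 30 to 240 ms about a 100 ms reference — an 8x ladder
#' matching the acquisition's dynamic range (band brightness times
#' illumination falloff), so the shortest exposure underexposes every
#' band and the longest partially saturates the brightest bands. Band brightness (source spectrum times
#' detector sensitivity) falls from 1.0 to 0.35 with wavelength, so
#' frames are brighter at lower wavelengths; scattering blur falls from
#' 12 to 4 px and disk-contrast transmission rises from 0.15 to 0.75
#' with wavelength, reflecting the deeper penetration of longer NIR
#' wavelengths. The disk (reflectance 0.25) is darker than the
#' background (0.55) and appears as a dark spot once recovered. The
#' halogen lamp sits off-axis, so illumination is not uniform: the field
#' loses 30% of its brightness from the brightest point (offset toward
#' the lamp) to the far corner — the non-uniformity the gray-patch
#' flat-field calibration exists to remove.
#'
#' @param seed integer RNG seed threaded into [generateStack()].
#' @return A [PhantomScene-class]; two calls with the same seed are
#'   identical.
#' @examples
#' defaultScene(seed = 0)
#' @export
defaultScene <- function(seed = 0L) {
  nb <- 10L
  new("PhantomScene",
      imageH = 256L, imageW = 256L,
      diskCenter = c(128, 128), diskDiameterPx = 125,
      diskReflectance = 0.25, backgroundReflectance = 0.55,
      bandCwlNm = c(713, 736, 759, 782, 805, 828, 851, 874, 897, 920),
      bandRelativeIntensity = seq(1.0, 0.35, length.out = nb),
      scatterSigmaPx = seq(12, 4, length.out = nb),
      attenuation = seq(0.15, 0.75, length.out = nb),
      exposureTimesMs = round(exp(seq(log(30), log(240), length.out = 10L)), 1),
      illuminationFalloff = 0.3,
      noiseGaussianSd = 0.01, noisePoissonScale = 0.01,
      seed = as.integer(seed))
}

#' Ground-truth disk mask for a scene
#'
#' Hard binary mask: pixel centers within `diskDiameterPx / 2` of the
#' disk center.
#'
#' @param scene a [PhantomScene-class].
#' @return logical matrix, `TRUE` on the disk.
#' @export
sceneMask <- function(scene) {
  stopifnot(is(scene, "PhantomScene"))
  r <- matrix(seq_len(scene@imageH), scene@imageH, scene@imageW)
  cc <- matrix(seq_len(scene@imageW), scene@imageH, scene@imageW, byrow = TRUE)
  (r - scene@diskCenter[1L])^2 + (cc - scene@diskCenter[2L])^2 <=
    (scene@diskDiameterPx / 2)^2
}

#' Measure a mask's disk diameter in pixels
#'
#' The widest row extent of the foreground: `max(col) - min(col) + 1`
#' maximized over rows. On the default scene this recovers the
#' configured 125 px exactly.
#'
#' @param mask logical (or 0/1) matrix with a single disk.
#' @return numeric, diameter in pixels.
#' @export
measureDiskDiameter <- function(mask) {
  if (!is.logical(mask)) mask <- mask > 0
  rows <- which(rowSums(mask) > 0)
  if (length(rows) == 0L) stop("mask has no foreground", call. = FALSE)
  max(vapply(rows, function(r) {
    cols <- which(mask[r, ])
    max(cols) - min(cols) + 1L
  }, integer(1L)))
}

#' Smooth illumination field of the scene
#'
#' The off-axis lamp makes illumination fall off smoothly across the
#' frame: a quadratic falloff from 1 at the brightest point — offset
#' toward the lamp side, at 40% of the frame height on the center
#' column — down to `1 - illuminationFalloff` at the farthest corner.
#' Band-independent (the lamp geometry does not change with the
#' filter), so a single gray-patch reference calibrates every band.
#'
#' @param scene a [PhantomScene-class].
#' @return numeric matrix in `[1 - falloff, 1]`.
#' @export
illuminationField <- function(scene) {
  stopifnot(is(scene, "PhantomScene"))
  h <- scene@imageH; w <- scene@imageW
  r0 <- 0.4 * h; c0 <- 0.5 * w
  r <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  d2 <- (r - r0)^2 + (cc - c0)^2
  1 - scene@illuminationFalloff * d2 / max(d2)
}

#' Ideal gray-patch reference capture
#'
#' The calibration frame of the acquisition protocol: a uniform gray
#' patch (reflectance 0.5) imaged under the scene's illumination field
#' at the reference exposure, noise-free. Feeding it to
#' [buildFlatField()] yields the gain map that flattens the
#' illumination non-uniformity of every band.
#'
#' @param scene a [PhantomScene-class].
#' @return numeric matrix in \eqn{[0,1]}.
#' @export
grayPatchReference <- function(scene) {
  stopifnot(is(scene, "PhantomScene"))
  0.5 * illuminationField(scene)
}

#' Render the ideal (noise-free, unit-exposure) radiance of one band
#'
#' The optical model is deliberately minimal: the reflectance field is
#' the uniform background plus the disk's contrast scaled by the band's
#' transmission factor; the field is blurred by a Gaussian point-spread
#' function of the band's scattering sigma (mirror border, so the
#' spatial flux of the disk signal is conserved); the result is
#' multiplied by the smooth illumination field and scaled by the band's
#' relative intensity. Deterministic given the scene.
#'
#' @param scene a [PhantomScene-class].
#' @param band band index in `1..length(bandCwlNm)`.
#' @return numeric matrix, the ideal radiance at the 100 ms reference
#'   exposure.
#' @export
renderBand <- function(scene, band) {
  stopifnot(is(scene, "PhantomScene"))
  band <- as.integer(band)
  if (is.na(band) || band < 1L || band > length(scene@bandCwlNm))
    stop(sprintf("band must be in 1..%d", length(scene@bandCwlNm)), call. = FALSE)
  contrast <- scene@diskReflectance - scene@backgroundReflectance
  refl <- scene@backgroundReflectance +
    contrast * scene@attenuation[band] * sceneMask(scene)
  refl <- .gaussBlur(refl, scene@scatterSigmaPx[band])
  refl * illuminationField(scene) * scene@bandRelativeIntensity[band]
}

#' Generate the full synthetic acquisition stack with ground truth
#'
#' For every (band, exposure) pair the frame is
#' `clip(radiance * exposure / 100ms + noise, 0, 1)` with Poisson-like
#' shot noise (sd = `noisePoissonScale * sqrt(signal)`) plus additive
#' Gaussian read noise, drawn from the scene's seeded generator. With
#' the default exposures the shortest frame underexposes (mean < 0.2 in
#' every band) and the longest saturates part of the acquisition (over
#' 1% of pixels clipped at 1.0 in the brighter bands, while the dark
#' disk, the dimmer corners and the dim long-wavelength bands clip
#' last). Fixing the seed makes the stack
#' bit-identical across calls; changing it changes only the noise,
#' never the ground truth.
#'
#' @param scene a [PhantomScene-class].
#' @return list with elements `stack` (an [ImageStack-class] of
#'   `n_bands * n_exposures` frames; 100 in the default design) and
#'   `truth` (the logical disk mask from [sceneMask()]).
#' @examples
#' ph <- generateStack(defaultScene(seed = 0))
#' nFrames(ph$stack)  # 100
#' @export
generateStack <- function(scene) {
  stopifnot(is(scene, "PhantomScene"))
  validObject(scene)
  nb <- length(scene@bandCwlNm)
  ne <- length(scene@exposureTimesMs)
  scales <- scene@exposureTimesMs / 100
  .withSeed(scene@seed, {
    framesList <- vector("list", nb * ne)
    wl <- numeric(nb * ne); ex <- numeric(nb * ne)
    i <- 0L
    for (b in seq_len(nb)) {
      radiance <- renderBand(scene, b)
      for (e in seq_len(ne)) {
        i <- i + 1L
        s <- radiance * scales[e]
        noise <- scene@noisePoissonScale * sqrt(pmax(s, 0)) *
          matrix(stats::rnorm(length(s)), nrow(s)) +
          scene@noiseGaussianSd * matrix(stats::rnorm(length(s)), nrow(s))
        framesList[[i]] <- .clip01(s + noise)
        wl[i] <- scene@bandCwlNm[b]
        ex[i] <- scene@exposureTimesMs[e]
      }
    }
    list(stack = imageStack(framesList, wl, ex,
                            metadata = list(scene = scene)),
         truth = sceneMask(scene))
  })
}

#' White-light proxy frame
#'
#' A stand-in for a conventional visible-light (RGB) photograph of the
#' scene, in which the buried disk is essentially invisible: visible
#' light barely penetrates the diffusive layer, so the proxy is rendered
#' with near-zero disk contrast (transmission 0.02) and very strong
#' scattering blur, under the same illumination field, exposed to
#' mid-gray, with the same noise model. Deterministic given the scene
#' (seeded from `scene@seed + 1`).
#'
#' @param scene a [PhantomScene-class].
#' @return numeric matrix in \eqn{[0,1]}.
#' @export
whiteLightProxy <- function(scene) {
  stopifnot(is(scene, "PhantomScene"))
  contrast <- scene@diskReflectance - scene@backgroundReflectance
  refl <- scene@backgroundReflectance + 0.02 * contrast * sceneMask(scene)
  refl <- .gaussBlur(refl, 3 * max(scene@scatterSigmaPx))
  s <- refl * illuminationField(scene)
  s <- s * (0.5 / mean(s))  # expose to mid-gray
  .withSeed(scene@seed + 1L, {
    noise <- scene@noisePoissonScale * sqrt(pmax(s, 0)) *
      matrix(stats::rnorm(length(s)), nrow(s)) +
      scene@noiseGaussianSd * matrix(stats::rnorm(length(s)), nrow(s))
    .clip01(s + noise)
  })
}
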