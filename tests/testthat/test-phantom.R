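# shared across the tests in this file
scDefault <- defaultScene(seed = 0)
phDefault <- generateStack(scDefault)

test_that("the default scene encodes the printed acquisition design", {
  expect_length(scDefault@bandCwlNm, 10)
  expect_equal(scDefault@bandCwlNm[1], 713)
  expect_equal(scDefault@bandCwlNm[10], 920)
  expect_equal(scDefault@diskDiameterPx, 125)
  expect_length(scDefault@exposureTimesMs, 10)
  expect_identical(sceneToList(defaultScene(0)), sceneToList(defaultScene(0)))
  # band brightness decreases with wavelength; scattering decreases;
  # disk-contrast transmission increases
  expect_true(all(diff(scDefault@bandRelativeIntensity) < 0))
  expect_true(all(diff(scDefault@scatterSigmaPx) < 0))
  expect_true(all(diff(scDefault@attenuation) > 0))
})

test_that("the generated stack is the full factorial acquisition with ground truth", {
  expect_equal(nFrames(phDefault$stack), 100)
  expect_true(isFactorial(phDefault$stack))
  expect_length(unique(wavelengths(phDefault$stack)), 10)
  expect_length(unique(exposures(phDefault$stack)), 10)
  expect_equal(measureDiskDiameter(phDefault$truth), 125)
})

test_that("a fixed seed reproduces the stack bit for bit; a new seed changes only the noise", {
  again <- generateStack(defaultScene(seed = 0))
  expect_identical(frames(again$stack), frames(phDefault$stack))
  other <- generateStack(defaultScene(seed = 99))
  expect_false(identical(frames(other$stack)[[1]], frames(phDefault$stack)[[1]]))
  expect_identical(other$truth, phDefault$truth)
})

test_that("frame brightness is monotone in exposure before saturation", {
  scales <- scDefault@exposureTimesMs / 100
  for (b in c(1, 5, 10)) {
    ideal <- renderBand(scDefault, b)
    preClipMeans <- mean(ideal) * scales
    expect_true(all(diff(preClipMeans) > 0))
  }
  # and on the noisy unsaturated frames of the dimmest band
  sel <- which(wavelengths(phDefault$stack) == 920)
  ms <- vapply(frames(phDefault$stack)[sel], mean, 0)
  expect_true(all(diff(ms[order(exposures(phDefault$stack)[sel])]) > 0))
})

test_that("the exposure ladder runs from underexposed to partially saturated", {
  wl <- wavelengths(phDefault$stack); ex <- exposures(phDefault$stack)
  for (b in unique(wl)) {
    lo <- frames(phDefault$stack)[[which(wl == b & ex == min(ex))]]
    expect_lt(mean(lo), 0.2)
  }
  satFrac <- vapply(frames(phDefault$stack), function(f) mean(f >= 1), 0)
  expect_gt(max(satFrac[ex == max(ex)]), 0.01)
  # no frame degenerates to a constant (its background keeps noise)
  expect_true(all(satFrac < 1))
})

test_that("the scattering blur conserves flux and degenerate optics are exact", {
  flat <- sceneFromList(list(illuminationFalloff = 0))
  sharp <- sceneFromList(list(illuminationFalloff = 0, scatterSigmaPx = rep(0, 10)))
  for (b in c(1, 10)) {
    a <- renderBand(flat, b); s <- renderBand(sharp, b)
    expect_lt(abs(sum(a) - sum(s)) / sum(s), 0.001)
  }
  # scatter 0, attenuation 1: the exact two-level disk image
  ideal <- sceneFromList(list(illuminationFalloff = 0,
                              scatterSigmaPx = rep(0, 10),
                              attenuation = rep(1, 10)))
  img <- renderBand(ideal, 1)
  mask <- sceneMask(ideal)
  expect_equal(unique(as.vector(img[mask])), 0.25)
  expect_equal(unique(as.vector(img[!mask])), 0.55)
  # attenuation 0: the disk is invisible
  opaque <- sceneFromList(list(illuminationFalloff = 0, attenuation = rep(0, 10)))
  img0 <- renderBand(opaque, 3)
  expect_equal(max(img0) - min(img0), 0)
  expect_equal(img0[1, 1], 0.55 * opaque@bandRelativeIntensity[3])
})

test_that("disk contrast falls with stronger scattering and weaker transmission", {
  mask <- sceneMask(scDefault)
  contrastOf <- function(img) abs(mean(img[mask]) - mean(img[!mask]))
  base <- list(illuminationFalloff = 0)
  sigmas <- c(2, 8, 16)
  cS <- vapply(sigmas, function(sg) {
    sc <- sceneFromList(c(base, list(scatterSigmaPx = rep(sg, 10))))
    contrastOf(renderBand(sc, 5))
  }, 0)
  expect_true(all(diff(cS) < 0))
  atts <- c(0.2, 0.5, 0.9)
  cA <- vapply(atts, function(a) {
    sc <- sceneFromList(c(base, list(attenuation = rep(a, 10))))
    contrastOf(renderBand(sc, 5))
  }, 0)
  expect_true(all(diff(cA) > 0))
})

test_that("the white-light proxy hides the disk under heavy scattering", {
  proxy <- whiteLightProxy(scDefault)
  expect_true(all(proxy >= 0 & proxy <= 1))
  expect_identical(proxy, whiteLightProxy(defaultScene(seed = 0)))
  # the disk is far less detectable than in the fused NIR result
  expect_lt(cnr(proxy, phDefault$truth), 3)
})

test_that("the gray-patch reference captures the illumination non-uniformity", {
  ref <- grayPatchReference(scDefault)
  L <- illuminationField(scDefault)
  expect_equal(ref, 0.5 * L)
  expect_equal(max(L), 1, tolerance = 1e-4)  # peak sits between pixel centers
  expect_equal(min(L), 1 - scDefault@illuminationFalloff, tolerance = 1e-2)
  # flat-fielding a rendered band removes the gradient in the background
  img <- renderBand(scDefault, 5)
  corrected <- applyFlatField(img, buildFlatField(ref))
  bg <- !phDefault$truth
  border <- bg & (row(img) < 40 | row(img) > 216)
  expect_lt(stats::sd(corrected[border]), stats::sd(img[border]) / 5)
})

test_that("invalid scenes are rejected at validation", {
  expect_error(sceneFromList(list(diskCenter = c(5, 5))), "inside the frame")
  expect_error(sceneFromList(list(attenuation = rep(0.5, 3))), "length")
  expect_error(sceneFromList(list(exposureTimesMs = c(-1, 10))), "> 0")
})
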