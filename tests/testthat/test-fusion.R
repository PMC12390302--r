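test_that("naive fusion is the per-pixel convex combination of the frames", {
  set.seed(91)
  img <- randomImage(8, 8)
  s <- constantStack(5, img)
  r <- fuseNaive(s, computeWeightStack(s))
  expect_equal(fusedImage(r), img)
  # frozen: weights (0.25, 0.75) over values (0, 1) gives 0.75
  s2 <- imageStack(list(matrix(0, 4, 4), matrix(1, 4, 4)),
                   c(713, 736), c(100, 100))
  ws2 <- manualWeights(list(matrix(1, 4, 4), matrix(3, 4, 4)))
  expect_equal(fusedImage(fuseNaive(s2, ws2)), matrix(0.75, 4, 4))
  # bounded by the per-pixel min/max over frames
  s3 <- randomStack(4, 16, 16)
  r3 <- fusedImage(fuseNaive(s3, computeWeightStack(s3)))
  lo <- Reduce(pmin, frames(s3)); hi <- Reduce(pmax, frames(s3))
  expect_true(all(r3 >= lo - 1e-12 & r3 <= hi + 1e-12))
  # externally supplied uniform weights reduce to the per-pixel mean
  ws3 <- manualWeights(replicate(4, matrix(1, 16, 16), simplify = FALSE))
  expect_equal(fusedImage(fuseNaive(s3, ws3)), Reduce(`+`, frames(s3)) / 4)
})

test_that("depth-1 pyramid fusion coincides with naive fusion", {
  set.seed(101)
  for (i in 1:3) {
    s <- randomStack(3, 12 + i, 15)
    ws <- computeWeightStack(s)
    d1 <- fusedImage(fusePyramid(s, ws, depth = 1))
    nv <- fusedImage(fuseNaive(s, ws))
    expect_lt(max(abs(d1 - nv)), 1e-9)
  }
})

test_that("both modes and strategies are idempotent on identical frames", {
  set.seed(111)
  img <- randomImage(16, 16)
  s <- imageStack(replicate(4, img, simplify = FALSE),
                  wavelengthNm = rep(c(713, 736), each = 2),
                  exposureMs = rep(c(50, 100), times = 2))
  for (mode in c("naive", "pyramid"))
    for (strategy in c("flat", "two_stage")) {
      r <- fuseStack(s, mode = mode, strategy = strategy, depth = 3)
      expect_lt(max(abs(fusedImage(r) - img)), 1e-9)
    }
})

test_that("fused output is invariant under frame reordering", {
  set.seed(121)
  fr <- replicate(4, randomImage(16, 16), simplify = FALSE)
  wl <- c(713, 713, 736, 736); ex <- c(50, 100, 50, 100)
  perm <- c(4, 2, 1, 3)
  s1 <- imageStack(fr, wl, ex)
  s2 <- imageStack(fr[perm], wl[perm], ex[perm])
  for (mode in c("naive", "pyramid")) {
    r1 <- fusedImage(fuseStack(s1, mode = mode, depth = 3))
    r2 <- fusedImage(fuseStack(s2, mode = mode, depth = 3))
    expect_lt(max(abs(r1 - r2)), 1e-10)
  }
})

test_that("pyramid blending removes the stitch line that naive fusion leaves", {
  fx <- seamFixture()
  naive <- fusedImage(fuseNaive(fx$stack, fx$weights))
  pyr <- fusedImage(fusePyramid(fx$stack, fx$weights, depth = 5))
  gNaive <- maxSeamGradient(naive)
  gPyr <- maxSeamGradient(pyr)
  expect_equal(gNaive, 0.4)  # hard 0.3 | 0.7 jump survives naive averaging
  expect_lt(gPyr, gNaive / 10)
})

test_that("two-stage fusion degenerates to flat on a single band", {
  set.seed(131)
  s <- imageStack(replicate(3, randomImage(16, 16), simplify = FALSE),
                  wavelengthNm = rep(713, 3), exposureMs = c(30, 100, 240))
  for (mode in c("naive", "pyramid")) {
    flat <- fusedImage(fuseStack(s, mode = mode, strategy = "flat", depth = 3))
    two <- fusedImage(fuseStack(s, mode = mode, strategy = "two_stage", depth = 3))
    expect_lt(max(abs(flat - two)), 1e-9)
  }
})

test_that("misaligned inputs and infeasible requests fail loudly", {
  set.seed(141)
  s <- randomStack(3, 8, 8)
  ws2 <- computeWeightStack(randomStack(2, 8, 8))
  expect_error(fuseNaive(s, ws2), "3 frames")
  wsBig <- computeWeightStack(randomStack(3, 9, 8))
  expect_error(fuseNaive(s, wsBig), "dimensions")
  expect_error(fusePyramid(s, computeWeightStack(s), depth = 10), "maximum depth")
  # non-factorial stack rejected by the two-stage strategy at validation
  nf <- imageStack(replicate(3, randomImage(8, 8), simplify = FALSE),
                   wavelengthNm = c(713, 713, 736), exposureMs = c(50, 100, 50))
  expect_error(fuseStack(nf, strategy = "two_stage", depth = 2), "factorial")
})

test_that("fusion results carry provenance and a valid pre-clip range", {
  set.seed(151)
  s <- randomStack(3, 16, 16)
  r <- fuseStack(s, sigma = 1.5, depth = 3, mode = "pyramid")
  expect_s4_class(r, "FusionResult")
  expect_identical(r@provenance$sigma, 1.5)
  expect_identical(r@depth, 3L)
  expect_identical(r@provenance$nFrames, 3L)
  expect_true(r@preClipRange[1] <= min(fusedImage(r)))
  expect_true(r@preClipRange[2] >= max(fusedImage(r)))
  expect_true(all(fusedImage(r) >= 0 & fusedImage(r) <= 1))
})
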