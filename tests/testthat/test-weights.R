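test_that("contrast weight is the absolute Laplacian response", {
  expect_equal(contrastWeight(matrix(0.5, 6, 6)), matrix(0, 6, 6))
  # frozen: unit impulse at the center of a 5x5 zero image, 4-neighbor stencil
  imp <- matrix(0, 5, 5); imp[3, 3] <- 1
  expected <- matrix(0, 5, 5)
  expected[3, 3] <- 4
  expected[2, 3] <- expected[4, 3] <- expected[3, 2] <- expected[3, 4] <- 1
  expect_equal(contrastWeight(imp), expected)
  # vertical step edge: response confined to the two columns at the edge
  step <- cbind(matrix(0, 6, 3), matrix(1, 6, 3))
  cw <- contrastWeight(step)
  expect_true(all(cw[, c(1, 2, 5, 6)] == 0))
  expect_true(all(cw[, 3:4] > 0))
  # random images against the dense convolution oracle, both stencils
  set.seed(61)
  x <- randomImage(11, 9)
  expect_equal(contrastWeight(x, 4L), abs(oracleConv2(x, lap4Kernel)),
               tolerance = 1e-12)
  expect_equal(contrastWeight(x, 8L), abs(oracleConv2(x, lap8Kernel)),
               tolerance = 1e-12)
})

test_that("exposedness weight is a Gaussian around mid-gray", {
  expect_equal(exposednessWeight(matrix(0.5, 3, 3)), matrix(1, 3, 3))
  # symmetry about 0.5 for any sigma
  for (s in c(0.2, 1, 2))
    expect_equal(exposednessWeight(matrix(0, 1, 1), s),
                 exposednessWeight(matrix(1, 1, 1), s))
  # evaluated independently: E(0) at sigma 2 is exp(-0.25 / 8)
  expect_equal(exposednessWeight(matrix(0, 1, 1), 2)[1, 1], exp(-0.03125))
  # strictly decreasing in |i - 0.5| along a gray ramp
  ramp <- matrix(seq(0.5, 1, length.out = 50), 1)
  e <- exposednessWeight(ramp, 2)
  expect_true(all(diff(as.vector(e)) < 0))
  expect_true(all(e > 0 & e <= 1))
  expect_error(exposednessWeight(matrix(0.5, 2, 2), 0), "positive")
  expect_error(exposednessWeight(matrix(0.5, 2, 2), -1), "positive")
})

test_that("weight combination is the element-wise product", {
  cw <- matrix(c(1, 3, 2, 4), 2, 2)
  expect_equal(combineWeights(cw, matrix(1, 2, 2)), cw)
  expect_equal(combineWeights(matrix(0, 2, 2), cw), matrix(0, 2, 2))
  expect_equal(combineWeights(matrix(c(1, 3, 2, 4), 2, 2),
                              matrix(c(0.5, 1, 0.5, 1), 2, 2)),
               matrix(c(0.5, 3, 1, 4), 2, 2))
  expect_error(combineWeights(matrix(1, 2, 2), matrix(1, 3, 2)), "dimensions")
})

test_that("normalization produces a per-pixel convex combination", {
  expect_equal(normalizeWeights(list(matrix(2.5, 3, 3))), list(matrix(1, 3, 3)))
  two <- normalizeWeights(list(matrix(4, 2, 2), matrix(4, 2, 2)))
  expect_equal(two[[1]], matrix(0.5, 2, 2))
  got <- normalizeWeights(list(matrix(1, 2, 2), matrix(3, 2, 2)))
  expect_equal(got[[1]], matrix(0.25, 2, 2))
  expect_equal(got[[2]], matrix(0.75, 2, 2))
  # all-zero pixel falls back to exactly uniform 1/N
  raw <- list(matrix(c(0, 1), 1, 2), matrix(c(0, 3), 1, 2),
              matrix(c(0, 4), 1, 2))
  nz <- normalizeWeights(raw)
  expect_equal(vapply(nz, function(g) g[1, 1], 0), rep(1 / 3, 3))
  expect_equal(vapply(nz, function(g) g[1, 2], 0), c(1, 3, 4) / 8)
  expect_error(normalizeWeights(list()), "nonempty")
  expect_error(normalizeWeights(list(matrix(-1, 2, 2))), "negative")
})

test_that("normalized weights sum to one at every pixel on random stacks", {
  set.seed(71)
  for (n in c(1, 2, 5)) {
    s <- randomStack(n, 13, 9)
    ws <- computeWeightStack(s)
    tot <- Reduce(`+`, normalizedWeights(ws))
    expect_lt(max(abs(tot - 1)), 1e-9)
    expect_true(all(vapply(rawWeights(ws), min, 0) >= 0))
    expect_true(all(vapply(normalizedWeights(ws), min, 0) >= 0))
  }
})

test_that("identical frames share the weight equally and texture wins over flatness", {
  s <- constantStack(4, matrix(0.5, 6, 6))
  ws <- computeWeightStack(s)
  for (g in normalizedWeights(ws)) expect_equal(g, matrix(0.25, 6, 6))
  # frame A flat at 0.5, frame B with an impulse: B takes all the weight
  # where its Laplacian response is nonzero, the uniform fallback elsewhere
  b <- matrix(0.5, 4, 4); b[2, 2] <- 0.9
  s2 <- imageStack(list(matrix(0.5, 4, 4), b), c(713, 736), c(100, 100))
  ws2 <- computeWeightStack(s2)
  cb <- contrastWeight(b)
  textured <- cb > 0
  expect_true(all(normalizedWeights(ws2)[[2]][textured] == 1))
  expect_true(all(normalizedWeights(ws2)[[1]][textured] == 0))
  expect_true(all(normalizedWeights(ws2)[[2]][!textured] == 0.5))
})

test_that("weight computation is equivariant under frame reordering", {
  set.seed(81)
  fr <- replicate(4, randomImage(8, 8), simplify = FALSE)
  wl <- c(713, 736, 759, 782); ex <- rep(100, 4)
  perm <- c(3, 1, 4, 2)
  s1 <- imageStack(fr, wl, ex)
  s2 <- imageStack(fr[perm], wl[perm], ex[perm])
  expect_equal(normalizedWeights(computeWeightStack(s1)),
               normalizedWeights(computeWeightStack(s2)))
})
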