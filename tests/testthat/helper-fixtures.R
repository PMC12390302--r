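# Independent brute-force oracles and small fixtures shared across tests.

# Dense O(n^2 k^2) 2-D convolution with mirror-reflected borders; the
# oracle deliberately avoids the package's separable shifted-sum path.
oracleConv2 <- function(x, K) {
  refl <- function(i, n) {
    if (n == 1L) return(1L)
    p <- (i - 1L) %% (2L * n - 2L)
    if (p >= n) p <- 2L * n - 2L - p
    p + 1L
  }
  kh <- (nrow(K) - 1L) %/% 2L
  kw <- (ncol(K) - 1L) %/% 2L
  out <- matrix(0, nrow(x), ncol(x))
  for (r in seq_len(nrow(x))) for (cc in seq_len(ncol(x))) {
    acc <- 0
    for (a in -kh:kh) for (b in -kw:kw)
      acc <- acc + K[a + kh + 1L, b + kw + 1L] *
        x[refl(r + a, nrow(x)), refl(cc + b, ncol(x))]
    out[r, cc] <- acc
  }
  out
}

oracleSmoothDownsample <- function(x) {
  k <- c(1, 4, 6, 4, 1) / 16
  s <- oracleConv2(x, outer(k, k))
  s[seq(1, nrow(s), 2), seq(1, ncol(s), 2), drop = FALSE]
}

lap4Kernel <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
lap8Kernel <- matrix(c(1, 1, 1, 1, -8, 1, 1, 1, 1), 3, 3)

randomImage <- function(h, w) matrix(runif(h * w), h, w)

randomStack <- function(n, h, w, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  imageStack(replicate(n, randomImage(h, w), simplify = FALSE),
             wavelengthNm = 700 + seq_len(n), exposureMs = rep(100, n))
}

# identical frames under distinct labels
constantStack <- function(n, img) {
  imageStack(replicate(n, img, simplify = FALSE),
             wavelengthNm = 700 + seq_len(n), exposureMs = rep(100, n))
}

# hand-built weight stack (bypasses the weight pipeline) for fusion tests
manualWeights <- function(grids, sigma = 2) {
  new("WeightStack", raw = grids, normalized = normalizeWeights(grids),
      sigma = sigma)
}

# scaled-down phantom for IO / pipeline tests where runtime matters
smallScene <- function(seed = 0L) {
  sceneFromList(list(imageH = 64L, imageW = 64L, diskCenter = c(32, 32),
                     diskDiameterPx = 31,
                     scatterSigmaPx = seq(4, 2, length.out = 10),
                     seed = as.integer(seed)))
}

# two constant frames with a hard left/right weight boundary: the
# stitch-line fixture
seamFixture <- function(h = 64, w = 64, lo = 0.3, hi = 0.7) {
  stack <- imageStack(list(matrix(lo, h, w), matrix(hi, h, w)),
                      wavelengthNm = c(713, 736), exposureMs = c(100, 100))
  w1 <- matrix(0, h, w); w1[, seq_len(w %/% 2)] <- 1
  list(stack = stack, weights = manualWeights(list(w1, 1 - w1)))
}

maxSeamGradient <- function(img) max(abs(img[, -1] - img[, -ncol(img)]))
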