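## Internal convolution primitives. All borders use whole-sample symmetric
## (mirror) reflection, which preserves constant images and avoids edge
## darkening; index folding has period 2n-2 so it degenerates gracefully at
## n = 1 and n = 2.

.reflectIdx <- function(i, n) {
  if (n == 1L) return(rep.int(1L, length(i)))
  p <- (i - 1L) %% (2L * n - 2L)
  ifelse(p >= n, 2L * n - 2L - p, p) + 1L
}

## 1-D convolution of each column (axis = 1) or row (axis = 2) with an
## odd-length kernel, mirror border. Implemented as a sum of shifted
## copies: vectorized, no loops over pixels.
.convAxis <- function(x, k, axis) {
  n <- dim(x)[axis]
  if (n == 1L) return(x * sum(k))
  half <- (length(k) - 1L) %/% 2L
  out <- array(0, dim(x))
  for (t in seq_along(k)) {
    idx <- .reflectIdx(seq_len(n) + (t - 1L - half), n)
    out <- out + k[t] * (if (axis == 1L) x[idx, , drop = FALSE]
                         else x[, idx, drop = FALSE])
  }
  out
}

.convSeparable <- function(x, k) .convAxis(.convAxis(x, k, 1L), k, 2L)

## Shift an image by (dr, dc) with mirror border; building block for the
## 3x3 Laplacian stencils.
.shiftReflect <- function(x, dr, dc) {
  ri <- .reflectIdx(seq_len(nrow(x)) + dr, nrow(x))
  ci <- .reflectIdx(seq_len(ncol(x)) + dc, ncol(x))
  x[ri, ci, drop = FALSE]
}

## Normalized 1-D Gaussian kernel truncated at 4 sigma (used by the
## phantom's scattering PSF).
.gaussKernel1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

.gaussBlur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  .convSeparable(x, .gaussKernel1d(sigma))
}

.clip01 <- function(x) pmin(pmax(x, 0), 1)

.asImage <- function(img, what = "image") {
  if (is.data.frame(img)) img <- as.matrix(img)
  if (is.vector(img) && is.numeric(img)) img <- matrix(img, nrow = 1L)
  msg <- .checkImage(img, what)
  if (!is.null(msg)) stop(msg, call. = FALSE)
  img
}
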