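#' Cross-section intensity traces through a point
#'
#' Extracts the full pixel row and the full pixel column through
#' `(row, col)`. Coordinates are 1-based; `row` indexes the vertical
#' axis (y) and `col` the horizontal axis (x), so `rowProfile` is the
#' horizontal trace (length = image width) and `colProfile` the vertical
#' trace (length = image height).
#'
#' @param img numeric matrix.
#' @param row,col 1-based cross-section location.
#' @return list with `rowProfile` and `colProfile` numeric vectors.
#' @export
crossSection <- function(img, row, col) {
  img <- .asImage(img)
  row <- as.integer(row); col <- as.integer(col)
  if (is.na(row) || row < 1L || row > nrow(img))
    stop(sprintf("row %d out of bounds 1..%d", row, nrow(img)), call. = FALSE)
  if (is.na(col) || col < 1L || col > ncol(img))
    stop(sprintf("col %d out of bounds 1..%d", col, ncol(img)), call. = FALSE)
  list(rowProfile = as.numeric(img[row, ]), colProfile = as.numeric(img[, col]))
}

#' Contrast-to-noise ratio of a masked region against the background
#'
#' `|mean(img[mask]) - mean(img[!mask])| / sd(img[!mask])`: how many
#' background noise standard deviations separate the target region from
#' the background. Invariant under affine intensity transforms with
#' positive scale; always non-negative. A constant background (zero sd)
#' makes the ratio undefined and is an error.
#'
#' @param img numeric matrix.
#' @param mask logical matrix of the same dimensions, `TRUE` on the
#'   target region; both classes must be nonempty.
#' @return non-negative numeric scalar.
#' @export
cnr <- function(img, mask) {
  img <- .asImage(img)
  if (!is.logical(mask)) mask <- mask > 0
  if (!identical(dim(mask), dim(img)))
    stop("mask dimensions must match the image", call. = FALSE)
  if (!any(mask) || all(mask))
    stop("both the mask and the background must be nonempty", call. = FALSE)
  bg <- img[!mask]
  s <- stats::sd(bg)
  if (s == 0)
    stop("background is constant: CNR undefined (zero sd)", call. = FALSE)
  abs(mean(img[mask]) - mean(bg)) / s
}

#' Extract a rectangular region of interest
#'
#' 1-based inclusive bounds `c(row0, row1, col0, col1)`; the returned
#' sub-image carries its origin in attributes `roi` for index
#' bookkeeping (a cross-section of the zoomed image matches the
#' corresponding slice of the full-frame cross-section).
#'
#' @param img numeric matrix.
#' @param roi integer vector `c(row0, row1, col0, col1)`, inclusive.
#' @return numeric matrix with attribute `roi`.
#' @export
zoomRoi <- function(img, roi) {
  img <- .asImage(img)
  roi <- as.integer(roi)
  if (length(roi) != 4L || anyNA(roi))
    stop("roi must be c(row0, row1, col0, col1)", call. = FALSE)
  if (roi[1L] < 1L || roi[2L] > nrow(img) || roi[3L] < 1L || roi[4L] > ncol(img) ||
      roi[1L] > roi[2L] || roi[3L] > roi[4L])
    stop(sprintf("roi [%d..%d] x [%d..%d] invalid for a %dx%d image",
                 roi[1L], roi[2L], roi[3L], roi[4L], nrow(img), ncol(img)),
         call. = FALSE)
  out <- img[roi[1L]:roi[2L], roi[3L]:roi[4L], drop = FALSE]
  attr(out, "roi") <- roi
  out
}

#' Full profile report at a point
#'
#' Bundles [crossSection()] traces, their min/max/mean, and (when a
#' ground-truth or user mask is supplied) the [cnr()] detectability
#' metric into a [ProfileReport-class].
#'
#' @inheritParams crossSection
#' @param mask optional logical matrix for the CNR metric.
#' @return A [ProfileReport-class].
#' @export
profileReport <- function(img, row, col, mask = NULL) {
  cs <- crossSection(img, row, col)
  statsOf <- function(v) list(min = min(v), max = max(v), mean = mean(v))
  new("ProfileReport",
      rowProfile = cs$rowProfile, colProfile = cs$colProfile,
      row = as.integer(row), col = as.integer(col),
      cnr = if (is.null(mask)) NA_real_ else cnr(img, mask),
      stats = list(row = statsOf(cs$rowProfile), col = statsOf(cs$colProfile)))
}
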