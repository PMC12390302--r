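.frameFileRe <- "^band([0-9]+\\.?[0-9]*)nm_exp([0-9]+\\.?[0-9]*)ms\\.(tiff?|png)$"

#' Read a single-channel image file
#'
#' TIFF or PNG. Integer data are normalized to \eqn{[0,1]} by the dtype
#' maximum (the readers do this natively for 8/16-bit data); float data
#' pass through unchanged, so exposure relationships across frames are
#' preserved. Multi-channel data are reduced to Rec. 601 luminance.
#'
#' @param path image file path.
#' @return numeric matrix in \eqn{[0,1]}.
#' @export
readImage <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  x <- if (grepl("\\.png$", path, ignore.case = TRUE)) png::readPNG(path)
       else tiff::readTIFF(path)
  if (is.array(x) && length(dim(x)) == 3L)
    x <- if (dim(x)[3L] >= 3L) toLuminance(x) else x[, , 1L]
  .clip01(.asImage(x, path))
}

.parseFrameName <- function(fname) {
  m <- regmatches(fname, regexec(.frameFileRe, fname))[[1L]]
  if (length(m) == 0L) return(NULL)
  c(wavelengthNm = as.numeric(m[2L]), exposureMs = as.numeric(m[3L]))
}

#' Read an image stack
#'
#' Three sources are supported. A **directory** is scanned for frames
#' following the naming convention `band{cwl}nm_exp{ms}ms.tiff` (or
#' `.png`), e.g. `band713nm_exp100ms.tiff` for the 713 nm band at
#' 100 ms; files not matching the convention are an error (name them or
#' supply a manifest). A **manifest CSV** with columns `path`,
#' `wavelength_nm`, `exposure_ms` (paths relative to the manifest)
#' overrides the convention for foreign data. A **multi-page TIFF** is
#' accepted when `wavelengthNm` and `exposureMs` vectors label its pages
#' in order. Frames are sorted by (wavelength, exposure); mixed
#' dimensions or an empty stack are errors.
#'
#' @param path directory, manifest CSV, or multi-page TIFF.
#' @param wavelengthNm,exposureMs per-page labels, only for multi-page
#'   TIFF input.
#' @return An [ImageStack-class].
#' @export
readStack <- function(path, wavelengthNm = NULL, exposureMs = NULL) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(tiff?|png)$", ignore.case = TRUE)
    files <- files[!grepl("^(truth_mask|preview|flat_reference)", files)]
    if (length(files) == 0L)
      stop(sprintf("no frames found in %s", path), call. = FALSE)
    labels <- lapply(files, .parseFrameName)
    bad <- files[vapply(labels, is.null, TRUE)]
    if (length(bad))
      stop(sprintf("cannot parse band/exposure from filename(s): %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    lab <- do.call(rbind, labels)
    return(imageStack(lapply(file.path(path, files), readImage),
                      lab[, "wavelengthNm"], lab[, "exposureMs"],
                      metadata = list(source = path)))
  }
  if (!file.exists(path)) stop(sprintf("no such path: %s", path), call. = FALSE)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    man <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("path", "wavelength_nm", "exposure_ms")
    if (!all(need %in% names(man)))
      stop("manifest must have columns path, wavelength_nm, exposure_ms",
           call. = FALSE)
    paths <- ifelse(grepl("^/", man$path), man$path,
                    file.path(dirname(path), man$path))
    return(imageStack(lapply(paths, readImage),
                      man$wavelength_nm, man$exposure_ms,
                      metadata = list(source = path)))
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.null(wavelengthNm) || is.null(exposureMs))
    stop("multi-page TIFF input needs wavelengthNm and exposureMs labels",
         call. = FALSE)
  imageStack(lapply(pages, function(p) .clip01(.asImage(p, path))),
             wavelengthNm, exposureMs, metadata = list(source = path))
}

#' Write an image stack as a directory of float TIFF frames
#'
#' Frames are written as 32-bit float TIFFs named by the
#' `band{cwl}nm_exp{ms}ms.tiff` convention that [readStack()] reads
#' back.
#'
#' @param stack an [ImageStack-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeStack <- function(stack, dir) {
  stopifnot(is(stack, "ImageStack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nFrames(stack))) {
    fn <- sprintf("band%gnm_exp%gms.tiff", wavelengths(stack)[i],
                  exposures(stack)[i])
    tiff::writeTIFF(frames(stack)[[i]], file.path(dir, fn),
                    bits.per.sample = 32L)
  }
  invisible(dir)
}

#' Write a fusion result with preview and sidecar
#'
#' Writes the fused image as a 32-bit float TIFF, an 8-bit PNG preview
#' (min/max stretched to 0..255), and a JSON sidecar echoing the fusion
#' parameters, input labels, pre-clip range and package version.
#'
#' @param result a [FusionResult-class].
#' @param path output TIFF path; the preview and sidecar take the same
#'   stem with `.png` / `.json` extensions.
#' @return named character vector of the three paths, invisibly.
#' @export
writeResult <- function(result, path) {
  stopifnot(is(result, "FusionResult"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tiff::writeTIFF(result@fused, path, bits.per.sample = 32L)
  stem <- sub("\\.tiff?$", "", path, ignore.case = TRUE)
  rng <- range(result@fused)
  prev <- if (diff(rng) > 0) (result@fused - rng[1L]) / diff(rng)
          else result@fused * 0
  png::writePNG(prev, paste0(stem, ".png"))
  sidecar <- c(result@provenance,
               list(version = as.character(utils::packageVersion("NIRfuse"))))
  jsonlite::write_json(sidecar, paste0(stem, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(tiff = path, png = paste0(stem, ".png"),
              json = paste0(stem, ".json")))
}

#' Write a phantom acquisition to disk
#'
#' Emits the exact directory layout [readStack()] and [runPipeline()]
#' consume: per-frame float TIFFs, the ground-truth mask as
#' `truth_mask.png`, the gray-patch calibration capture as
#' `flat_reference.tiff`, the white-light proxy as
#' `preview_white_light.png`, and a YAML echo of the scene parameters.
#'
#' @param scene a [PhantomScene-class].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
writePhantom <- function(scene, dir) {
  stopifnot(is(scene, "PhantomScene"))
  ph <- generateStack(scene)
  writeStack(ph$stack, dir)
  png::writePNG(ph$truth * 1, file.path(dir, "truth_mask.png"))
  tiff::writeTIFF(grayPatchReference(scene), file.path(dir, "flat_reference.tiff"),
                  bits.per.sample = 32L)
  png::writePNG(whiteLightProxy(scene), file.path(dir, "preview_white_light.png"))
  yaml::write_yaml(sceneToList(scene), file.path(dir, "scene.yaml"))
  invisible(dir)
}

#' Convert a scene to / from a plain list (YAML-friendly)
#'
#' @param scene a [PhantomScene-class].
#' @return `sceneToList`: a named list of scene parameters.
#' @export
sceneToList <- function(scene) {
  stopifnot(is(scene, "PhantomScene"))
  nm <- slotNames("PhantomScene")
  stats::setNames(lapply(nm, function(s) slot(scene, s)), nm)
}

#' @rdname sceneToList
#' @param x named list as produced by `sceneToList` (or a `scene.yaml`);
#'   missing entries fall back to [defaultScene()] values.
#' @return `sceneFromList`: a [PhantomScene-class].
#' @export
sceneFromList <- function(x) {
  base <- sceneToList(defaultScene())
  base[names(x)] <- x
  ints <- c("imageH", "imageW", "seed")
  for (s in ints) base[[s]] <- as.integer(base[[s]])
  do.call(new, c(list("PhantomScene"), base))
}
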