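# Raster and manifest I/O. Images live on disk as 8-bit PNG (JPEG accepted
# read-only), masks as 8-bit {0,255} single-channel PNG, probability maps as
# 32-bit float TIFF, manifests as JSON.

#' Read an RGB raster file
#'
#' 8-bit channels are rescaled to `[0,1]`. Grayscale images are replicated
#' to three channels; an alpha channel is dropped.
#'
#' @param path Path to a PNG or JPEG file.
#' @return An H x W x 3 array in `[0,1]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  raw <- tryCatch(
    switch(ext,
           png = png::readPNG(path),
           jpg = , jpeg = jpeg::readJPEG(path),
           stopf("unsupported raster format '%s' (expected png/jpeg)", ext)),
    error = function(e) stopf("cannot decode '%s' as %s: %s", path, ext,
                              conditionMessage(e)))
  if (is.matrix(raw)) raw <- array(raw, dim = c(dim(raw), 1L))
  if (dim(raw)[3] == 1L) raw <- array(raw[, , 1], dim = c(dim(raw)[1:2], 3L))
  if (dim(raw)[3] >= 4L) raw <- raw[, , 1:3, drop = FALSE]
  assert_image(raw)
  raw
}

#' Write an RGB image as 8-bit PNG
#'
#' @param img H x W x 3 array in `[0,1]`.
#' @param path Output path.
#' @export
write_image <- function(img, path) {
  assert_image(img)
  png::writePNG(img, path)
  invisible(path)
}

#' Write / read a binary mask as single-channel {0,255} PNG
#'
#' `read_mask()` maps stored values > 127 to 1. Reading a multi-channel file
#' is a format error: masks are single-channel by contract.
#'
#' @param mask H x W binary matrix.
#' @param path File path.
#' @return `read_mask()` returns an H x W matrix over `{0,1}`.
#' @export
write_mask <- function(mask, path) {
  assert_mask(mask)
  png::writePNG(mask, path)  # {0,1} floats encode to {0,255} bytes
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- tryCatch(png::readPNG(path),
                  error = function(e) stopf("cannot decode mask '%s': %s",
                                            path, conditionMessage(e)))
  if (!is.matrix(raw))
    stopf("mask file '%s' has %d channels; expected single-channel", path,
          dim(raw)[3])
  out <- (raw > 127 / 255) * 1
  assert_mask(out)
  out
}

#' Write / read a probability map as 32-bit float TIFF
#'
#' @param prob H x W matrix in `[0,1]`.
#' @param path File path.
#' @return `read_probmap()` returns an H x W matrix in `[0,1]`.
#' @export
write_probmap <- function(prob, path) {
  assert_probmap(prob)
  tiff::writeTIFF(prob, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' @rdname write_probmap
#' @export
read_probmap <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- tryCatch(tiff::readTIFF(path),
                  error = function(e) stopf("cannot decode TIFF '%s': %s",
                                            path, conditionMessage(e)))
  if (!is.matrix(raw)) raw <- raw[, , 1]
  assert_probmap(clip01(raw))
  clip01(raw)
}

#' Dataset manifest: sources and per-sample provenance
#'
#' Records the foreground/background source ids and, for every composite,
#' which pair produced it, under which blend mode or lambda vector, and the
#' seed: enough to regenerate the sample.
#'
#' @param fg_ids,bg_ids Character vectors of source ids (nonempty).
#' @param records List of per-sample entries; each a named list with at
#'   least `id`, `fg_id`, `bg_id` and either `mode` or `lambda`, plus `seed`.
#' @param format_version Manifest schema version string.
#' @return An object of class `"dataset_manifest"`.
#' @export
dataset_manifest <- function(fg_ids, bg_ids, records = list(),
                             format_version = "1.0") {
  fg_ids <- as.character(fg_ids)
  bg_ids <- as.character(bg_ids)
  if (length(fg_ids) < 1 || length(bg_ids) < 1)
    stopf("manifest needs at least one foreground and one background id")
  ids <- vapply(records, function(r) as.character(r$id), character(1))
  if (anyDuplicated(ids)) stopf("manifest record id collision: %s",
                                ids[duplicated(ids)][1])
  for (r in records) {
    if (!r$fg_id %in% fg_ids)
      stopf("record '%s' references unknown foreground id '%s'", r$id, r$fg_id)
    if (!r$bg_id %in% bg_ids)
      stopf("record '%s' references unknown background id '%s'", r$id, r$bg_id)
  }
  structure(list(
    format_version = format_version,
    n_foregrounds = length(fg_ids), n_backgrounds = length(bg_ids),
    fg_ids = fg_ids, bg_ids = bg_ids, records = records
  ), class = "dataset_manifest")
}

#' Write / read a dataset manifest as JSON
#'
#' Round trip is exact; lambda vectors are serialized at full precision.
#'
#' @param manifest A [dataset_manifest()].
#' @param path File path.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "dataset_manifest"))
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  records <- lapply(x$records, function(r) {
    if (!is.null(r$lambda)) r$lambda <- as.numeric(unlist(r$lambda))
    if (!is.null(r$modes)) r$modes <- as.character(unlist(r$modes))
    r
  })
  dataset_manifest(
    fg_ids = as.character(unlist(x$fg_ids)),
    bg_ids = as.character(unlist(x$bg_ids)),
    records = records,
    format_version = x$format_version
  )
}

#' @export
print.dataset_manifest <- function(x, ...) {
  cat(sprintf("<dataset_manifest v%s> %d foregrounds, %d backgrounds, %d records\n",
              x$format_version, x$n_foregrounds, x$n_backgrounds,
              length(x$records)))
  invisible(x)
}
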