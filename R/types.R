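# Core data types. Images are plain H x W x 3 arrays of reals in [0,1]
# (row-major, origin top-left); masks are H x W matrices over {0,1};
# probability maps are H x W matrices in [0,1]. Conversion to/from 8-bit
# happens only at file boundaries. Samples are light S3 lists.

#' Validate an RGB working image
#'
#' @param img H x W x 3 numeric array with values in `[0,1]`, `H, W >= 8`.
#' @return `img`, invisibly, after validation.
#' @export
assert_image <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3 || dim(img)[3] != 3)
    stopf("image must be an H x W x 3 array")
  d <- dim(img)
  if (d[1] < 8 || d[2] < 8) stopf("image must be at least 8 x 8, got %d x %d", d[1], d[2])
  if (anyNA(img) || min(img) < 0 || max(img) > 1)
    stopf("image values must lie in [0,1]")
  invisible(img)
}

#' Validate a binary mask
#'
#' @param mask H x W matrix over `{0,1}` (1 = tool/foreground).
#' @param image Optional paired image; dimensions must agree.
#' @return `mask`, invisibly.
#' @export
assert_mask <- function(mask, image = NULL) {
  if (!is.matrix(mask)) stopf("mask must be an H x W matrix")
  if (anyNA(mask) || !all(mask %in% c(0, 1)))
    stopf("mask values must be 0 or 1")
  if (!is.null(image) && !identical(dim(mask), dim(image)[1:2]))
    stopf("mask (%d x %d) and image (%d x %d) dimensions differ",
          nrow(mask), ncol(mask), dim(image)[1], dim(image)[2])
  invisible(mask)
}

#' Validate a probability map
#'
#' @param prob H x W matrix of reals in `[0,1]` (per-pixel foreground
#'   probability).
#' @return `prob`, invisibly.
#' @export
assert_probmap <- function(prob) {
  if (!is.matrix(prob)) stopf("probability map must be an H x W matrix")
  if (anyNA(prob) || min(prob) < 0 || max(prob) > 1)
    stopf("probability values must lie in [0,1]")
  invisible(prob)
}

#' Foreground sample: an instrument image with its binary tool mask
#'
#' The pair `(x_f, y_f)` produced by chroma-key extraction (or a fixture).
#' Invariants: the mask is nonempty and every connected tool component
#' touches at least one image border (instruments enter the frame from
#' outside).
#'
#' @param image H x W x 3 array in `[0,1]`.
#' @param mask Paired H x W binary mask.
#' @param id Opaque identifier string.
#' @param check Validate invariants (default `TRUE`).
#' @return An object of class `"foreground_sample"`.
#' @export
foreground_sample <- function(image, mask, id = "fg", check = TRUE) {
  if (check) {
    assert_image(image)
    assert_mask(mask, image)
    if (sum(mask) == 0) stopf("foreground mask is empty")
    if (!all_components_touch_border(mask))
      stopf("every foreground component must touch an image border")
  }
  structure(list(image = image, mask = mask, id = as.character(id)),
            class = "foreground_sample")
}

#' Background sample: a tissue image with implicit all-background label
#'
#' @param image H x W x 3 array in `[0,1]`.
#' @param id Opaque identifier string.
#' @return An object of class `"background_sample"`.
#' @export
background_sample <- function(image, id = "bg") {
  assert_image(image)
  structure(list(image = image, id = as.character(id)),
            class = "background_sample")
}

#' Composite sample: a blended image, its propagated label, and provenance
#'
#' The label of a composite is always the foreground mask, irrespective of
#' the blending function used.
#'
#' @param image Blended H x W x 3 array in `[0,1]`.
#' @param label H x W binary mask (the foreground label).
#' @param provenance Named list: foreground id, background id, blend mode or
#'   lambda vector, draw index, seed.
#' @return An object of class `"composite_sample"`.
#' @export
composite_sample <- function(image, label, provenance = list()) {
  assert_image(image)
  assert_mask(label, image)
  structure(list(image = image, label = label, provenance = provenance),
            class = "composite_sample")
}

#' @export
print.foreground_sample <- function(x, ...) {
  cat(sprintf("<foreground_sample '%s'> %d x %d, %d tool px (%.1f%%)\n",
              x$id, nrow(x$mask), ncol(x$mask), sum(x$mask),
              100 * mean(x$mask)))
  invisible(x)
}

#' @export
print.background_sample <- function(x, ...) {
  cat(sprintf("<background_sample '%s'> %d x %d\n", x$id,
              dim(x$image)[1], dim(x$image)[2]))
  invisible(x)
}

#' @export
print.composite_sample <- function(x, ...) {
  p <- x$provenance
  cat(sprintf("<composite_sample> %d x %d, fg=%s bg=%s %s\n",
              dim(x$image)[1], dim(x$image)[2],
              if (is.null(p$fg_id)) "?" else p$fg_id,
              if (is.null(p$bg_id)) "?" else p$bg_id,
              if (!is.null(p$lambda)) paste0("lambda=(",
                paste(sprintf("%.3f", p$lambda), collapse = ", "), ")")
              else if (!is.null(p$mode)) paste0("mode=", p$mode) else ""))
  invisible(x)
}

# TRUE iff mask is nonempty and each 8-connected component touches a border.
all_components_touch_border <- function(mask) {
  if (sum(mask) == 0) return(FALSE)
  lab <- label_components(mask)
  n <- max(lab)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  all(seq_len(n) %in% border)
}
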