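#' Certainty bands for probability-map refinement
#'
#' Network probabilities below `low` are treated as sure background and
#' probabilities at or above `high` as sure foreground (strictly-less /
#' greater-or-equal semantics). GrabCut never modifies these certain
#' pixels; it only decides the uncertain band in between, expanding the
#' certainty zones according to colour contrast in the specific image.
#'
#' @param low,high Reals with `0 <= low < high <= 1` (defaults 0.2, 0.8).
#' @return List of class `"certainty_bands"`.
#' @export
certainty_bands <- function(low = 0.2, high = 0.8) {
  if (!(low >= 0 && low < high && high <= 1))
    stopf("certainty bands must satisfy 0 <= low < high <= 1")
  structure(list(low = low, high = high), class = "certainty_bands")
}

#' GrabCut post-processing of a network probability map
#'
#' Replaces GrabCut's usual manual scribbles with the network's certainty
#' zones: `prob < low` seeds sure background, `prob >= high` sure
#' foreground, and pixels in the open uncertain band are probable
#' (initialized foreground when `prob >= 0.5`). This bridges minor domain
#' gaps between the training data and the target images without manual
#' interaction.
#'
#' @param image H x W x 3 array in `[0,1]` (the image being segmented).
#' @param prob H x W probability map in `[0,1]` (foreground probability).
#' @param bands A [certainty_bands()].
#' @param iterations GrabCut rounds (default 5).
#' @param rng A [make_rng()] handle.
#' @return H x W binary mask. Every certain-seeded pixel retains its seeded
#'   class. If no pixel reaches the sure-foreground band the map is
#'   returned binarized at 0.5 unchanged, with a warning (no foreground
#'   colour model can be fit).
#' @export
grabcut_postprocess <- function(image, prob, bands = certainty_bands(),
                                iterations = 5L,
                                rng = make_rng(0, "refine")) {
  assert_image(image)
  assert_probmap(prob)
  if (!identical(dim(prob), dim(image)[1:2]))
    stopf("probability map and image dimensions differ")
  sure_fg <- prob >= bands$high
  sure_bg <- prob < bands$low
  if (!any(sure_fg) || !any(sure_bg)) {
    warnf("no sure-%s pixels: returning the 0.5-binarized map unchanged",
          if (!any(sure_fg)) "foreground" else "background")
    return(binarize(prob, 0.5))
  }
  trimap <- matrix(GC_PR_BGD, nrow(prob), ncol(prob))
  trimap[prob >= 0.5] <- GC_PR_FGD
  trimap[sure_bg] <- GC_BGD
  trimap[sure_fg] <- GC_FGD
  out <- grabcut(image, trimap, iterations = iterations, rng = rng)
  out[sure_fg] <- 1
  out[sure_bg] <- 0
  out
}
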