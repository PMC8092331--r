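#' Chroma-key foreground extraction
#'
#' Instruments are recorded over a green chroma key; the tool mask is the
#' complement of the green pixel set. The stages are: HSV thresholding,
#' keeping the largest `n_instruments` connected components (noise
#' reduction), then GrabCut refinement seeded from the threshold mask.
#'
#' @param hue_low,hue_high Green hue band in degrees on the 0-360 wheel.
#' @param min_saturation,min_value Minimum S and V for a pixel to count as
#'   chroma green (dark or washed-out pixels fail the test).
#' @param n_instruments Number of instruments in frame (largest-N component
#'   filter).
#' @param grabcut_iterations GrabCut rounds for refinement.
#' @param sure_fg_erosion Disc radius (px) eroding the candidate mask into
#'   the sure-foreground seed.
#' @return A validated list of class `"chroma_config"`.
#' @export
chroma_config <- function(hue_low = 80, hue_high = 160, min_saturation = 0.25,
                          min_value = 0.15, n_instruments = 1L,
                          grabcut_iterations = 5L, sure_fg_erosion = 5L) {
  cfg <- list(hue_low = hue_low, hue_high = hue_high,
              min_saturation = min_saturation, min_value = min_value,
              n_instruments = as.integer(n_instruments),
              grabcut_iterations = as.integer(grabcut_iterations),
              sure_fg_erosion = as.integer(sure_fg_erosion))
  if (!(hue_low >= 0 && hue_low < hue_high && hue_high <= 360))
    stopf("chroma hue band must satisfy 0 <= low < high <= 360")
  if (cfg$n_instruments < 1) stopf("n_instruments must be >= 1")
  structure(cfg, class = "chroma_config")
}

# The green pixel set: hue inside the band AND sufficiently saturated AND
# sufficiently bright.
green_set <- function(image, cfg) {
  hsv <- rgb_to_hsv_arr(image)
  (hsv$h >= cfg$hue_low & hsv$h <= cfg$hue_high &
     hsv$s >= cfg$min_saturation & hsv$v >= cfg$min_value) * 1
}

#' HSV threshold: candidate tool mask from a chroma-key image
#'
#' Converts to HSV and returns the complement of the green set as the tool
#' candidate (1 = tool).
#'
#' @param image H x W x 3 array in `[0,1]`.
#' @param cfg A [chroma_config()].
#' @return H x W binary candidate mask.
#' @export
hsv_threshold <- function(image, cfg = chroma_config()) {
  assert_image(image)
  1 - green_set(image, cfg)
}

#' Keep only the n largest 8-connected components
#'
#' Noise reduction for HSV-thresholded chroma masks: only pixels inside the
#' `n` largest components are retained. Equal-area ties break toward the
#' smaller label of the deterministic raster-scan labelling. If the mask has
#' `<= n` components it is returned unchanged.
#'
#' @param mask H x W binary matrix.
#' @param n Number of components to keep (the instrument count).
#' @return Filtered binary mask.
#' @export
keep_largest_components <- function(mask, n) {
  assert_mask(mask)
  if (n < 1) stopf("n must be >= 1")
  lab <- label_components(mask)
  ncomp <- max(lab)
  if (ncomp <= n) return(mask)
  areas <- tabulate(lab[lab > 0], nbins = ncomp)
  keep <- order(-areas, seq_len(ncomp))[seq_len(n)]
  (matrix(lab %in% keep, nrow(mask), ncol(mask))) * 1
}

#' GrabCut refinement of a chroma candidate mask
#'
#' Seeds GrabCut from the chroma evidence: green-thresholded pixels are sure
#' background, the candidate eroded by `sure_fg_erosion` is sure foreground
#' (erosion guards against halo pixels poisoning the foreground colour
#' model), everything else is probable (initialized from the candidate).
#'
#' @param image H x W x 3 chroma-key image.
#' @param candidate Binary candidate mask (from [hsv_threshold()] +
#'   [keep_largest_components()]).
#' @param cfg A [chroma_config()].
#' @param rng A [make_rng()] handle.
#' @return Refined binary tool mask. An empty candidate returns an empty
#'   mask with a warning (no foreground colour model can be fit).
#' @export
grabcut_refine_chroma <- function(image, candidate, cfg = chroma_config(),
                                  rng = make_rng(0, "chroma-grabcut")) {
  assert_image(image)
  assert_mask(candidate, image)
  if (sum(candidate) == 0) {
    warnf("empty candidate mask: no foreground model can be fit")
    return(candidate)
  }
  sure_fg <- if (cfg$sure_fg_erosion > 0)
    erode_mask(candidate, disc_brush(cfg$sure_fg_erosion)) else candidate
  if (sum(sure_fg) == 0) sure_fg <- candidate  # thin tool: trust the candidate
  green <- green_set(image, cfg)
  green[sure_fg == 1] <- 0  # sure-fg wins where the seeds would overlap
  trimap <- matrix(GC_PR_BGD, nrow(candidate), ncol(candidate))
  trimap[candidate == 1] <- GC_PR_FGD
  trimap[green == 1] <- GC_BGD
  trimap[sure_fg == 1] <- GC_FGD
  out <- grabcut(image, trimap, iterations = cfg$grabcut_iterations, rng = rng)
  out[green == 1] <- 0
  out[sure_fg == 1] <- 1
  out
}

#' Automated quality heuristics for an extracted mask
#'
#' Surrogate for manual visual inspection. Flags raised: (a) component count
#' differs from the configured instrument count, (b) foreground fraction
#' outside `[0.005, 0.8]`, (c) no component touches an image border. The
#' score is `1 - flags/3`. Failing masks are flagged, never dropped;
#' exclusion is the caller's decision.
#'
#' @param mask H x W binary matrix.
#' @param cfg A [chroma_config()] (supplies `n_instruments`).
#' @return List with `flags` (named logical), `score` in `[0,1]`,
#'   `component_count` and `foreground_fraction`.
#' @export
qc_score <- function(mask, cfg = chroma_config()) {
  assert_mask(mask)
  lab <- label_components(mask)
  ncomp <- max(lab)
  frac <- mean(mask)
  border_ok <- sum(mask) > 0 && all_components_touch_border(mask)
  flags <- c(component_count = ncomp != cfg$n_instruments,
             foreground_fraction = frac < 0.005 || frac > 0.8,
             border_connectivity = !border_ok)
  list(flags = flags, score = 1 - sum(flags) / 3,
       component_count = ncomp, foreground_fraction = frac)
}

#' Full chroma extraction pipeline
#'
#' threshold -> largest-N component filter -> GrabCut refinement, plus the
#' automated quality report.
#'
#' @inheritParams grabcut_refine_chroma
#' @return List with `mask` (refined binary mask) and `qc` (the
#'   [qc_score()] report).
#' @export
extract_foreground <- function(image, cfg = chroma_config(),
                               rng = make_rng(0, "chroma-grabcut")) {
  cand <- hsv_threshold(image, cfg)
  cand <- keep_largest_components(cand, cfg$n_instruments)
  mask <- if (sum(cand) == 0) {
    warnf("HSV threshold found no tool pixels")
    cand
  } else grabcut_refine_chroma(image, cand, cfg, rng)
  list(mask = mask, qc = qc_score(mask, cfg))
}
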