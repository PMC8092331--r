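# Evaluation primitives: binarization, epsilon-stabilized IoU (Jaccard),
# per-sequence means, and pixel-wise cross-entropy.

#' Binarize a probability map
#'
#' Pixels with probability at or above the threshold become foreground
#' (ties go to foreground).
#'
#' @param prob H x W probability map in `[0,1]`.
#' @param threshold Real in `[0,1]` (default 0.5).
#' @return H x W binary mask.
#' @export
binarize <- function(prob, threshold = 0.5) {
  assert_probmap(prob)
  if (threshold < 0 || threshold > 1) stopf("threshold must lie in [0,1]")
  (prob >= threshold) * 1
}

#' Intersection over union (Jaccard index) of two binary masks
#'
#' `J = (|A intersect B| + eps) / (|A union B| + eps)` with `eps` the
#' machine epsilon, so two empty masks score 1 and `J` is bounded to
#' `[0,1]`. The `denominator = "sum"` switch replaces the union by the
#' plain sum of areas (no intersection subtraction) for comparison with
#' formulations that state it that way; it is not a Jaccard index (two
#' identical nonempty masks then score 0.5).
#'
#' @param pred,truth H x W binary masks of equal size.
#' @param frame_id Optional opaque frame identifier carried in the record.
#' @param denominator `"union"` (Jaccard, default) or `"sum"`.
#' @return A `score_record` list: `J`, `frame_id`, `n_pixels`, `epsilon`.
#' @export
iou <- function(pred, truth, frame_id = NA_character_,
                denominator = c("union", "sum")) {
  assert_mask(pred)
  assert_mask(truth)
  denominator <- match.arg(denominator)
  if (!identical(dim(pred), dim(truth)))
    stopf("mask sizes differ: %d x %d vs %d x %d", nrow(pred), ncol(pred),
          nrow(truth), ncol(truth))
  eps <- .Machine$double.eps
  inter <- sum(pred * truth)
  denom <- if (denominator == "union") sum(pred) + sum(truth) - inter
  else sum(pred) + sum(truth)
  structure(list(J = (inter + eps) / (denom + eps),
                 frame_id = frame_id, n_pixels = length(pred), epsilon = eps),
            class = "score_record")
}

#' Mean IoU over a sequence of frames
#'
#' @param records Nonempty list of `score_record`s from [iou()].
#' @return A `sequence_score` list: `records`, `mean_J`, and `percent`
#'   (`mean_J * 100`, the conventional reporting scale).
#' @export
sequence_miou <- function(records) {
  if (length(records) == 0) stopf("empty record list")
  js <- vapply(records, function(r) r$J, numeric(1))
  structure(list(records = records, mean_J = mean(js),
                 percent = 100 * mean(js)),
            class = "sequence_score")
}

#' @export
print.sequence_score <- function(x, ...) {
  cat(sprintf("<sequence_score> %d frames, mIoU = %.4f (%.1f%%)\n",
              length(x$records), x$mean_J, x$percent))
  invisible(x)
}

#' Pixel-wise cross-entropy between a probability map and a binary label
#'
#' Two-class cross-entropy with natural logarithm,
#' `L = -sum_i [y_i log p_i + (1 - y_i) log(1 - p_i)]`, where `p` is the
#' predicted foreground probability. Probabilities are floored at `1e-12`
#' (and capped at `1 - 1e-12`) for numerical safety.
#'
#' @param pred H x W probability map.
#' @param truth H x W binary mask of the same size.
#' @return Nonnegative scalar loss (summed over pixels).
#' @export
pixelwise_cross_entropy <- function(pred, truth) {
  assert_probmap(pred)
  assert_mask(truth)
  if (!identical(dim(pred), dim(truth))) stopf("sizes differ")
  p <- pmin(pmax(pred, 1e-12), 1 - 1e-12)
  -sum(truth * log(p) + (1 - truth) * log(1 - p))
}
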