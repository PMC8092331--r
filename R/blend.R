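# The blending basis {phi_m}, M = 3: trivial copy-paste, Gaussian
# feathering, Laplacian pyramid blending. Whatever the blending function,
# the composite's label is the foreground mask, bit-exactly.

BLEND_MODES <- c("trivial", "gaussian_feather", "laplacian")

#' Blending specification
#'
#' @param mode One of `"trivial"`, `"gaussian_feather"`, `"laplacian"`.
#' @param erosion_kernel Odd square erosion kernel size for feathering
#'   (default 3).
#' @param blur_kernel Odd Gaussian blur kernel size for feathering
#'   (default 5); sigma follows the conventional kernel-to-sigma rule
#'   `0.3 * ((k - 1)/2 - 1) + 0.8`.
#' @param pyramid_levels Laplacian pyramid depth (default 4).
#' @return List of class `"blend_spec"`.
#' @export
blend_spec <- function(mode = "trivial", erosion_kernel = 3L,
                       blur_kernel = 5L, pyramid_levels = 4L) {
  mode <- match.arg(mode, BLEND_MODES)
  if (!is_odd(erosion_kernel) || erosion_kernel < 1 ||
      !is_odd(blur_kernel) || blur_kernel < 1)
    stopf("erosion and blur kernels must be odd and >= 1")
  if (pyramid_levels < 1) stopf("pyramid_levels must be >= 1")
  structure(list(mode = mode, erosion_kernel = as.integer(erosion_kernel),
                 blur_kernel = as.integer(blur_kernel),
                 pyramid_levels = as.integer(pyramid_levels)),
            class = "blend_spec")
}

#' The default ordered blending basis (M = 3)
#'
#' @param cfg Optional `pipeline_config` supplying kernel parameters.
#' @return Ordered list of three [blend_spec()] objects: trivial, Gaussian
#'   feathering, Laplacian.
#' @export
default_basis <- function(cfg = NULL) {
  p <- if (is.null(cfg)) list(erosion_kernel = 3L, blur_kernel = 5L,
                              pyramid_levels = 4L) else cfg$blend
  lapply(BLEND_MODES, function(m)
    blend_spec(m, p$erosion_kernel, p$blur_kernel, p$pyramid_levels))
}

check_pair <- function(fg, bg) {
  stopifnot(inherits(fg, "foreground_sample"), inherits(bg, "background_sample"))
  if (!identical(dim(fg$image), dim(bg$image)))
    stopf("foreground (%s) and background (%s) sizes differ",
          paste(dim(fg$image)[1:2], collapse = "x"),
          paste(dim(bg$image)[1:2], collapse = "x"))
}

blend_result <- function(image, label)
  structure(list(image = image, label = label), class = "blend_result")

#' Trivial blending (copy-paste)
#'
#' Pixels activated in the tool mask are copied from the foreground onto
#' the background; the label is the foreground mask.
#'
#' @param fg A [foreground_sample()].
#' @param bg A [background_sample()] of the same size.
#' @return A `blend_result` with fields `image` and `label`.
#' @export
blend_trivial <- function(fg, bg) {
  check_pair(fg, bg)
  m3 <- mask3(fg$mask)
  blend_result(fg$image * m3 + bg$image * (1 - m3), fg$mask)
}

#' Gaussian feathering
#'
#' The binary mask is eroded (k = 3) and blurred (k = 5) into a soft mask
#' `m`; the blend is `m * x_f + (1 - m) * x_b` per channel. The label stays
#' the original binary mask, not the soft one.
#'
#' @inheritParams blend_trivial
#' @param spec A [blend_spec()] carrying the kernel sizes.
#' @return A `blend_result`.
#' @export
blend_gaussian_feather <- function(fg, bg, spec = blend_spec("gaussian_feather")) {
  check_pair(fg, bg)
  m <- fg$mask
  if (spec$erosion_kernel > 1) m <- erode_mask(m, box_brush(spec$erosion_kernel))
  if (spec$blur_kernel > 1) m <- conv_sep(m, gaussian_kernel(spec$blur_kernel))
  m3 <- mask3(m)
  blend_result(clip01(fg$image * m3 + bg$image * (1 - m3)), fg$mask)
}

#' Laplacian pyramid blending
#'
#' Laplacian pyramids of foreground and background are combined level-wise,
#' weighted by the Gaussian pyramid of the mask, then collapsed: seams are
#' blended at coarse scales and detail at fine scales, avoiding the crisp
#' boundary of copy-paste. The output is clipped (not renormalized) to
#' `[0,1]`; the label stays the binary mask.
#'
#' @inheritParams blend_gaussian_feather
#' @return A `blend_result`.
#' @export
blend_laplacian <- function(fg, bg, spec = blend_spec("laplacian")) {
  check_pair(fg, bg)
  L <- spec$pyramid_levels
  d <- dim(fg$image)
  if (min(d[1], d[2]) < 2^L)
    stopf("image (%d x %d) smaller than 2^%d: reduce pyramid_levels",
          d[1], d[2], L)
  pad <- padded_dims(d[1], d[2], L)
  out <- array(0, c(pad$H, pad$W, 3))
  mp <- gauss_pyramid(pad_to(fg$mask, pad$H, pad$W), L)
  for (c in 1:3) {
    lf <- lap_pyramid(pad_to(fg$image[, , c], pad$H, pad$W), L)
    lb <- lap_pyramid(pad_to(bg$image[, , c], pad$H, pad$W), L)
    comb <- mapply(function(a, b, w) w * a + (1 - w) * b,
                   lf, lb, mp, SIMPLIFY = FALSE)
    out[, , c] <- collapse_pyramid(comb)
  }
  blend_result(clip01(out[seq_len(d[1]), seq_len(d[2]), , drop = FALSE]),
               fg$mask)
}

#' Apply a blend spec by mode
#'
#' @inheritParams blend_gaussian_feather
#' @return A `blend_result`.
#' @export
blend_apply <- function(fg, bg, spec) {
  switch(spec$mode,
         trivial = blend_trivial(fg, bg),
         gaussian_feather = blend_gaussian_feather(fg, bg, spec),
         laplacian = blend_laplacian(fg, bg, spec))
}

# ---- pyramid machinery: 5-tap binomial kernel, reflect-101 borders ----

BINOMIAL5 <- c(1, 4, 6, 4, 1) / 16

pyr_down <- function(m) {
  s <- conv_sep(m, BINOMIAL5)
  s[seq(1, nrow(m), by = 2), seq(1, ncol(m), by = 2), drop = FALSE]
}

pyr_up <- function(m, H, W) {
  up <- matrix(0, H, W)
  up[seq(1, H, by = 2), seq(1, W, by = 2)] <- m
  conv_sep(up, 2 * BINOMIAL5)  # doubled kernel compensates the zero fill
}

gauss_pyramid <- function(m, L) {
  pyr <- vector("list", L + 1)
  pyr[[1]] <- m
  for (l in seq_len(L)) pyr[[l + 1]] <- pyr_down(pyr[[l]])
  pyr
}

# Levels 1..L are band-pass (G_l - up(G_{l+1})); level L+1 is the residual.
lap_pyramid <- function(m, L) {
  gp <- gauss_pyramid(m, L)
  lp <- vector("list", L + 1)
  for (l in seq_len(L)) {
    g <- gp[[l]]
    lp[[l]] <- g - pyr_up(gp[[l + 1]], nrow(g), ncol(g))
  }
  lp[[L + 1]] <- gp[[L + 1]]
  lp
}

collapse_pyramid <- function(lp) {
  L <- length(lp) - 1
  acc <- lp[[L + 1]]
  for (l in rev(seq_len(L))) {
    g <- lp[[l]]
    acc <- g + pyr_up(acc, nrow(g), ncol(g))
  }
  acc
}

padded_dims <- function(H, W, L) {
  u <- 2^L
  list(H = as.integer(ceiling(H / u) * u), W = as.integer(ceiling(W / u) * u))
}

# Extend a matrix to (H, W) by reflect-101 continuation on the two far edges.
pad_to <- function(m, H, W) {
  if (nrow(m) == H && ncol(m) == W) return(m)
  ri <- c(seq_len(nrow(m)), nrow(m) - seq_len(H - nrow(m)))
  ci <- c(seq_len(ncol(m)), ncol(m) - seq_len(W - ncol(m)))
  m[clamp_idx(ri, nrow(m)), clamp_idx(ci, ncol(m)), drop = FALSE]
}
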