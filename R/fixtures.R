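# Procedural fixtures emulating the recording conditions every stage is
# tested against: elongated metallic tool shapes over an illuminated,
# noisy green chroma field (with soft shadows excluded from the ground
# truth), red/pink low-frequency tissue backgrounds, and corrupted
# probability maps. Fixture masks are exact by construction -- no
# extraction step is involved -- so they serve as ground truth.

#' Fixture specification
#'
#' @param n_tools Number of instruments per image, 1 to 3.
#' @param height,width Image size in pixels (>= 64).
#' @param green_hue,green_spread Chroma green hue centre and half-spread,
#'   degrees.
#' @param illum_amplitude Illumination gradient amplitude in `[0,1]`.
#' @param noise_sigma Pixel noise sigma in `[0,1]`.
#' @param tool_radius Tool half-width range, px.
#' @param shadow_strength Multiplicative darkening of the soft shadow
#'   (1 = no shadow). Shadows are drawn in the green field but excluded
#'   from the ground-truth mask.
#' @param seed Integer seed; fixtures are fully deterministic given the
#'   spec.
#' @return List of class `"fixture_spec"`.
#' @export
fixture_spec <- function(n_tools = 2L, height = 96L, width = 96L,
                         green_hue = 120, green_spread = 12,
                         illum_amplitude = 0.15, noise_sigma = 0.02,
                         tool_radius = c(4, 9), shadow_strength = 0.75,
                         seed = 1L) {
  if (n_tools < 1 || n_tools > 3) stopf("n_tools must be in [1,3]")
  if (height < 64 || width < 64) stopf("fixture size must be at least 64 x 64")
  structure(list(n_tools = as.integer(n_tools), height = as.integer(height),
                 width = as.integer(width), green_hue = green_hue,
                 green_spread = green_spread,
                 illum_amplitude = illum_amplitude, noise_sigma = noise_sigma,
                 tool_radius = tool_radius, shadow_strength = shadow_strength,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate a green-screen foreground fixture with exact ground truth
#'
#' A green chroma field (hue inside the configured band, modulated by an
#' illumination gradient and Gaussian noise) with `n_tools` elongated
#' capsule/polyline shapes shaded with a metallic gray-to-specular gradient
#' and a soft shadow under each tool. Every tool touches an image border;
#' tools are pairwise disjoint, so the mask has exactly `n_tools`
#' components and is exact by construction.
#'
#' @param spec A [fixture_spec()].
#' @return A [foreground_sample()] whose `mask` is the ground truth.
#' @export
make_foreground_fixture <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  rng <- make_rng(spec$seed, "fixture-foreground")
  H <- spec$height; W <- spec$width

  img <- green_field(spec, rng)
  sep <- disc_brush(3)
  # place all tools, restarting the whole arrangement when one cannot be
  # fit disjointly (bounded retries at both levels)
  arrangement <- NULL
  for (restart in 1:8) {
    mask <- matrix(0, H, W)
    tools <- list()
    ok <- TRUE
    for (t in seq_len(spec$n_tools)) {
      placed <- FALSE
      for (attempt in 1:40) {
        tool <- draw_tool_geometry(spec, rng)
        if (sum(tool$mask) < 20) next
        # disjointness: a 3-px dilation of the new tool must avoid the rest
        if (sum(dilate_mask(tool$mask, sep) * mask) > 0) next
        mask <- pmax(mask, tool$mask)
        tools[[t]] <- tool
        placed <- TRUE
        break
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) { arrangement <- list(mask = mask, tools = tools); break }
  }
  if (is.null(arrangement)) stopf("tool placement failed after bounded retries")
  mask <- arrangement$mask
  tools <- arrangement$tools
  # soft shadows first (under the tools), then the tools on top
  for (tool in tools) img <- cast_shadow(img, tool$mask, mask, spec)
  for (tool in tools) img <- paint_tool(img, tool)
  img <- clip01(img + array(rng_rnorm(rng, H * W * 3, 0, spec$noise_sigma),
                            c(H, W, 3)))
  foreground_sample(img, mask, id = sprintf("fixture-fg-%d", spec$seed))
}

# Green chroma field: hue near the band centre, saturation high, value
# modulated by a linear illumination gradient plus low-frequency variation.
green_field <- function(spec, rng) {
  H <- spec$height; W <- spec$width
  theta <- rng_runif(rng, 1, 0, 2 * pi)
  gy <- (seq_len(H) - 1) / max(1, H - 1) - 0.5
  gx <- (seq_len(W) - 1) / max(1, W - 1) - 0.5
  grad <- outer(gy * sin(theta), gx * cos(theta), "+")
  grad <- grad / max(abs(grad), 1e-9)
  h <- matrix(spec$green_hue, H, W) +
    matrix(rng_rnorm(rng, H * W, 0, spec$green_spread / 6), H, W)
  s <- clip01(matrix(0.8, H, W) + 0.05 * grad)
  v <- clip01(matrix(0.55, H, W) + spec$illum_amplitude * grad)
  hsv_image(h, s, v)
}

# An articulated capsule: a 2-3 segment polyline entering from a random
# border, with per-pixel distance to the axis and arclength fraction kept
# for shading.
draw_tool_geometry <- function(spec, rng) {
  H <- spec$height; W <- spec$width
  r <- rng_runif(rng, 1, spec$tool_radius[1], spec$tool_radius[2])
  side <- rng_int(rng, 4)
  p0 <- switch(side,
               c(1, rng_runif(rng, 1, 0.15, 0.85) * W),                # top
               c(H, rng_runif(rng, 1, 0.15, 0.85) * W),                # bottom
               c(rng_runif(rng, 1, 0.15, 0.85) * H, 1),                # left
               c(rng_runif(rng, 1, 0.15, 0.85) * H, W))                # right
  # direction angle with (dy, dx) = (sin a, cos a), pointing inward
  ang <- switch(side, pi / 2, 3 * pi / 2, 0, pi)
  ang <- ang + rng_runif(rng, 1, -0.5, 0.5)
  nseg <- 1L + rng_int(rng, 2)  # 2 or 3 segments
  len <- rng_runif(rng, nseg, 0.25, 0.45) * min(H, W)
  pts <- matrix(0, nseg + 1L, 2)
  pts[1, ] <- p0
  a <- ang
  for (s in seq_len(nseg)) {
    pts[s + 1L, ] <- pts[s, ] + len[s] * c(sin(a), cos(a))
    a <- a + rng_runif(rng, 1, -0.6, 0.6)
  }
  yy <- matrix(seq_len(H), H, W)
  xx <- matrix(rep(seq_len(W), each = H), H, W)
  dmin <- matrix(Inf, H, W)
  smin <- matrix(0, H, W)
  total <- sum(len)
  acc <- 0
  for (s in seq_len(nseg)) {
    a1 <- pts[s, ]; a2 <- pts[s + 1L, ]
    v <- a2 - a1
    vv <- sum(v^2)
    t <- ((yy - a1[1]) * v[1] + (xx - a1[2]) * v[2]) / max(vv, 1e-9)
    t <- pmin(pmax(t, 0), 1)
    dy <- yy - (a1[1] + t * v[1]); dx <- xx - (a1[2] + t * v[2])
    dseg <- sqrt(dy^2 + dx^2)
    upd <- dseg < dmin
    smin[upd] <- (acc + t[upd] * len[s]) / total
    dmin[upd] <- dseg[upd]
    acc <- acc + len[s]
  }
  list(mask = (dmin <= r) * 1, dist = dmin, arc = smin, radius = r)
}

# Metallic shading: gray base brightening along the shaft with a specular
# ridge on the axis and a slightly cool tint.
paint_tool <- function(img, tool) {
  idx <- tool$mask == 1
  v <- 0.35 + 0.35 * tool$arc[idx] +
    0.3 * exp(-(tool$dist[idx] / (0.35 * tool$radius))^2)
  tint <- c(0.92, 0.94, 1.0)
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[idx] <- clip01(v * tint[ch])
    img[, , ch] <- plane
  }
  img
}

# Soft shadow: the tool mask shifted diagonally and blurred, darkening the
# green field multiplicatively (hue and saturation are preserved, so the
# shadow stays inside the chroma band -- the hard case thresholding must
# survive). Shadows never cover tool pixels of any tool.
cast_shadow <- function(img, tool_mask, all_mask, spec) {
  sh <- shift_image(tool_mask, 3L, 3L, fill = 0)
  sh <- gauss_blur(sh, 1.5)
  sh[all_mask == 1] <- 0
  fac <- 1 - (1 - spec$shadow_strength) * sh
  img * mask3(fac)
}

#' Generate a tissue-like background fixture
#'
#' A red/pink low-frequency textured field (multi-octave value noise mapped
#' to a tissue palette) with specular highlights and a dark vignette. No
#' pixel falls inside the chroma green band.
#'
#' @param spec A [fixture_spec()].
#' @return A [background_sample()].
#' @export
make_background_fixture <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  rng <- make_rng(spec$seed, "fixture-background")
  H <- spec$height; W <- spec$width
  t1 <- low_freq_field(c(H, W), rng)
  t2 <- low_freq_field(c(H, W), rng)
  t3 <- low_freq_field(c(H, W), rng)
  h <- 345 + 25 * t1                      # wraps through red into pink
  s <- 0.45 + 0.3 * t2
  v <- 0.3 + 0.45 * t3
  img <- hsv_image(h, s, v)
  # specular highlights: a few bright soft spots (desaturated, never green)
  nspot <- rng_int(rng, 3)
  yy <- matrix(seq_len(H), H, W); xx <- matrix(rep(seq_len(W), each = H), H, W)
  for (i in seq_len(nspot)) {
    cy <- rng_runif(rng, 1, 0.2, 0.8) * H; cx <- rng_runif(rng, 1, 0.2, 0.8) * W
    rad <- rng_runif(rng, 1, 0.03, 0.08) * min(H, W)
    g <- exp(-((yy - cy)^2 + (xx - cx)^2) / (2 * rad^2))
    img <- clip01(img + 0.5 * mask3(g))
  }
  # dark vignette
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  dist2 <- outer((seq_len(H) - cy)^2, (seq_len(W) - cx)^2, "+")
  vig <- 1 - 0.3 * dist2 / max(dist2)
  img <- img * mask3(vig)
  img <- clip01(img + array(rng_rnorm(rng, H * W * 3, 0, spec$noise_sigma),
                            c(H, W, 3)))
  background_sample(img, id = sprintf("fixture-bg-%d", spec$seed))
}

#' Generate a corrupted probability map from a ground-truth mask
#'
#' The mask is Gaussian-blurred, then a fraction `flip_rate` of pixels is
#' pushed into the uncertain band `(0.2, 0.8)`; values are clipped to
#' `[0,1]`. With `flip_rate = 0` and `blur_sigma = 0` the map equals the
#' mask exactly.
#'
#' @param truth H x W binary ground-truth mask.
#' @param flip_rate Fraction of pixels pushed into the uncertain band,
#'   in `[0, 0.5]`.
#' @param blur_sigma Gaussian blur sigma in pixels.
#' @param rng A [make_rng()] handle.
#' @return H x W probability map in `[0,1]`.
#' @export
make_probmap_fixture <- function(truth, flip_rate = 0.3, blur_sigma = 1.5,
                                 rng = make_rng(0, "probmap")) {
  assert_mask(truth)
  if (flip_rate < 0 || flip_rate > 0.5) stopf("flip_rate must be in [0, 0.5]")
  p <- if (blur_sigma > 0) gauss_blur(truth, blur_sigma) else truth
  n <- round(flip_rate * length(p))
  if (n > 0) {
    idx <- with_rng(rng, sample.int(length(p), n))
    p[idx] <- rng_runif(rng, n, 0.2 + 1e-6, 0.8 - 1e-6)
  }
  clip01(p)
}
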