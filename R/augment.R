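# Domain-randomization augmentation stack. Geometric operations are applied
# identically to image and mask (bilinear vs nearest); photometric
# operations never touch labels. The specific magnitudes are configurable;
# the defaults keep tools recognizable.

#' Augmentation configuration
#'
#' Per-operation probabilities and parameter ranges for the foreground,
#' background and post-blend augmentations, the flying distractors and the
#' endoscopic padding. All probabilities are in `[0,1]`; set them to 0 for
#' an identity stack.
#'
#' @param p_flip_h,p_flip_v,p_zoom,p_rotate,p_shift Geometric op
#'   probabilities (foreground; flips also apply to backgrounds).
#' @param p_rot90 Probability of a random 90-degree background rotation.
#' @param p_droplets Probability of drawing blood droplets / debris on the
#'   tools.
#' @param p_brightness Brightness jitter probability.
#' @param p_photo Probability of each post-blend photometric op.
#' @param zoom_range Multiplicative zoom range.
#' @param rotation_range Rotation range, degrees.
#' @param shift_frac Maximum shift as a fraction of width/height.
#' @param brightness_delta Maximum additive brightness change.
#' @param droplet_lambda Poisson mean droplet count.
#' @param droplet_radius Droplet radius range, px.
#' @param droplet_alpha Droplet opacity range.
#' @param droplet_hue_jitter Droplet hue jitter around dark red, degrees.
#' @param cutout_count,cutout_size Cutout count range and square size range.
#' @param smoke_intensity,shadow_intensity Intensity ranges for synthetic
#'   smoke (additive) and shadows (multiplicative).
#' @param jpeg_quality JPEG compression quality range (1-100).
#' @param noise_sigma Noise sigma range (Gaussian / multiplicative / ISO).
#' @param blur_kernel Blur kernel size range (odd sizes drawn inside it).
#' @param distractor_count Flying-distractor count range (uniform integer).
#' @param padding_prob Probability of endoscopic padding.
#' @param padding_width_frac Max rectangular padding width, fraction of W.
#' @param disc_radius_frac Circular padding radius range, fraction of
#'   `min(H, W)`.
#' @param padding_noise_sigma Gaussian noise sigma on the black padding.
#' @param max_retries Retry budget for border-connectivity-preserving
#'   geometric draws before falling back to identity.
#' @param repad_after_blend Re-apply the padding after blending and zero the
#'   overlapped label (off by default).
#' @return List of class `"augment_config"`.
#' @export
augment_config <- function(p_flip_h = 0.5, p_flip_v = 0.5, p_zoom = 0.5,
                           p_rotate = 0.5, p_shift = 0.5, p_rot90 = 0.5,
                           p_droplets = 0.5, p_brightness = 0.5,
                           p_photo = 0.3,
                           zoom_range = c(0.7, 1.3),
                           rotation_range = c(-90, 90),
                           shift_frac = 0.2,
                           brightness_delta = 0.2,
                           droplet_lambda = 3,
                           droplet_radius = c(2, 15),
                           droplet_alpha = c(0.3, 0.8),
                           droplet_hue_jitter = 10,
                           cutout_count = c(1, 3),
                           cutout_size = c(8, 32),
                           smoke_intensity = c(0.1, 0.4),
                           shadow_intensity = c(0.2, 0.5),
                           jpeg_quality = c(50, 100),
                           noise_sigma = c(0.01, 0.05),
                           blur_kernel = c(3, 7),
                           distractor_count = c(0, 3),
                           padding_prob = 0.3,
                           padding_width_frac = 0.1,
                           disc_radius_frac = c(0.45, 0.55),
                           padding_noise_sigma = 0.02,
                           max_retries = 20L,
                           repad_after_blend = FALSE) {
  cfg <- as.list(environment())
  probs <- cfg[grep("^p_|padding_prob", names(cfg))]
  if (any(unlist(probs) < 0 | unlist(probs) > 1))
    stopf("all probabilities must lie in [0,1]")
  structure(cfg, class = "augment_config")
}

#' An all-identity augmentation configuration
#'
#' Every probability set to zero; useful for debugging and for the
#' `--no-augment` pipeline mode.
#' @return An [augment_config()] with all probabilities 0.
#' @export
no_augment_config <- function() {
  augment_config(p_flip_h = 0, p_flip_v = 0, p_zoom = 0, p_rotate = 0,
                 p_shift = 0, p_rot90 = 0, p_droplets = 0, p_brightness = 0,
                 p_photo = 0, padding_prob = 0, distractor_count = c(0, 0))
}

# ---- foreground ----

#' Augment a foreground sample
#'
#' Random zoom, rotation, flips and shifts applied identically to image
#' (bilinear) and mask (nearest, rebinarized at 0.5), preserving the
#' invariant that every tool component stays connected to the image border:
#' draws violating it are resampled up to `max_retries`, then identity is
#' used. Blood droplets / tissue debris are drawn only on tool pixels, and
#' brightness is jittered.
#'
#' @param fg A [foreground_sample()].
#' @param cfg An [augment_config()].
#' @param rng A [make_rng()] handle.
#' @return An augmented [foreground_sample()].
#' @export
augment_foreground <- function(fg, cfg = augment_config(),
                               rng = make_rng(0, "fg-aug")) {
  stopifnot(inherits(fg, "foreground_sample"))
  img <- fg$image; msk <- fg$mask
  d <- dim(img)
  fill <- apply(img, 3, stats::median)  # neutral fill for exposed regions

  attempt <- function() {
    im <- img; mk <- msk
    if (rng_runif(rng, 1) < cfg$p_flip_h) { im <- flip_horizontal(im); mk <- flip_horizontal(mk) }
    if (rng_runif(rng, 1) < cfg$p_flip_v) { im <- flip_vertical(im); mk <- flip_vertical(mk) }
    if (rng_runif(rng, 1) < cfg$p_zoom) {
      z <- rng_runif(rng, 1, cfg$zoom_range[1], cfg$zoom_range[2])
      zoomed <- zoom_pair(im, mk, z, fill)
      im <- zoomed$image; mk <- zoomed$mask
    }
    if (rng_runif(rng, 1) < cfg$p_rotate) {
      a <- rng_runif(rng, 1, cfg$rotation_range[1], cfg$rotation_range[2])
      im <- rotate_image(im, a, fill = mean(fill))
      mk <- (rotate_image(mk, a, nearest = TRUE, fill = 0) >= 0.5) * 1
    }
    if (rng_runif(rng, 1) < cfg$p_shift) {
      dy <- round(rng_runif(rng, 1, -cfg$shift_frac, cfg$shift_frac) * d[1])
      dx <- round(rng_runif(rng, 1, -cfg$shift_frac, cfg$shift_frac) * d[2])
      im <- shift_image(im, dy, dx, fill = mean(fill))
      mk <- shift_image(mk, dy, dx, fill = 0)
    }
    list(image = clip01(im), mask = mk)
  }

  out <- NULL
  for (i in seq_len(max(1L, cfg$max_retries))) {
    cand <- attempt()
    if (sum(cand$mask) > 0 && all_components_touch_border(cand$mask)) {
      out <- cand
      break
    }
  }
  if (is.null(out)) out <- list(image = img, mask = msk)  # identity fallback

  if (rng_runif(rng, 1) < cfg$p_droplets)
    out$image <- draw_droplets(out$image, out$mask, cfg, rng)
  if (rng_runif(rng, 1) < cfg$p_brightness) {
    delta <- rng_runif(rng, 1, -cfg$brightness_delta, cfg$brightness_delta)
    out$image <- clip01(out$image + delta)
  }
  foreground_sample(out$image, out$mask, id = fg$id)
}

zoom_pair <- function(im, mk, z, fill) {
  d <- dim(im)
  H2 <- max(8L, round(d[1] * z)); W2 <- max(8L, round(d[2] * z))
  im2 <- resize_image(im, H2, W2)
  mk2 <- (resize_image(mk, H2, W2, nearest = TRUE) >= 0.5) * 1
  if (z >= 1) {  # centre crop back to original extent
    y0 <- (H2 - d[1]) %/% 2L; x0 <- (W2 - d[2]) %/% 2L
    im2 <- im2[y0 + seq_len(d[1]), x0 + seq_len(d[2]), , drop = FALSE]
    mk2 <- mk2[y0 + seq_len(d[1]), x0 + seq_len(d[2]), drop = FALSE]
  } else {       # centre pad back to original extent
    imp <- array(rep(fill, each = d[1] * d[2]), d)
    mkp <- matrix(0, d[1], d[2])
    y0 <- (d[1] - H2) %/% 2L; x0 <- (d[2] - W2) %/% 2L
    imp[y0 + seq_len(H2), x0 + seq_len(W2), ] <- im2
    mkp[y0 + seq_len(H2), x0 + seq_len(W2)] <- mk2
    im2 <- imp; mk2 <- mkp
  }
  list(image = im2, mask = mk2)
}

# Blood droplets / tissue debris: dark-red soft discs alpha-blended onto
# tool pixels only (pixels with mask = 0 are never modified).
draw_droplets <- function(img, mask, cfg, rng) {
  tool <- which(mask == 1)
  if (length(tool) == 0) return(img)
  k <- min(rng_rpois(rng, 1, cfg$droplet_lambda), 12)
  if (k == 0) return(img)
  n1 <- nrow(mask); n2 <- ncol(mask)
  row <- ((tool - 1L) %% n1) + 1L
  col <- ((tool - 1L) %/% n1) + 1L
  for (i in seq_len(k)) {
    pick <- rng_int(rng, length(tool))
    cy <- row[pick]; cx <- col[pick]
    r <- rng_runif(rng, 1, cfg$droplet_radius[1], cfg$droplet_radius[2])
    a <- rng_runif(rng, 1, cfg$droplet_alpha[1], cfg$droplet_alpha[2])
    hue <- rng_runif(rng, 1, -cfg$droplet_hue_jitter, cfg$droplet_hue_jitter)
    colr <- hsv_to_rgb(hue, 0.85, 0.3)
    yy <- clamp_idx(cy + seq(-ceiling(r), ceiling(r)), n1)
    xx <- clamp_idx(cx + seq(-ceiling(r), ceiling(r)), n2)
    yy <- unique(yy); xx <- unique(xx)
    dist2 <- outer((yy - cy)^2, (xx - cx)^2, "+")
    w <- a * exp(-dist2 / (0.5 * r^2))           # soft droplet profile
    w <- w * mask[yy, xx, drop = FALSE]          # restricted to the tool
    dcol <- c(colr$r, colr$g, colr$b)
    for (ch in 1:3)
      img[yy, xx, ch] <- (1 - w) * img[yy, xx, ch] + w * dcol[ch]
  }
  clip01(img)
}

# ---- background ----

#' Augment a background sample
#'
#' Horizontal/vertical flips, brightness changes, and random 90-degree
#' rotations (all label-free: a background carries no mask).
#'
#' @param bg A [background_sample()].
#' @inheritParams augment_foreground
#' @return An augmented [background_sample()].
#' @export
augment_background <- function(bg, cfg = augment_config(),
                               rng = make_rng(0, "bg-aug")) {
  stopifnot(inherits(bg, "background_sample"))
  img <- bg$image
  if (rng_runif(rng, 1) < cfg$p_flip_h) img <- flip_horizontal(img)
  if (rng_runif(rng, 1) < cfg$p_flip_v) img <- flip_vertical(img)
  if (rng_runif(rng, 1) < cfg$p_rot90) {
    k <- rng_int(rng, 3)  # 90, 180 or 270 degrees
    if (dim(img)[1] == dim(img)[2]) img <- rotate90(img, k)
    else img <- rotate90(img, 2)  # non-square frames: only 180 keeps extent
  }
  if (rng_runif(rng, 1) < cfg$p_brightness) {
    delta <- rng_runif(rng, 1, -cfg$brightness_delta, cfg$brightness_delta)
    img <- clip01(img + delta)
  }
  background_sample(img, id = bg$id)
}

#' Add flying distractors to a background
#'
#' Distractors are cutouts of *other* backgrounds shaped like a
#' (transformed) tool mask, blended into the background with the same
#' blending procedure later used for the true tools. They contribute no
#' label: a composite built from a distracted background has exactly the
#' label of one built from the clean background. This discourages a
#' segmentation network from using blending artifacts as a foreground cue.
#'
#' @param bg Target [background_sample()].
#' @param donor_bgs Nonempty list of donor [background_sample()]s providing
#'   the cutout textures.
#' @param shape_source A [foreground_sample()] providing the tool shape.
#' @param blend_fun Blending procedure, `function(fg, bg) -> blend_result`
#'   (the same one used for the true tools).
#' @inheritParams augment_foreground
#' @return A [background_sample()] with distractors blended in.
#' @export
add_flying_distractors <- function(bg, donor_bgs, shape_source, blend_fun,
                                   cfg = augment_config(),
                                   rng = make_rng(0, "distractors")) {
  stopifnot(inherits(bg, "background_sample"))
  if (length(donor_bgs) == 0) stopf("donor background list is empty")
  if (sum(shape_source$mask) == 0) stopf("shape source mask is empty")
  k <- rng_int(rng, cfg$distractor_count[2] - cfg$distractor_count[1] + 1L) -
    1L + cfg$distractor_count[1]
  if (k == 0) return(bg)
  d <- dim(bg$image)
  img <- bg$image
  for (i in seq_len(k)) {
    donor <- donor_bgs[[rng_int(rng, length(donor_bgs))]]
    tex <- conform_image(donor$image, d[1], d[2])
    shp <- conform_image(shape_source$mask, d[1], d[2], nearest = TRUE)
    # exact random rigid-ish transform of the shape
    if (rng_runif(rng, 1) < 0.5) shp <- flip_horizontal(shp)
    if (rng_runif(rng, 1) < 0.5) shp <- flip_vertical(shp)
    if (d[1] == d[2] && rng_runif(rng, 1) < 0.5) shp <- rotate90(shp, rng_int(rng, 3))
    dy <- rng_int(rng, d[1]) - d[1] %/% 2L
    dx <- rng_int(rng, d[2]) - d[2] %/% 2L
    shp <- shift_image(shp, dy, dx, fill = 0)
    if (sum(shp) == 0) next
    pseudo <- structure(list(image = tex, mask = shp, id = donor$id),
                        class = "foreground_sample")  # unchecked: shape need not touch border
    res <- blend_fun(pseudo, background_sample(img, id = bg$id))
    img <- res$image
  }
  background_sample(img, id = bg$id)
}

#' Add endoscopic padding to a background
#'
#' With probability `padding_prob`, overlays the black border typical of
#' endoscope optics: either a rectangular frame of random width or the
#' complement of a centred disc of random radius, set to black plus
#' Gaussian noise. Image size is unchanged.
#'
#' @inheritParams augment_background
#' @return A [background_sample()].
#' @export
add_endoscopic_padding <- function(bg, cfg = augment_config(),
                                   rng = make_rng(0, "padding")) {
  stopifnot(inherits(bg, "background_sample"))
  if (rng_runif(rng, 1) >= cfg$padding_prob) return(bg)
  region <- draw_padding_region(dim(bg$image)[1:2], cfg, rng)
  background_sample(apply_padding(bg$image, region, cfg, rng), id = bg$id)
}

draw_padding_region <- function(d, cfg, rng,
                                shape = c("random", "rectangular",
                                          "circular")) {
  shape <- match.arg(shape)
  n1 <- d[1]; n2 <- d[2]
  if (shape == "random")
    shape <- if (rng_runif(rng, 1) < 0.5) "rectangular" else "circular"
  else rng_runif(rng, 1)  # keep the draw sequence identical either way
  if (shape == "rectangular") {
    w <- max(1L, round(rng_runif(rng, 1, 0.02, cfg$padding_width_frac) * n2))
    reg <- matrix(FALSE, n1, n2)
    reg[c(seq_len(w), n1 - seq_len(w) + 1L), ] <- TRUE
    reg[, c(seq_len(w), n2 - seq_len(w) + 1L)] <- TRUE
  } else {
    r <- rng_runif(rng, 1, cfg$disc_radius_frac[1], cfg$disc_radius_frac[2]) *
      min(n1, n2)
    cy <- (n1 + 1) / 2; cx <- (n2 + 1) / 2
    reg <- outer((seq_len(n1) - cy)^2, (seq_len(n2) - cx)^2, "+") > r^2
  }
  reg
}

apply_padding <- function(img, region, cfg, rng) {
  n <- sum(region)
  if (n == 0) return(img)
  noise <- rng_rnorm(rng, 3L * n, 0, cfg$padding_noise_sigma)
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[region] <- noise[(ch - 1L) * n + seq_len(n)]
    img[, , ch] <- plane
  }
  clip01(img)
}

# ---- blended-image photometric augmentations ----

#' Photometric augmentation of a blended image
#'
#' Each operation is applied independently with probability `p_photo`:
#' cutouts, synthetic smoke and shadows, JPEG compression, RGB and HSV
#' shifts, multiplicative / Gaussian / ISO noise, and Gaussian / motion /
#' median blur. None of them modifies the label.
#'
#' @param x H x W x 3 array in `[0,1]`.
#' @inheritParams augment_foreground
#' @return Augmented image, clipped to `[0,1]`.
#' @export
augment_blended <- function(x, cfg = augment_config(),
                            rng = make_rng(0, "post-aug")) {
  assert_image(x)
  p <- cfg$p_photo
  if (rng_runif(rng, 1) < p) x <- op_cutout(x, cfg, rng)
  if (rng_runif(rng, 1) < p) x <- op_smoke(x, cfg, rng)
  if (rng_runif(rng, 1) < p) x <- op_shadow(x, cfg, rng)
  if (rng_runif(rng, 1) < p) x <- op_jpeg(x, cfg, rng)
  if (rng_runif(rng, 1) < p) x <- clip01(x + rep(rng_runif(rng, 3, -0.05, 0.05),
                                                 each = dim(x)[1] * dim(x)[2]))
  if (rng_runif(rng, 1) < p) x <- op_hsv_shift(x, rng)
  if (rng_runif(rng, 1) < p) {  # multiplicative noise
    s <- rng_runif(rng, 1, cfg$noise_sigma[1], cfg$noise_sigma[2])
    x <- clip01(x * (1 + array(rng_rnorm(rng, length(x), 0, s), dim(x))))
  }
  if (rng_runif(rng, 1) < p) {  # additive Gaussian noise
    s <- rng_runif(rng, 1, cfg$noise_sigma[1], cfg$noise_sigma[2])
    x <- clip01(x + array(rng_rnorm(rng, length(x), 0, s), dim(x)))
  }
  if (rng_runif(rng, 1) < p) {  # ISO noise: sigma grows with intensity
    s <- rng_runif(rng, 1, cfg$noise_sigma[1], cfg$noise_sigma[2])
    x <- clip01(x + sqrt(pmax(x, 0)) * array(rng_rnorm(rng, length(x), 0, s),
                                             dim(x)))
  }
  if (rng_runif(rng, 1) < p) {  # one of gaussian / motion / median blur
    which_blur <- rng_int(rng, 3)
    k <- draw_odd(rng, cfg$blur_kernel)
    x <- switch(which_blur,
                blur_rgb(x, sigma = 0.3 * ((k - 1) / 2 - 1) + 0.8, k = k),
                op_motion_blur(x, k, rng),
                op_median_blur(x, k))
  }
  clip01(x)
}

draw_odd <- function(rng, range) {
  k <- rng_int(rng, range[2] - range[1] + 1L) - 1L + range[1]
  if (k %% 2 == 0) k <- k + 1L
  as.integer(k)
}

op_cutout <- function(x, cfg, rng) {
  n <- rng_int(rng, cfg$cutout_count[2] - cfg$cutout_count[1] + 1L) - 1L +
    cfg$cutout_count[1]
  d <- dim(x)
  for (i in seq_len(n)) {
    s <- rng_int(rng, cfg$cutout_size[2] - cfg$cutout_size[1] + 1L) - 1L +
      cfg$cutout_size[1]
    s <- min(s, d[1], d[2])
    y0 <- rng_int(rng, d[1] - s + 1L); x0 <- rng_int(rng, d[2] - s + 1L)
    x[y0 - 1L + seq_len(s), x0 - 1L + seq_len(s), ] <- 0
  }
  x
}

low_freq_field <- function(d, rng, octaves = c(4L, 8L, 16L)) {
  acc <- matrix(0, d[1], d[2])
  w <- 1
  for (o in octaves) {
    g <- matrix(rng_rnorm(rng, o * o), o, o)
    acc <- acc + w * resize_image(g, d[1], d[2])
    w <- w / 2
  }
  rng01 <- range(acc)
  if (diff(rng01) < 1e-12) return(matrix(0.5, d[1], d[2]))
  (acc - rng01[1]) / diff(rng01)
}

op_smoke <- function(x, cfg, rng) {
  s <- rng_runif(rng, 1, cfg$smoke_intensity[1], cfg$smoke_intensity[2])
  f <- low_freq_field(dim(x), rng)
  clip01(x + s * mask3(f))
}

op_shadow <- function(x, cfg, rng) {
  s <- rng_runif(rng, 1, cfg$shadow_intensity[1], cfg$shadow_intensity[2])
  f <- low_freq_field(dim(x), rng)
  clip01(x * (1 - s * mask3(f)))
}

op_jpeg <- function(x, cfg, rng) {
  q <- rng_runif(rng, 1, cfg$jpeg_quality[1], cfg$jpeg_quality[2]) / 100
  jpeg_roundtrip(x, q)
}

# Encode/decode through an in-memory JPEG at the given quality in [0,1].
jpeg_roundtrip <- function(x, quality) {
  raw <- jpeg::writeJPEG(x, raw(), quality = quality)
  out <- jpeg::readJPEG(raw)
  if (is.matrix(out)) out <- array(out, dim = c(dim(out), 1L))
  if (dim(out)[3] == 1L) out <- array(out[, , 1], dim = c(dim(out)[1:2], 3L))
  clip01(out)
}

op_hsv_shift <- function(x, rng) {
  hsv <- rgb_to_hsv_arr(x)
  h <- hsv$h + rng_runif(rng, 1, -15, 15)
  s <- clip01(hsv$s + rng_runif(rng, 1, -0.1, 0.1))
  v <- clip01(hsv$v + rng_runif(rng, 1, -0.1, 0.1))
  hsv_image(h, s, v)
}

op_motion_blur <- function(x, k, rng) {
  # axis-aligned or diagonal streak kernel
  dir <- rng_int(rng, 4)
  ker <- matrix(0, k, k)
  mid <- (k + 1L) / 2L
  if (dir == 1) ker[mid, ] <- 1
  else if (dir == 2) ker[, mid] <- 1
  else if (dir == 3) diag(ker) <- 1
  else ker[cbind(seq_len(k), rev(seq_len(k)))] <- 1
  ker <- ker / sum(ker)
  for (ch in 1:3) x[, , ch] <- conv2_full(x[, , ch], ker)
  clip01(x)
}

# Dense 2D convolution with reflect-101 border (small kernels only).
conv2_full <- function(m, ker) {
  p <- (nrow(ker) - 1L) %/% 2L
  mp <- pad_reflect101(m, p)
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(nrow(ker))) for (j in seq_len(ncol(ker))) {
    w <- ker[i, j]
    if (w == 0) next
    out <- out + w * mp[(i - 1L) + seq_len(nrow(m)), (j - 1L) + seq_len(ncol(m))]
  }
  out
}

op_median_blur <- function(x, k) {
  r <- (k - 1L) %/% 2L
  if (r < 1) return(x)
  for (ch in 1:3)
    x[, , ch] <- from_eb(EBImage::medianFilter(to_eb(x[, , ch]), r))
  clip01(x)
}

# ---- standardization ----

#' Standardize a foreground-background pair to a common resolution
#'
#' Both images are resized to exactly `width` pixels wide preserving aspect
#' ratio (bilinear for images, nearest for the mask, rebinarized at 0.5);
#' the taller element is then randomly cropped vertically so both heights
#' match, leaving a co-registered pair ready for blending.
#'
#' @param fg A [foreground_sample()].
#' @param bg A [background_sample()].
#' @param width Standard width in pixels (default 640).
#' @param rng A [make_rng()] handle (crop offset).
#' @return List with the standardized `fg` and `bg`.
#' @export
standardize_pair <- function(fg, bg, width = 640L, rng = make_rng(0, "std")) {
  stopifnot(inherits(fg, "foreground_sample"), inherits(bg, "background_sample"))
  width <- as.integer(width)
  if (dim(fg$image)[2] < width / 4 || dim(bg$image)[2] < width / 4)
    stopf("inputs must be at least width/4 = %d pixels wide", width %/% 4L)
  rs <- function(img, nearest = FALSE) {
    d <- dim(img)
    H <- max(8L, as.integer(round(d[1] * width / d[2])))
    resize_image(img, H, width, nearest = nearest)
  }
  fim <- rs(fg$image)
  fmk <- (rs(fg$mask, nearest = TRUE) >= 0.5) * 1
  bim <- rs(bg$image)
  hf <- nrow(fmk); hb <- nrow(bim)
  h <- min(hf, hb)
  crop <- function(img, off) {
    if (length(dim(img)) == 3) img[off + seq_len(h), , , drop = FALSE]
    else img[off + seq_len(h), , drop = FALSE]
  }
  if (hf > h) {
    off <- rng_int(rng, hf - h + 1L) - 1L
    fim <- crop(fim, off); fmk <- crop(fmk, off)
  }
  if (hb > h) {
    off <- rng_int(rng, hb - h + 1L) - 1L
    bim <- crop(bim, off)
  }
  list(fg = structure(list(image = fim, mask = fmk, id = fg$id),
                      class = "foreground_sample"),
       bg = background_sample(bim, id = bg$id))
}

# Resize to width W then centre-crop/pad vertically to H (donor conforming).
conform_image <- function(img, H, W, nearest = FALSE) {
  d <- dim(img)
  H2 <- max(8L, as.integer(round(d[1] * W / d[2])))
  out <- resize_image(img, H2, W, nearest = nearest)
  if (length(d) == 3 || length(dim(out)) == 3) {
    if (H2 == H) return(out)
    if (H2 > H) { y0 <- (H2 - H) %/% 2L; return(out[y0 + seq_len(H), , , drop = FALSE]) }
    pad <- array(0, c(H, W, 3)); y0 <- (H - H2) %/% 2L
    pad[y0 + seq_len(H2), , ] <- out
    return(pad)
  }
  if (H2 == H) return(out)
  if (H2 > H) { y0 <- (H2 - H) %/% 2L; return(out[y0 + seq_len(H), , drop = FALSE]) }
  pad <- matrix(0, H, W); y0 <- (H - H2) %/% 2L
  pad[y0 + seq_len(H2), ] <- out
  pad
}
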