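# Augmentation stack: identity limits, geometric/mask consistency, label
# safety of photometric ops, distractors, padding, standardization.

test_that("zero-probability configs are identities everywhere", {
  p <- test_pair(seed = 61)
  cfg <- no_augment_config()
  fga <- augment_foreground(p$fg, cfg, make_rng(1, "a"))
  expect_identical(fga$image, p$fg$image)
  expect_identical(fga$mask, p$fg$mask)
  bga <- augment_background(p$bg, cfg, make_rng(1, "b"))
  expect_identical(bga$image, p$bg$image)
  expect_identical(augment_blended(p$bg$image, cfg, make_rng(1, "c")),
                   p$bg$image)
  expect_identical(add_endoscopic_padding(p$bg, cfg, make_rng(1, "d"))$image,
                   p$bg$image)
  nod <- add_flying_distractors(p$bg, list(p$bg), p$fg,
                                function(f, b) blend_trivial(f, b),
                                cfg, make_rng(1, "e"))
  expect_identical(nod$image, p$bg$image)
})

test_that("flips and 90-degree rotations are exact group operations", {
  p <- test_pair(seed = 62)
  img <- p$bg$image
  expect_identical(chromablend:::flip_horizontal(
    chromablend:::flip_horizontal(img)), img)
  expect_identical(chromablend:::flip_vertical(
    chromablend:::flip_vertical(img)), img)
  expect_identical(chromablend:::rotate90(img, 4), img)
  expect_identical(chromablend:::rotate90(chromablend:::rotate90(img, 1), 3),
                   img)
  # flips commute with mask extraction: transform(mask) == mask(transform)
  m <- p$fg$mask
  expect_identical(chromablend:::flip_horizontal(m) ,
                   chromablend:::flip_horizontal(p$fg$mask))
})

test_that("brightness jitter is invertible before clipping", {
  img <- array(0.5, c(16, 16, 3))
  up <- chromablend:::clip01(img + 0.1)
  down <- chromablend:::clip01(up - 0.1)
  expect_lt(max(abs(down - img)), 1 / 255)
})

test_that("droplets change no pixel outside the tool mask", {
  cfg <- augment_config(p_flip_h = 0, p_flip_v = 0, p_zoom = 0, p_rotate = 0,
                        p_shift = 0, p_droplets = 1, p_brightness = 0)
  for (s in 1:20) {
    fg <- make_foreground_fixture(fixture_spec(n_tools = 1L + (s - 1L) %% 3L,
                                               seed = 600 + s))
    out <- augment_foreground(fg, cfg, make_rng(s, "drop"))
    off <- chromablend:::mask3(1 - fg$mask) == 1
    expect_identical(out$image[off], fg$image[off])
    expect_identical(out$mask, fg$mask)
  }
})

test_that("geometric foreground augmentation keeps tools border-connected", {
  cfg <- augment_config(p_droplets = 0, p_brightness = 0)
  ok <- 0L
  n_changed <- 0L
  for (s in 1:100) {
    fg <- make_foreground_fixture(fixture_spec(n_tools = 1L + (s - 1L) %% 3L,
                                               seed = 700 + s))
    out <- augment_foreground(fg, cfg, make_rng(s, "geo"))
    lab <- label_components(out$mask)
    border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    if (sum(out$mask) > 0 && all(seq_len(max(lab)) %in% border)) ok <- ok + 1L
    if (!identical(out$mask, fg$mask)) n_changed <- n_changed + 1L
  }
  expect_equal(ok, 100L)        # invariant holds on 100% of draws
  expect_gt(n_changed, 50L)     # and the stack is actually transforming
})

test_that("interpolating transforms keep image and mask co-registered", {
  cfg <- augment_config(p_flip_h = 0, p_flip_v = 0, p_zoom = 1, p_rotate = 1,
                        p_shift = 0, p_droplets = 0, p_brightness = 0,
                        rotation_range = c(-30, 30), zoom_range = c(0.85, 1.15))
  for (s in 1:10) {
    fg <- make_foreground_fixture(fixture_spec(n_tools = 1, seed = 800 + s))
    out <- augment_foreground(fg, cfg, make_rng(s, "interp"))
    # the bright tool pixels should coincide with the transformed mask:
    # segment the augmented image by colour (tool is gray: low saturation)
    hsv <- chromablend:::rgb_to_hsv_arr(out$image)
    toolish <- (hsv$s < 0.22) * 1
    if (sum(out$mask) == 0) next
    expect_gte(oracle_iou(toolish * out$mask, out$mask), 0.8)
  }
})

test_that("background rot90 composes to identity and stays valid", {
  bg <- make_background_fixture(fixture_spec(seed = 63))
  cfg <- augment_config(p_flip_h = 0, p_flip_v = 0, p_rot90 = 1,
                        p_brightness = 0)
  out <- augment_background(bg, cfg, make_rng(4, "r"))
  expect_s3_class(out, "background_sample")
  expect_identical(dim(out$image), dim(bg$image))
})

test_that("flying distractors take texture from donors and leave labels alone", {
  p <- test_pair(seed = 64)
  donor <- make_background_fixture(fixture_spec(seed = 6400))
  cfg <- augment_config(distractor_count = c(1, 1))
  rng <- make_rng(9, "dis")
  out <- add_flying_distractors(p$bg, list(donor), p$fg,
                                function(f, b) blend_trivial(f, b), cfg, rng)
  diff <- which(out$image != p$bg$image)
  expect_gt(length(diff), 0)
  # with trivial blending the changed pixels equal the donor texture
  donor_conf <- chromablend:::conform_image(donor$image, 96, 96)
  expect_identical(out$image[diff], donor_conf[diff])
  # label of a composite is untouched by distractors on the background
  comp_clean <- blend_trivial(p$fg, p$bg)
  comp_dist <- blend_trivial(p$fg, out)
  expect_identical(comp_clean$label, comp_dist$label)
  expect_error(add_flying_distractors(p$bg, list(), p$fg,
                                      function(f, b) blend_trivial(f, b),
                                      cfg, rng),
               "empty")
})

test_that("endoscopic padding blackens the border and spares the interior", {
  bg <- make_background_fixture(fixture_spec(seed = 65))
  cfg <- augment_config(padding_prob = 1, padding_noise_sigma = 0.02)
  rng <- make_rng(11, "pad")
  reg <- chromablend:::draw_padding_region(c(96, 96), cfg, rng, "circular")
  out <- chromablend:::apply_padding(bg$image, reg, cfg, rng)
  corners <- rbind(c(1, 1), c(1, 96), c(96, 1), c(96, 96))
  for (i in 1:4)
    expect_lte(max(out[corners[i, 1], corners[i, 2], ]), 3 * 0.02)
  # rectangular frame: interior window untouched
  for (s in 1:10) {
    rngs <- make_rng(s, "padrect")
    regs <- chromablend:::draw_padding_region(c(96, 96), cfg, rngs,
                                              "rectangular")
    w <- sum(regs[, 50]) / 2
    outr <- chromablend:::apply_padding(bg$image, regs, cfg, rngs)
    inner <- (w + 1):(96 - w)
    expect_identical(outr[inner, inner, ], bg$image[inner, inner, ])
  }
})

test_that("cutout changes exactly its patch and photometrics spare labels", {
  p <- test_pair(seed = 66)
  img <- blend_trivial(p$fg, p$bg)$image
  cfg <- augment_config(cutout_count = c(1, 1), cutout_size = c(16, 16))
  out <- chromablend:::op_cutout(img, cfg, make_rng(2, "cut"))
  changed <- which(apply(out != img, c(1, 2), any))
  expect_equal(length(changed), 256)
  expect_true(all(out[chromablend:::mask3(
    matrix(seq_len(96 * 96) %in% changed, 96, 96) * 1) == 1] == 0))
})

test_that("jpeg round trip at quality 100 is near-lossless on gray content", {
  rng <- make_rng(3, "jpg")
  g <- matrix(rng_runif(rng, 48 * 48), 48)
  img <- array(rep(g, 3), c(48, 48, 3))
  out <- chromablend:::jpeg_roundtrip(img, 1.0)
  expect_lte(max(abs(out - img)), 2 / 255)
})

test_that("standardize_pair enforces width, aspect ratio and equal heights", {
  rngm <- make_rng(8, "mk")
  big_fg_img <- chromablend:::resize_image(
    make_foreground_fixture(fixture_spec(seed = 67))$image, 960, 1280)
  big_fg_mask <- (chromablend:::resize_image(
    make_foreground_fixture(fixture_spec(seed = 67))$mask, 960, 1280,
    nearest = TRUE) >= 0.5) * 1
  fg <- foreground_sample(big_fg_img, big_fg_mask, check = FALSE)
  bg <- background_sample(chromablend:::resize_image(
    make_background_fixture(fixture_spec(seed = 68))$image, 360, 640))
  std <- standardize_pair(fg, bg, 640, make_rng(1, "std"))
  expect_equal(dim(std$fg$image)[2], 640)
  expect_equal(dim(std$bg$image)[2], 640)
  expect_equal(dim(std$fg$image)[1], dim(std$bg$image)[1])
  expect_equal(dim(std$fg$image)[1], 360)  # min(480, 360) after aspect resize
  expect_identical(dim(std$fg$mask), dim(std$fg$image)[1:2])
  expect_true(all(std$fg$mask %in% c(0, 1)))
})
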