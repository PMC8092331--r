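# The blending basis: trivial copy-paste, Gaussian feathering, Laplacian
# pyramid blending, and the properties shared by all modes.

test_that("trivial blending selects per pixel and handles degenerate masks", {
  p <- test_pair(seed = 41)
  out <- blend_trivial(p$fg, p$bg)
  m3 <- chromablend:::mask3(p$fg$mask)
  expect_identical(out$image, p$fg$image * m3 + p$bg$image * (1 - m3))
  expect_identical(out$label, p$fg$mask)

  ones <- structure(list(image = p$fg$image, mask = matrix(1, 96, 96),
                         id = "x"), class = "foreground_sample")
  expect_identical(blend_trivial(ones, p$bg)$image, p$fg$image)
  zeros <- structure(list(image = p$fg$image, mask = matrix(0, 96, 96),
                          id = "x"), class = "foreground_sample")
  expect_identical(blend_trivial(zeros, p$bg)$image, p$bg$image)

  # checkerboard against the elementwise oracle
  cb <- (outer(1:96, 1:96, "+") %% 2) * 1
  chk <- structure(list(image = p$fg$image, mask = cb, id = "x"),
                   class = "foreground_sample")
  got <- blend_trivial(chk, p$bg)$image
  for (c in 1:3) {
    want <- ifelse(cb == 1, p$fg$image[, , c], p$bg$image[, , c])
    expect_identical(got[, , c], want)
  }

  small <- background_sample(array(0.5, c(48, 48, 3)))
  expect_error(blend_trivial(p$fg, small), "sizes differ")
})

test_that("gaussian feathering matches the erode-blur-mix oracle bit for bit", {
  p <- test_pair(seed = 42, size = 64)
  spec <- blend_spec("gaussian_feather")
  got <- blend_gaussian_feather(p$fg, p$bg, spec)
  m <- chromablend:::conv_sep(
    chromablend:::erode_mask(p$fg$mask, chromablend:::box_brush(3)),
    chromablend:::gaussian_kernel(5))
  for (c in 1:3)
    expect_identical(got$image[, , c],
                     chromablend:::clip01(m * p$fg$image[, , c] +
                                            (1 - m) * p$bg$image[, , c]))
  expect_identical(got$label, p$fg$mask)
  # the label is the binary mask, not the soft one
  expect_true(all(got$label %in% c(0, 1)))
})

test_that("feathering kernels agree with naive dense oracles", {
  rng <- make_rng(5, "feather")
  m <- random_mask(24, 24, 0.5, rng)
  expect_identical(chromablend:::erode_mask(m, chromablend:::box_brush(3)),
                   oracle_erode_box(m, 3))
  blurred <- chromablend:::conv_sep(m, chromablend:::gaussian_kernel(5))
  expect_lt(max(abs(blurred - oracle_gauss_blur(m, 5))), 1e-12)
})

test_that("an all-ones mask makes feathering return the foreground exactly", {
  p <- test_pair(seed = 43, size = 64)
  ones <- structure(list(image = p$fg$image, mask = matrix(1, 64, 64),
                         id = "x"), class = "foreground_sample")
  out <- blend_gaussian_feather(ones, p$bg)
  expect_lt(max(abs(out$image - p$fg$image)), 1e-12)
})

test_that("feathering formula arithmetic: m = 0.25 mixes 1 and 0 to 0.25", {
  # direct check of the mixing arithmetic the soft mask feeds into
  m <- 0.25
  expect_equal(m * 1.0 + (1 - m) * 0.0, 0.25)
  # and through the code path: constant images under any soft mask
  fg <- structure(list(image = array(1, c(16, 16, 3)),
                       mask = {
                         mm <- matrix(0, 16, 16); mm[1:8, ] <- 1; mm
                       }, id = "x"), class = "foreground_sample")
  bg <- background_sample(array(0, c(16, 16, 3)))
  out <- blend_gaussian_feather(fg, bg)
  soft <- chromablend:::conv_sep(
    chromablend:::erode_mask(fg$mask, chromablend:::box_brush(3)),
    chromablend:::gaussian_kernel(5))
  expect_equal(out$image[, , 1], soft, tolerance = 1e-12)
})

test_that("feathered pixels far from any mask edge are exactly fg or bg", {
  rng <- make_rng(6, "far")
  for (trial in 1:5) {
    p <- test_pair(seed = 500 + trial, size = 64)
    out <- blend_gaussian_feather(p$fg, p$bg)
    d <- boundary_distance(p$fg$mask)
    far <- d >= 3 + 5  # k_e + k_b
    fgsel <- chromablend:::mask3((far & p$fg$mask == 1) * 1) == 1
    bgsel <- chromablend:::mask3((far & p$fg$mask == 0) * 1) == 1
    if (any(fgsel))
      expect_lt(max(abs(out$image[fgsel] - p$fg$image[fgsel])), 1e-9)
    if (any(bgsel))
      expect_lt(max(abs(out$image[bgsel] - p$bg$image[bgsel])), 1e-9)
  }
})

test_that("laplacian blending reconstructs its input in degenerate cases", {
  p <- test_pair(seed = 44, size = 96)
  # x_f = x_b: pyramid reconstruction identity
  same_bg <- background_sample(p$fg$image, id = "same")
  out <- blend_laplacian(p$fg, same_bg)
  expect_lt(max(abs(out$image - p$fg$image)), 2 / 255)
  # all-ones mask: weights degenerate to the foreground
  ones <- structure(list(image = p$fg$image, mask = matrix(1, 96, 96),
                         id = "x"), class = "foreground_sample")
  out2 <- blend_laplacian(ones, p$bg)
  expect_lt(max(abs(out2$image - p$fg$image)), 2 / 255)
  expect_identical(out2$label, ones$mask)
})

test_that("laplacian blending widens a hard seam monotonically", {
  H <- 64; W <- 64
  fg_img <- array(1, c(H, W, 3))
  bg_img <- array(0, c(H, W, 3))
  m <- matrix(0, H, W); m[, 1:(W / 2)] <- 1
  fg <- structure(list(image = fg_img, mask = m, id = "x"),
                  class = "foreground_sample")
  bg <- background_sample(bg_img)
  lap <- blend_laplacian(fg, bg)$image
  profile <- lap[H / 2, , 1]
  expect_true(all(diff(profile) <= 1e-9))            # monotone across the seam
  transition <- sum(profile > 0.05 & profile < 0.95)
  expect_gt(transition, 1)                           # wider than copy-paste
  triv <- blend_trivial(fg, bg)$image[H / 2, , 1]
  expect_equal(sum(triv > 0.05 & triv < 0.95), 0)
})

test_that("labels are bit-identical across all blend modes", {
  p <- test_pair(seed = 45)
  for (spec in default_basis()) {
    out <- blend_apply(p$fg, p$bg, spec)
    expect_identical(out$label, p$fg$mask)
    expect_true(min(out$image) >= 0 && max(out$image) <= 1)
  }
})

test_that("modes agree away from the mask boundary (exact or decaying)", {
  p <- test_pair(seed = 46, n_tools = 1, size = 128)
  b1 <- blend_trivial(p$fg, p$bg)$image
  b2 <- blend_gaussian_feather(p$fg, p$bg)$image
  b3 <- blend_laplacian(p$fg, p$bg)$image
  d <- boundary_distance(p$fg$mask)
  far <- chromablend:::mask3((d >= 8) * 1) == 1       # k_e + k_b
  expect_lt(max(abs(b1[far] - b2[far])), 1e-9)
  # pyramid influence decays over ~4 * 2^L rather than vanishing at 2^L
  far32 <- chromablend:::mask3((d > 32) * 1) == 1
  expect_gt(sum(far32), 0)
  expect_lt(max(abs(b1[far32] - b3[far32])), 0.02)
})

test_that("blend specs validate kernels and pyramid depth", {
  expect_error(blend_spec("gaussian_feather", erosion_kernel = 4), "odd")
  expect_error(blend_spec("laplacian", pyramid_levels = 0), "pyramid")
  small <- test_pair(seed = 47, size = 64)
  deep <- blend_spec("laplacian", pyramid_levels = 7)  # 2^7 > 64
  expect_error(blend_laplacian(small$fg, small$bg, deep), "pyramid_levels")
})
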