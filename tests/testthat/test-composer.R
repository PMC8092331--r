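# Sampling core: Dirichlet weights, mix-blend, multi-blend, the on-the-fly
# stream and the precomputed dataset.

test_that("dirichlet draws live on the open simplex with correct moments", {
  expect_identical(draw_mix_weights(5)$lambda, 1)  # M = 1 degenerate simplex
  rng <- make_rng(31, "lam")
  L <- t(replicate(10000, draw_mix_weights(c(1, 1, 1), rng)$lambda))
  expect_true(all(L > 0))
  expect_true(all(abs(rowSums(L) - 1) < 1e-9))
  se_mean <- sqrt(1 / 18) / sqrt(10000)
  expect_true(all(abs(colMeans(L) - 1 / 3) < 3 * se_mean))
  se_var <- stats::var(L[, 1]) * sqrt(2 / (10000 - 1))
  expect_lt(abs(stats::var(L[, 1]) - 1 / 18), 3 * se_var)
  expect_error(draw_mix_weights(c(1, 0, 1)), "positive")
})

test_that("near-zero alpha collapses draws onto single basis functions", {
  rng <- make_rng(32, "corner")
  mx <- replicate(10000, max(draw_mix_weights(c(0.001, 0.001, 0.001),
                                              rng)$lambda))
  expect_gte(mean(mx > 0.99), 0.99)
})

test_that("mix_blend is the convex combination of the basis blends", {
  p <- test_pair(seed = 71)
  basis <- default_basis()
  blends <- lapply(basis, function(sp) blend_apply(p$fg, p$bg, sp))
  w <- mix_weights(c(0.5, 0.25, 0.25))
  out <- mix_blend(p$fg, p$bg, basis, w)
  manual <- 0.5 * blends[[1]]$image + 0.25 * blends[[2]]$image +
    0.25 * blends[[3]]$image
  expect_identical(out$image, chromablend:::clip01(manual))
  # spot arithmetic: basis values (0.2, 0.6, 0.6) under these weights -> 0.4
  expect_equal(0.5 * 0.2 + 0.25 * 0.6 + 0.25 * 0.6, 0.4)
  # convex hull property, pre-clipping
  lo <- pmin(blends[[1]]$image, blends[[2]]$image, blends[[3]]$image)
  hi <- pmax(blends[[1]]$image, blends[[2]]$image, blends[[3]]$image)
  expect_true(all(manual >= lo - 1e-12 & manual <= hi + 1e-12))
  expect_identical(out$label, p$fg$mask)
})

test_that("mix_blend approaches a pure basis blend in the corner limit", {
  p <- test_pair(seed = 72)
  basis <- default_basis()
  eps <- 1e-6
  w <- mix_weights(c(1 - 2 * eps, eps, eps))
  out <- mix_blend(p$fg, p$bg, basis, w)
  expect_lt(max(abs(out$image - blend_trivial(p$fg, p$bg)$image)), 3e-6)
  # where all basis functions agree the output is independent of lambda:
  # blending an image with itself makes every basis the identity
  same <- background_sample(p$fg$image, id = "same")
  o_a <- mix_blend(p$fg, same, basis, mix_weights(c(0.2, 0.3, 0.5)))
  o_b <- mix_blend(p$fg, same, basis, mix_weights(c(0.98, 0.01, 0.01)))
  expect_lt(max(abs(o_a$image - o_b$image)), 1e-9)
})

test_that("multi_blend enumerates one composite per basis function", {
  p <- test_pair(seed = 73)
  outs <- multi_blend(p$fg, p$bg)
  expect_length(outs, 3)
  expect_identical(vapply(outs, function(o) o$provenance$mode, character(1)),
                   c("trivial", "gaussian_feather", "laplacian"))
  for (o in outs) expect_identical(o$label, p$fg$mask)
  # M = 1 basis degenerates to the single blend
  one <- multi_blend(p$fg, p$bg, default_basis()[1])
  expect_identical(one[[1]]$image, blend_trivial(p$fg, p$bg)$image)
})

test_that("labels are invariant across modes and lambda draws", {
  p <- test_pair(seed = 74)
  basis <- default_basis()
  labels <- lapply(multi_blend(p$fg, p$bg, basis), `[[`, "label")
  rng <- make_rng(74, "lam")
  for (i in 1:10) {
    w <- draw_mix_weights(c(1, 1, 1), rng)
    labels[[length(labels) + 1L]] <- mix_blend(p$fg, p$bg, basis, w)$label
  }
  for (l in labels) expect_identical(l, p$fg$mask)
})

test_that("the sample stream is deterministic and covers all pairs", {
  fgs <- lapply(1:4, function(s)
    make_foreground_fixture(fixture_spec(n_tools = 1L + (s - 1L) %% 3L,
                                         seed = s)))
  bgs <- lapply(1:5, function(s)
    make_background_fixture(fixture_spec(seed = 40 + s)))
  cfg <- default_config(list(standard_width = 96, seed = 17))
  a <- sample_stream(fgs, bgs, cfg)
  b <- sample_stream(fgs, bgs, cfg)
  sa <- replicate(10, a(), simplify = FALSE)
  sb <- replicate(10, b(), simplify = FALSE)
  for (i in 1:10) {
    expect_identical(sa[[i]]$image, sb[[i]]$image)
    expect_identical(sa[[i]]$label, sb[[i]]$label)
    expect_identical(sa[[i]]$provenance$lambda, sb[[i]]$provenance$lambda)
  }
  # pair coverage and lambda distinctness, without the augmentation cost
  st <- sample_stream(fgs, bgs, cfg, augment = FALSE)
  pairs <- character(0); lambdas <- list()
  for (k in 1:1000) {
    s <- st()
    pairs <- c(pairs, paste(s$provenance$fg_id, s$provenance$bg_id))
    lambdas[[k]] <- s$provenance$lambda
  }
  expect_equal(length(unique(pairs)), 20)  # every (i, j) visited
  expect_equal(anyDuplicated(do.call(rbind, lambdas)), 0)
})

test_that("precompute writes M basis images per sample and a loader remixes", {
  fgs <- lapply(1:2, function(s)
    make_foreground_fixture(fixture_spec(n_tools = 1, seed = 90 + s)))
  bgs <- lapply(1:2, function(s)
    make_background_fixture(fixture_spec(seed = 95 + s)))
  cfg <- default_config(list(standard_width = 96, seed = 23))
  out <- withr::local_tempdir()
  man <- precompute_dataset(fgs, bgs, 4, cfg, out, augment = FALSE)
  expect_length(man$records, 4)
  pngs <- list.files(out, pattern = "\\.png$")
  expect_equal(sum(grepl("_mask", pngs)), 4)
  expect_equal(sum(!grepl("_mask", pngs)), 12)  # 4 samples x M = 3
  # the near-corner lambda reproduces the stored trivial image
  rec <- man$records[[1]]
  eps <- 1e-6
  loaded <- load_precomputed(out, rec,
                             mix_weights(c(1 - 2 * eps, eps, eps)))
  stored <- read_image(file.path(out, sprintf("%s_trivial.png", rec$id)))
  expect_lte(max(abs(loaded$image - stored)), 1 / 255)
  # rerun with the same seed: identical manifest
  out2 <- withr::local_tempdir()
  man2 <- precompute_dataset(fgs, bgs, 4, cfg, out2, augment = FALSE)
  expect_identical(man, man2)
  f1 <- list.files(out, pattern = "png$", full.names = TRUE)
  f2 <- list.files(out2, pattern = "png$", full.names = TRUE)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("stream and blend contracts reject degenerate inputs", {
  p <- test_pair(seed = 75)
  expect_error(sample_stream(list(), list(p$bg)), "nonempty")
  expect_error(mix_weights(c(0.5, 0.5, 0.1)), "sum to 1")
  expect_error(mix_blend(p$fg, p$bg, default_basis(),
                         mix_weights(c(0.5, 0.5))), "differ")
})
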