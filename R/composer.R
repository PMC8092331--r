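# The sampling core. multi-blend enumerates one composite per basis
# function for each foreground-background pair; mix-blend emits, per visit
# of a pair, a single composite equal to a Dirichlet-weighted convex
# combination of all basis blends. The label never depends on the blend.

#' Dirichlet mix weights
#'
#' @param lambda Numeric vector on the open simplex: strictly positive,
#'   summing to 1 (within 1e-9).
#' @param alpha The concentration vector that generated it (strictly
#'   positive reals, one per blending function).
#' @return List of class `"mix_weights"`.
#' @export
mix_weights <- function(lambda, alpha = rep(1, length(lambda))) {
  if (length(lambda) != length(alpha)) stopf("lambda and alpha lengths differ")
  if (any(lambda <= 0)) stopf("all mix weights must be strictly positive")
  if (abs(sum(lambda) - 1) > 1e-9) stopf("mix weights must sum to 1")
  if (any(alpha <= 0)) stopf("all alpha components must be strictly positive")
  structure(list(lambda = lambda, alpha = alpha), class = "mix_weights")
}

#' Draw Dirichlet mix weights
#'
#' Samples `lambda ~ Dir(alpha)` via normalized Gamma draws, computed on
#' the log scale with the small-shape boost `G_a = G_{a+1} * U^{1/a}` so
#' that near-degenerate concentrations (e.g. `alpha = 0.001`, the corner
#' regime in which the mix collapses onto single basis functions) do not
#' underflow. Components are floored at 1e-15 and renormalized to keep
#' strict positivity.
#'
#' @param alpha Vector of strictly positive reals, one per blending
#'   function.
#' @param rng A [make_rng()] handle.
#' @return A [mix_weights()] object.
#' @export
draw_mix_weights <- function(alpha, rng = make_rng(0, "lambda")) {
  if (length(alpha) < 1 || any(alpha <= 0))
    stopf("alpha must be a vector of strictly positive reals")
  M <- length(alpha)
  if (M == 1) return(mix_weights(1, alpha))
  g_boost <- rng_rgamma(rng, M, shape = alpha + 1)
  u <- rng_runif(rng, M)
  logg <- log(g_boost) + log(u) / alpha
  lambda <- exp(logg - max(logg))
  lambda <- pmax(lambda / sum(lambda), 1e-15)
  lambda <- lambda / sum(lambda)
  mix_weights(lambda, alpha)
}

#' Mix-blend: Dirichlet-weighted convex combination of basis blends
#'
#' Computes all `M` basis blends of the pair and returns their per-pixel
#' convex combination `sum_m lambda_m phi_m(x_f, x_b)`, clipped to `[0,1]`.
#' The label is the foreground mask, independent of `lambda`.
#'
#' @param fg A [foreground_sample()].
#' @param bg A [background_sample()] of the same size.
#' @param basis Ordered list of [blend_spec()]s (see [default_basis()]).
#' @param weights A [mix_weights()] with `length(lambda) == length(basis)`.
#' @param provenance Extra provenance fields carried into the result.
#' @return A [composite_sample()].
#' @export
mix_blend <- function(fg, bg, basis = default_basis(),
                      weights = mix_weights(rep(1, length(basis)) / length(basis)),
                      provenance = list()) {
  if (length(basis) != length(weights$lambda))
    stopf("basis size (%d) and lambda size (%d) differ",
          length(basis), length(weights$lambda))
  blends <- lapply(basis, function(sp) blend_apply(fg, bg, sp))
  img <- Reduce(`+`, Map(function(b, l) l * b$image,
                         blends, as.list(weights$lambda)))
  composite_sample(clip01(img), fg$mask,
                   c(list(fg_id = fg$id, bg_id = bg$id,
                          lambda = weights$lambda), provenance))
}

#' Multi-blend: one composite per basis function
#'
#' @inheritParams mix_blend
#' @return List of `length(basis)` [composite_sample()]s with identical
#'   labels and provenance differing only in `mode`.
#' @export
multi_blend <- function(fg, bg, basis = default_basis(), provenance = list()) {
  lapply(basis, function(sp) {
    b <- blend_apply(fg, bg, sp)
    composite_sample(b$image, b$label,
                     c(list(fg_id = fg$id, bg_id = bg$id, mode = sp$mode),
                       provenance))
  })
}

#' On-the-fly mix-blend sample stream
#'
#' The training-side generator: each draw picks a foreground-background
#' pair uniformly at random, augments both (flying distractors and
#' endoscopic padding are applied to the background, the distractors
#' blended with the *same* lambda-weighted procedure as the tools),
#' standardizes the pair, computes all basis blends, draws a fresh
#' `lambda ~ Dir(alpha)` and emits the weighted sum with its label. The
#' whole stream is determined by `cfg$seed`.
#'
#' @param fgs Nonempty list of [foreground_sample()]s.
#' @param bgs Nonempty list of [background_sample()]s.
#' @param cfg A [default_config()] pipeline configuration.
#' @param augment Apply the augmentation stack (default `TRUE`; `FALSE`
#'   uses [no_augment_config()]).
#' @return A function; each call returns the next [composite_sample()].
#' @examples
#' fgs <- lapply(1:2, function(s) make_foreground_fixture(fixture_spec(seed = s)))
#' bgs <- lapply(1:2, function(s) make_background_fixture(fixture_spec(seed = s)))
#' nxt <- sample_stream(fgs, bgs, default_config(list(standard_width = 96)))
#' s1 <- nxt()
#' dim(s1$image)
#' @export
sample_stream <- function(fgs, bgs, cfg = default_config(), augment = TRUE) {
  if (length(fgs) == 0 || length(bgs) == 0)
    stopf("foreground and background sets must be nonempty")
  acfg <- if (augment) cfg$augment else no_augment_config()
  if (!inherits(acfg, "augment_config")) acfg <- do.call(augment_config, acfg)
  basis <- default_basis(cfg)
  streams <- list(
    pair = make_rng(cfg$seed, "pair"),
    lambda = make_rng(cfg$seed, "lambda"),
    fg = make_rng(cfg$seed, "fg-aug"),
    bg = make_rng(cfg$seed, "bg-aug"),
    distract = make_rng(cfg$seed, "distractors"),
    pad = make_rng(cfg$seed, "padding"),
    std = make_rng(cfg$seed, "standardize"),
    post = make_rng(cfg$seed, "post-aug"),
    gc = make_rng(cfg$seed, "grabcut")
  )
  draw_index <- 0L
  function() {
    draw_index <<- draw_index + 1L
    i <- rng_int(streams$pair, length(fgs))
    j <- rng_int(streams$pair, length(bgs))
    w <- draw_mix_weights(cfg$alpha, streams$lambda)
    fga <- if (augment) augment_foreground(fgs[[i]], acfg, streams$fg)
    else fgs[[i]]
    bga <- if (augment) augment_background(bgs[[j]], acfg, streams$bg)
    else bgs[[j]]
    std <- standardize_pair(fga, bga, cfg$standard_width, streams$std)
    if (augment) {
      mix_fun <- function(f, b) {
        r <- mix_blend(f, b, basis, w)
        blend_result(r$image, r$label)
      }
      shape_idx <- rng_int(streams$distract, length(fgs))
      std$bg <- add_flying_distractors(std$bg, bgs, fgs[[shape_idx]],
                                       mix_fun, acfg, streams$distract)
      std$bg <- add_endoscopic_padding(std$bg, acfg, streams$pad)
    }
    samp <- mix_blend(std$fg, std$bg, basis, w,
                      provenance = list(draw_index = draw_index,
                                        seed = cfg$seed))
    if (augment) {
      samp$image <- augment_blended(samp$image, acfg, streams$post)
      samp$image <- clip01(samp$image)
    }
    samp
  }
}

#' Precompute a dataset of basis blends
#'
#' For each sample, the augmented standardized pair is blended once per
#' basis function and all `M` images are stored together with one label
#' mask; the Dirichlet weighting is deferred to load time
#' ([load_precomputed()]), so a fixed dataset on disk supports unlimited
#' lambda resampling. Flying distractors are applied per basis mode so
#' that every stored image is internally consistent with its blending
#' function.
#'
#' @inheritParams sample_stream
#' @param n_samples Number of samples to precompute.
#' @param out_dir Output directory (created if missing).
#' @return The [dataset_manifest()], also written to
#'   `file.path(out_dir, "manifest.json")`.
#' @export
precompute_dataset <- function(fgs, bgs, n_samples, cfg = default_config(),
                               out_dir = tempfile("precomp"),
                               augment = TRUE) {
  if (length(fgs) == 0 || length(bgs) == 0)
    stopf("foreground and background sets must be nonempty")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  acfg <- if (augment) cfg$augment else no_augment_config()
  if (!inherits(acfg, "augment_config")) acfg <- do.call(augment_config, acfg)
  basis <- default_basis(cfg)
  streams <- list(
    pair = make_rng(cfg$seed, "pair"),
    fg = make_rng(cfg$seed, "fg-aug"),
    bg = make_rng(cfg$seed, "bg-aug"),
    distract = make_rng(cfg$seed, "distractors"),
    pad = make_rng(cfg$seed, "padding"),
    std = make_rng(cfg$seed, "standardize")
  )
  records <- vector("list", n_samples)
  for (s in seq_len(n_samples)) {
    i <- rng_int(streams$pair, length(fgs))
    j <- rng_int(streams$pair, length(bgs))
    fga <- if (augment) augment_foreground(fgs[[i]], acfg, streams$fg)
    else fgs[[i]]
    bga <- if (augment) augment_background(bgs[[j]], acfg, streams$bg)
    else bgs[[j]]
    std <- standardize_pair(fga, bga, cfg$standard_width, streams$std)
    bg_base <- if (augment)
      add_endoscopic_padding(std$bg, acfg, streams$pad) else std$bg
    shape_idx <- if (augment) rng_int(streams$distract, length(fgs)) else 1L
    id <- sprintf("sample-%05d", s)
    modes <- character(length(basis))
    for (m in seq_along(basis)) {
      sp <- basis[[m]]
      bg_m <- if (augment)
        add_flying_distractors(bg_base, bgs, fgs[[shape_idx]],
                               function(f, b) blend_apply(f, b, sp),
                               acfg, make_rng(cfg$seed,
                                              sprintf("distract-%d-%s", s, sp$mode)))
      else bg_base
      res <- blend_apply(std$fg, bg_m, sp)
      write_image(res$image, file.path(out_dir,
                                       sprintf("%s_%s.png", id, sp$mode)))
      modes[m] <- sp$mode
    }
    write_mask(std$fg$mask, file.path(out_dir, sprintf("%s_mask.png", id)))
    records[[s]] <- list(id = id, fg_id = fgs[[i]]$id, bg_id = bgs[[j]]$id,
                         modes = modes, seed = cfg$seed)
  }
  manifest <- dataset_manifest(
    fg_ids = unique(vapply(fgs, function(f) f$id, character(1))),
    bg_ids = unique(vapply(bgs, function(b) b$id, character(1))),
    records = records
  )
  write_manifest(manifest, file.path(out_dir, "manifest.json"))
  manifest
}

#' Load a precomputed sample, applying the Dirichlet weighted sum
#'
#' @param dir The precompute output directory.
#' @param record One record from the manifest (or a sample id string).
#' @param weights A [mix_weights()]; defaults to a fresh draw from
#'   `Dir(alpha)`.
#' @param alpha Concentration used when `weights` is `NULL`.
#' @param rng RNG handle for the default draw.
#' @return A [composite_sample()].
#' @export
load_precomputed <- function(dir, record, weights = NULL,
                             alpha = c(1, 1, 1),
                             rng = make_rng(0, "lambda")) {
  if (is.character(record)) {
    manifest <- read_manifest(file.path(dir, "manifest.json"))
    ids <- vapply(manifest$records, function(r) r$id, character(1))
    record <- manifest$records[[match(record, ids)]]
  }
  if (is.null(weights)) weights <- draw_mix_weights(alpha, rng)
  imgs <- lapply(record$modes, function(m)
    read_image(file.path(dir, sprintf("%s_%s.png", record$id, m))))
  if (length(imgs) != length(weights$lambda))
    stopf("stored basis size and lambda size differ")
  img <- Reduce(`+`, Map(function(im, l) l * im, imgs,
                         as.list(weights$lambda)))
  label <- read_mask(file.path(dir, sprintf("%s_mask.png", record$id)))
  composite_sample(clip01(img), label,
                   list(fg_id = record$fg_id, bg_id = record$bg_id,
                        lambda = weights$lambda, seed = record$seed))
}
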