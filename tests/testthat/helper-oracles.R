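# Independent oracles and shared fixture builders for the test suite.
# Oracles deliberately use different algorithms from the implementation.

# 8-connected component labelling by minimum-label propagation: every
# foreground pixel starts with a unique id and repeatedly takes the minimum
# over its 8-neighbourhood until a fixed point. Independent of the
# igraph-based implementation.
oracle_label_components <- function(mask) {
  n1 <- nrow(mask); n2 <- ncol(mask)
  lab <- matrix(0, n1, n2)
  lab[mask == 1] <- seq_len(sum(mask))
  lab[mask == 0] <- Inf
  shift <- function(m, dy, dx) {
    out <- matrix(Inf, n1, n2)
    ys <- seq_len(n1) - dy; xs <- seq_len(n2) - dx
    oky <- ys >= 1 & ys <= n1; okx <- xs >= 1 & xs <= n2
    out[oky, okx] <- m[ys[oky], xs[okx]]
    out
  }
  repeat {
    new <- lab
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      new <- pmin(new, shift(lab, dy, dx))
    }
    new[mask == 0] <- Inf
    if (identical(new, lab)) break
    lab <- new
  }
  lab[mask == 0] <- 0
  out <- matrix(0L, n1, n2)
  fg <- which(mask == 1)
  out[fg] <- match(lab[fg], unique(lab[fg][order(fg)]))
  out
}

# Brute-force IoU by explicit set operations on pixel index sets.
oracle_iou <- function(pred, truth) {
  a <- which(pred == 1); b <- which(truth == 1)
  eps <- .Machine$double.eps
  (length(intersect(a, b)) + eps) / (length(union(a, b)) + eps)
}

# Naive O(n k^2) erosion: min over an explicit window with replicate border.
oracle_erode_box <- function(mask, k) {
  r <- (k - 1) %/% 2
  n1 <- nrow(mask); n2 <- ncol(mask)
  out <- mask
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    ys <- pmin(pmax(i + (-r:r), 1), n1)
    xs <- pmin(pmax(j + (-r:r), 1), n2)
    out[i, j] <- min(mask[ys, xs])
  }
  out
}

# Naive dense 2D Gaussian blur with reflect-101 border.
oracle_gauss_blur <- function(m, k) {
  sigma <- 0.3 * ((k - 1) / 2 - 1) + 0.8
  x <- seq(-(k - 1) / 2, (k - 1) / 2)
  k1 <- exp(-x^2 / (2 * sigma^2)); k1 <- k1 / sum(k1)
  ker <- outer(k1, k1)
  r <- (k - 1) %/% 2
  n1 <- nrow(m); n2 <- ncol(m)
  refl <- function(i, n) {
    i <- ifelse(i < 1, 2 - i, i)
    ifelse(i > n, 2 * n - i, i)
  }
  out <- matrix(0, n1, n2)
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    ys <- refl(i + (-r:r), n1); xs <- refl(j + (-r:r), n2)
    out[i, j] <- sum(ker * m[ys, xs])
  }
  out
}

# Small random binary mask for property tests.
random_mask <- function(n1, n2, p = 0.4, rng) {
  matrix((rng_runif(rng, n1 * n2) < p) * 1, n1, n2)
}

# Standard small fixture pair used across blend/composer tests.
test_pair <- function(seed = 1, n_tools = 2, size = 96) {
  list(fg = make_foreground_fixture(fixture_spec(n_tools = n_tools,
                                                 height = size, width = size,
                                                 seed = seed)),
       bg = make_background_fixture(fixture_spec(height = size, width = size,
                                                 seed = seed + 1000)))
}

# Chebyshev distance of every pixel to the nearest mask-boundary pixel
# (a pixel whose 3x3 window contains both classes), by multi-source BFS
# through repeated dilation.
boundary_distance <- function(mask) {
  b3 <- matrix(1, 3, 3)
  er <- chromablend:::erode_mask(mask, b3)
  di <- chromablend:::dilate_mask(mask, b3)
  known <- (di != er) * 1
  d <- ifelse(known == 1, 0, Inf)
  step <- 0
  while (any(is.infinite(d)) && step <= nrow(mask) + ncol(mask)) {
    step <- step + 1
    grown <- chromablend:::dilate_mask(known, b3)
    d[grown == 1 & is.infinite(d)] <- step
    known <- grown
  }
  d
}
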