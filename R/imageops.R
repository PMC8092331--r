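# Low-level raster operations shared across modules. Convolution and
# morphology are implemented with explicit border policies (reflect-101 for
# filters, replicate for erosion) because the blending contracts depend on
# constant fields being fixed points; geometric resampling goes through
# EBImage.

# Pad a matrix by reflect-101 (mirror without repeating the edge sample).
pad_reflect101 <- function(m, p) {
  n1 <- nrow(m); n2 <- ncol(m)
  ri <- c(rev(seq_len(p) + 1L), seq_len(n1), n1 - seq_len(p))
  ci <- c(rev(seq_len(p) + 1L), seq_len(n2), n2 - seq_len(p))
  m[clamp_idx(ri, n1), clamp_idx(ci, n2)]
}

# Separable 2D convolution of a matrix with a 1D kernel, reflect-101 border.
conv_sep <- function(m, kernel) {
  k <- length(kernel)
  if (k == 1) return(m * kernel)
  p <- (k - 1L) %/% 2L
  mp <- pad_reflect101(m, p)
  n1 <- nrow(m); n2 <- ncol(m)
  # rows
  acc <- matrix(0, n1, n2 + 2L * p)
  for (i in seq_len(k)) acc <- acc + kernel[i] * mp[(i - 1L) + seq_len(n1), ]
  # cols
  out <- matrix(0, n1, n2)
  for (i in seq_len(k)) out <- out + kernel[i] * acc[, (i - 1L) + seq_len(n2)]
  out
}

# 1D Gaussian kernel of odd size k; sigma from the conventional rule when
# not supplied: sigma = 0.3 * ((k - 1)/2 - 1) + 0.8.
gaussian_kernel <- function(k, sigma = NULL) {
  stopifnot(is_odd(k), k >= 1)
  if (is.null(sigma)) sigma <- 0.3 * ((k - 1) / 2 - 1) + 0.8
  x <- seq(-(k - 1) / 2, (k - 1) / 2)
  w <- exp(-x^2 / (2 * sigma^2))
  w / sum(w)
}

# Gaussian blur of a matrix (kernel size derived from sigma when k missing).
gauss_blur <- function(m, sigma, k = NULL) {
  if (sigma <= 0) return(m)
  if (is.null(k)) k <- 2L * ceiling(3 * sigma) + 1L
  conv_sep(m, gaussian_kernel(k, sigma))
}

blur_rgb <- function(img, sigma, k = NULL) {
  for (c in 1:3) img[, , c] <- gauss_blur(img[, , c], sigma, k)
  img
}

# Binary erosion with replicate-border semantics: min over the structuring
# element's offsets, out-of-frame samples replicate the edge (so an all-ones
# mask stays all ones). `brush` is a matrix of 0/1 with odd dimensions.
erode_mask <- function(mask, brush) {
  off <- which(brush == 1, arr.ind = TRUE)
  cy <- (nrow(brush) + 1L) / 2L; cx <- (ncol(brush) + 1L) / 2L
  n1 <- nrow(mask); n2 <- ncol(mask)
  out <- mask
  for (r in seq_len(nrow(off))) {
    dy <- off[r, 1] - cy; dx <- off[r, 2] - cx
    if (dy == 0 && dx == 0) next
    out <- pmin(out, mask[clamp_idx(seq_len(n1) + dy, n1),
                          clamp_idx(seq_len(n2) + dx, n2)])
  }
  out
}

dilate_mask <- function(mask, brush) 1 - erode_mask(1 - mask, brush)

box_brush <- function(k) matrix(1, k, k)

disc_brush <- function(radius) {
  if (radius < 1) return(matrix(1, 1, 1))
  k <- 2L * as.integer(radius) + 1L
  x <- seq_len(k) - (radius + 1)
  (outer(x^2, x^2, "+") <= radius^2) * 1
}

#' Label 8-connected components of a binary mask
#'
#' Components are numbered deterministically by the raster-scan order
#' (column-major, as stored) of their first pixel, so equal-area ties in
#' downstream sorts break reproducibly.
#'
#' @param mask H x W binary matrix.
#' @return Integer H x W matrix; 0 = background, 1..n = component labels.
#' @export
label_components <- function(mask) {
  assert_mask(mask)
  n1 <- nrow(mask); n2 <- ncol(mask)
  lab <- matrix(0L, n1, n2)
  fg <- which(mask == 1)
  if (length(fg) == 0) return(lab)
  idx <- matrix(0L, n1, n2)
  idx[fg] <- seq_along(fg)
  row <- ((fg - 1L) %% n1) + 1L
  col <- ((fg - 1L) %/% n1) + 1L
  edges <- integer(0)
  for (d in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    nr <- row + d[1]; nc <- col + d[2]
    ok <- nr >= 1L & nr <= n1 & nc <= n2
    nb <- idx[cbind(nr[ok], nc[ok])]
    keep <- nb > 0L
    edges <- c(edges, rbind(idx[fg][ok][keep], nb[keep]))
  }
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  memb <- igraph::components(g)$membership
  # renumber by first occurrence in raster order (fg indices are sorted)
  lab[fg] <- match(memb, unique(memb))
  lab
}

# ---- EBImage-backed geometric transforms on the H x W(,3) convention ----
# EBImage stores [x, y, channel]; these wrappers transpose in and out.

to_eb <- function(img) {
  if (length(dim(img)) == 3)
    EBImage::Image(aperm(img, c(2, 1, 3)), colormode = "Color")
  else EBImage::Image(t(img), colormode = "Grayscale")
}

from_eb <- function(eb, channels = 3) {
  a <- EBImage::imageData(eb)
  if (length(dim(a)) == 3) aperm(a, c(2, 1, 3)) else t(a)
}

# Resize to exact (H, W). Bilinear for images, nearest for masks.
resize_image <- function(img, H, W, nearest = FALSE) {
  eb <- to_eb(img)
  out <- EBImage::resize(eb, w = W, h = H,
                         filter = if (nearest) "none" else "bilinear")
  res <- from_eb(out)
  if (length(dim(img)) == 3) clip01(res) else res
}

# Rotate about the image centre keeping the original extent; `fill` pads.
rotate_image <- function(img, angle, fill = 0, nearest = FALSE) {
  eb <- to_eb(img)
  d <- dim(img)
  out <- EBImage::rotate(eb, angle, filter = if (nearest) "none" else "bilinear",
                         output.dim = c(d[2], d[1]), bg.col = fill)
  res <- from_eb(out)
  if (length(dim(img)) == 3) clip01(res) else res
}

# Integer pixel shift with constant fill (positive dy shifts content down).
shift_image <- function(img, dy, dx, fill = 0) {
  d <- dim(img)
  n1 <- d[1]; n2 <- d[2]
  out <- if (length(d) == 3) array(fill, d) else matrix(fill, n1, n2)
  sy <- seq_len(n1) - dy; sx <- seq_len(n2) - dx
  oky <- sy >= 1 & sy <= n1; okx <- sx >= 1 & sx <= n2
  if (any(oky) && any(okx)) {
    if (length(d) == 3) out[oky, okx, ] <- img[sy[oky], sx[okx], , drop = FALSE]
    else out[oky, okx] <- img[sy[oky], sx[okx], drop = FALSE]
  }
  out
}

flip_horizontal <- function(img) {
  if (length(dim(img)) == 3) img[, rev(seq_len(dim(img)[2])), , drop = FALSE]
  else img[, rev(seq_len(ncol(img))), drop = FALSE]
}

flip_vertical <- function(img) {
  if (length(dim(img)) == 3) img[rev(seq_len(dim(img)[1])), , , drop = FALSE]
  else img[rev(seq_len(nrow(img))), , drop = FALSE]
}

# Rotate by k * 90 degrees counter-clockwise (exact index permutation).
rotate90 <- function(img, k = 1) {
  k <- ((k %% 4) + 4) %% 4
  if (k == 0) return(img)
  rot1 <- function(m) t(m)[rev(seq_len(ncol(m))), , drop = FALSE]
  for (i in seq_len(k)) {
    if (length(dim(img)) == 3) {
      d <- dim(img)
      out <- array(0, c(d[2], d[1], 3))
      for (c in 1:3) out[, , c] <- rot1(img[, , c])
      img <- out
    } else img <- rot1(img)
  }
  img
}
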