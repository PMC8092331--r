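# Small internal helpers shared across modules.

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

is_odd <- function(k) k %% 2 == 1

#' @noRd
# Replicate a H x W matrix across 3 channels.
mask3 <- function(m) array(m, dim = c(nrow(m), ncol(m), 3L))

# Clamp integer indices into [1, n] (replicate-border addressing).
clamp_idx <- function(i, n) pmin(pmax(i, 1L), n)

# Vectorised HSV -> RGB. h in degrees (any real), s, v in [0,1].
# Returns a list(r, g, b) of the same shape as the inputs.
hsv_to_rgb <- function(h, s, v) {
  h <- (h %% 360) / 60
  i <- floor(h)
  f <- h - i
  p <- v * (1 - s)
  q <- v * (1 - s * f)
  t <- v * (1 - s * (1 - f))
  r <- g <- b <- v
  idx <- i == 0; r[idx] <- v[idx]; g[idx] <- t[idx]; b[idx] <- p[idx]
  idx <- i == 1; r[idx] <- q[idx]; g[idx] <- v[idx]; b[idx] <- p[idx]
  idx <- i == 2; r[idx] <- p[idx]; g[idx] <- v[idx]; b[idx] <- t[idx]
  idx <- i == 3; r[idx] <- p[idx]; g[idx] <- q[idx]; b[idx] <- v[idx]
  idx <- i == 4; r[idx] <- t[idx]; g[idx] <- p[idx]; b[idx] <- v[idx]
  idx <- i == 5; r[idx] <- v[idx]; g[idx] <- p[idx]; b[idx] <- q[idx]
  list(r = r, g = g, b = b)
}

# RGB array (H x W x 3, [0,1]) -> list(h_deg, s, v), each H x W.
rgb_to_hsv_arr <- function(img) {
  d <- dim(img)
  m <- rbind(as.vector(img[, , 1]), as.vector(img[, , 2]), as.vector(img[, , 3]))
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 1)
  list(
    h = matrix(hsv[1, ] * 360, d[1], d[2]),
    s = matrix(hsv[2, ], d[1], d[2]),
    v = matrix(hsv[3, ], d[1], d[2])
  )
}

# Build an H x W x 3 array from HSV fields (degrees, [0,1], [0,1]).
hsv_image <- function(h, s, v) {
  rgb <- hsv_to_rgb(h, s, v)
  out <- array(0, dim = c(nrow(h), ncol(h), 3L))
  out[, , 1] <- rgb$r
  out[, , 2] <- rgb$g
  out[, , 3] <- rgb$b
  clip01(out)
}
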