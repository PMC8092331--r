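#' Named deterministic random streams
#'
#' All stochastic operations in the package draw from named substreams
#' derived from one global seed. Each `(seed, stream_label)` pair yields an
#' independent deterministic sequence, so adding draws to one stream (e.g. a
#' new augmentation) never perturbs another. Handles carry their own state;
#' the caller's global `.Random.seed` is left untouched.
#'
#' @param seed Integer master seed.
#' @param stream_label Character label naming the substream.
#' @return An object of class `"cb_rng"` usable with the `rng_*` draw helpers.
#' @examples
#' r1 <- make_rng(7, "lambda")
#' r2 <- make_rng(7, "lambda")
#' identical(rng_runif(r1, 5), rng_runif(r2, 5))
#' @export
make_rng <- function(seed, stream_label = "main") {
  stopifnot(is.numeric(seed), length(seed) == 1, length(stream_label) == 1)
  derived <- (((as.numeric(seed) %% 2147483647) * 69621) %% 2147483647 +
                hash_string(stream_label)) %% 2147483647
  e <- new.env(parent = emptyenv())
  e$seed <- as.integer(derived)
  e$state <- NULL
  class(e) <- "cb_rng"
  e
}

# Deterministic 31-bit polynomial hash of a string (no external digest dep).
hash_string <- function(s) {
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2147483647
  h
}

#' Evaluate an expression under a named stream's RNG state
#'
#' @param rng A handle from [make_rng()].
#' @param expr Expression drawing from R's RNG.
#' @return The value of `expr`; the stream state advances.
#' @export
with_rng <- function(rng, expr) {
  stopifnot(inherits(rng, "cb_rng"))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  if (is.null(rng$state)) set.seed(rng$seed)
  else assign(".Random.seed", rng$state, envir = globalenv())
  val <- force(expr)
  rng$state <- get(".Random.seed", envir = globalenv())
  val
}

#' @rdname with_rng
#' @param n,min,max As in [stats::runif()].
#' @export
rng_runif <- function(rng, n, min = 0, max = 1) with_rng(rng, stats::runif(n, min, max))

#' @rdname with_rng
#' @param mean,sd As in [stats::rnorm()].
#' @export
rng_rnorm <- function(rng, n, mean = 0, sd = 1) with_rng(rng, stats::rnorm(n, mean, sd))

#' @rdname with_rng
#' @param shape,rate As in [stats::rgamma()].
#' @export
rng_rgamma <- function(rng, n, shape, rate = 1) with_rng(rng, stats::rgamma(n, shape, rate))

#' @rdname with_rng
#' @param lambda As in [stats::rpois()].
#' @export
rng_rpois <- function(rng, n, lambda) with_rng(rng, stats::rpois(n, lambda))

#' @rdname with_rng
#' @param k Upper bound: draws uniformly from `1:k`.
#' @export
rng_int <- function(rng, k, n = 1) with_rng(rng, sample.int(k, n, replace = TRUE))
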