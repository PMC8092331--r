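# GrabCut: iterative segmentation alternating Gaussian-mixture colour
# modelling with s-t min-cut energy minimization (Rother et al. style).
# Trimap codes follow the usual convention:
#   0 = sure background, 1 = sure foreground,
#   2 = probable background, 3 = probable foreground.
# Sure pixels are pinned with large terminal capacities and re-asserted
# after every cut, so they are never relabelled.

GC_BGD <- 0L; GC_FGD <- 1L; GC_PR_BGD <- 2L; GC_PR_FGD <- 3L

#' Run GrabCut on an image given a trimap of seed labels
#'
#' Alternates (a) fitting one Gaussian mixture per class to the currently
#' foreground/background pixels, (b) solving the resulting pixel-labelling
#' energy exactly by s-t min-cut on the 8-connected pixel graph with
#' contrast-sensitive edge weights `gamma * exp(-beta * ||z_i - z_j||^2)`.
#' Certain (sure) pixels keep their seeded class on every input.
#'
#' @param image H x W x 3 array in `[0,1]`.
#' @param trimap Integer H x W matrix over `{0,1,2,3}` (see codes above).
#' @param iterations Number of GMM-refit / min-cut rounds (default 5).
#' @param n_components Gaussian mixture components per class (default 5).
#' @param gamma Edge-contrast weight (default 50, the standard setting).
#' @param rng A [make_rng()] handle (GMM initialization uses k-means).
#' @return H x W binary matrix; 1 = foreground. Sure-seeded pixels always
#'   retain their seeded class.
#' @export
grabcut <- function(image, trimap, iterations = 5L, n_components = 5L,
                    gamma = 50, rng = make_rng(0, "grabcut")) {
  assert_image(image)
  if (!identical(dim(trimap), dim(image)[1:2]))
    stopf("trimap and image dimensions differ")
  if (!all(trimap %in% 0:3)) stopf("trimap values must be in {0,1,2,3}")
  n1 <- nrow(trimap); n2 <- ncol(trimap); N <- n1 * n2
  alpha <- trimap == GC_FGD | trimap == GC_PR_FGD
  probable <- trimap == GC_PR_BGD | trimap == GC_PR_FGD
  if (!any(probable)) return(alpha * 1)       # all pixels certain: nothing to solve
  if (!any(alpha) || all(alpha)) return(alpha * 1)  # degenerate: one class empty

  z <- cbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
             as.vector(image[, , 3]))

  # ---- n-links (8-neighbourhood), contrast-sensitive weights ----
  row <- rep(seq_len(n1), times = n2)
  col <- rep(seq_len(n2), each = n1)
  pix <- seq_len(N)
  elist <- list(); wlist <- list(); sqsum <- 0; sqn <- 0
  for (d in list(c(1L, 0L, 1), c(0L, 1L, 1), c(1L, 1L, sqrt(2)),
                 c(-1L, 1L, sqrt(2)))) {
    nr <- row + d[1]; nc <- col + d[2]
    ok <- nr >= 1L & nr <= n1 & nc <= n2
    a <- pix[ok]; b <- (nc[ok] - 1L) * n1 + nr[ok]
    sq <- rowSums((z[a, , drop = FALSE] - z[b, , drop = FALSE])^2)
    sqsum <- sqsum + sum(sq); sqn <- sqn + length(sq)
    elist[[length(elist) + 1L]] <- cbind(a, b)
    wlist[[length(wlist) + 1L]] <- list(sq = sq, dist = d[3])
  }
  beta <- if (sqsum > 0) 1 / (2 * sqsum / sqn) else 0
  nl_edges <- do.call(rbind, elist)
  nl_caps <- unlist(lapply(wlist, function(w) gamma / w$dist * exp(-beta * w$sq)))

  BIG <- 1e9
  S <- N + 1L; T <- N + 2L
  sure_fg <- which(trimap == GC_FGD)
  sure_bg <- which(trimap == GC_BGD)
  prob_idx <- which(probable)

  prev <- alpha
  for (it in seq_len(iterations)) {
    # Round 1 fits the colour models on the sure (scribble-equivalent)
    # pixels only, so unreliable probable seeds cannot poison them; later
    # rounds refit on the evolving labelling as usual.
    if (it == 1 && length(sure_fg) > 0 && length(sure_bg) > 0) {
      fgm <- fit_gmm(z[sure_fg, , drop = FALSE], n_components, rng)
      bgm <- fit_gmm(z[sure_bg, , drop = FALSE], n_components, rng)
    } else {
      fgm <- fit_gmm(z[alpha, , drop = FALSE], n_components, rng)
      bgm <- fit_gmm(z[!alpha, , drop = FALSE], n_components, rng)
    }
    if (is.null(fgm) || is.null(bgm)) break
    d_fg <- -gmm_logdens(fgm, z[prob_idx, , drop = FALSE])
    d_bg <- -gmm_logdens(bgm, z[prob_idx, , drop = FALSE])
    # t-links: cutting (p,T) pays the cost of labelling p foreground
    t_edges <- rbind(cbind(S, c(prob_idx, sure_fg, sure_bg)),
                     cbind(c(prob_idx, sure_fg, sure_bg), T))
    t_caps <- c(d_bg, rep(BIG, length(sure_fg)), rep(0, length(sure_bg)),
                d_fg, rep(0, length(sure_fg)), rep(BIG, length(sure_bg)))
    edges <- rbind(nl_edges, t_edges)
    caps <- pmin(c(nl_caps, t_caps), BIG)
    g <- igraph::make_empty_graph(n = N + 2L, directed = FALSE)
    g <- igraph::add_edges(g, t(edges))
    cut <- igraph::min_cut(g, source = S, target = T, capacity = caps,
                           value.only = FALSE)
    side <- logical(N + 2L)
    side[as.integer(cut$partition1)] <- TRUE
    fg_side <- if (side[S]) side else !side
    alpha <- fg_side[seq_len(N)]
    alpha[sure_fg] <- TRUE          # certainty preservation, by construction
    alpha[sure_bg] <- FALSE
    dim(alpha) <- c(n1, n2)
    if (identical(alpha, prev)) break
    prev <- alpha
  }
  alpha * 1
}

# Fit a K-component full-covariance Gaussian mixture by k-means hard
# assignment (the classic GrabCut fitting step). Returns NULL when the
# class has no pixels.
fit_gmm <- function(z, K, rng) {
  n <- nrow(z)
  if (n == 0) return(NULL)
  K <- min(K, nrow(unique(z)), n - 1L)  # stats::kmeans needs k < n
  if (K <= 1) {
    cl <- rep(1L, n)
    K <- 1L
  } else {
    km <- with_rng(rng, suppressWarnings(
      stats::kmeans(z, centers = K, iter.max = 20, nstart = 1)))
    cl <- km$cluster
  }
  comps <- vector("list", K)
  for (k in seq_len(K)) {
    zk <- z[cl == k, , drop = FALSE]
    mu <- colMeans(zk)
    sig <- if (nrow(zk) > 1) stats::cov(zk) else diag(0, 3)
    # covariance floor ~ sensor-noise scale: hard-assigned clusters of
    # smoothly shaded regions are otherwise overconfident, and their
    # data terms would swamp the smoothness energy
    sig <- sig + diag(1e-3, 3)
    ch <- chol(sig)
    comps[[k]] <- list(
      w = nrow(zk) / n, mu = mu, chol_inv = backsolve(ch, diag(3)),
      logdet = 2 * sum(log(diag(ch)))
    )
  }
  comps
}

# Log mixture density at each row of z.
gmm_logdens <- function(gmm, z) {
  n <- nrow(z)
  if (n == 0) return(numeric(0))
  logs <- matrix(-Inf, n, length(gmm))
  for (k in seq_along(gmm)) {
    cmp <- gmm[[k]]
    zc <- sweep(z, 2, cmp$mu) %*% cmp$chol_inv
    q <- rowSums(zc^2)
    logs[, k] <- log(cmp$w) - 0.5 * (q + cmp$logdet + 3 * log(2 * pi))
  }
  m <- apply(logs, 1, max)
  m + log(rowSums(exp(logs - m)))
}
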