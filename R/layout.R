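#' Two- or three-dimensional layout of the structure components
#'
#' Projects the eigengap-selected multiscale diffusion components to a
#' low-dimensional visualization by building a fuzzy neighbor graph on the
#' components and optimizing the embedding with attractive/repulsive
#' cross-entropy descent (UMAP). `M` is the effective minimum distance
#' between embedded points and `S` their effective scale (the spread of the
#' low-dimensional similarity curve). The layout is initialized from the
#' first `d` selected components, so runs are reproducible and seed-stable;
#' coordinates are centered at the origin.
#'
#' @param space a `diffusion_space`.
#' @param M effective minimum distance between embedded points (default 0.3).
#' @param S effective scale of embedded points (default 1.0; must be >= M).
#' @param d output dimensionality, 2 or 3.
#' @param seed integer random seed.
#' @param n_neighbors neighborhood size of the fuzzy graph (default 15).
#' @return object of class `layout_embedding`: list with `coords` (n x d,
#'   axis means 0), `params` (M, S, d, seed), `source` (fingerprint of the
#'   input component matrix).
#' @export
embed_layout <- function(space, M = 0.3, S = 1.0, d = 2, seed = 42,
                         n_neighbors = 15) {
  stopifnot(inherits(space, "diffusion_space"), M > 0, S >= M, d %in% c(2, 3))
  if (space$selected_m < 2)
    stop("validation error: need at least 2 selected components", call. = FALSE)
  comp <- structure_components(space)
  n <- nrow(comp)
  # spectral-style init from the leading components, rescaled to the usual
  # 1e-4-noise-free init extent uwot expects
  init <- comp[, seq_len(d), drop = FALSE]
  init <- scale(init, center = TRUE, scale = FALSE)
  sdev <- max(apply(init, 2, stats::sd))
  if (sdev > 0) init <- init * (2.5 / sdev)   # spread the optimizer expects
  set.seed(seed)
  coords <- uwot::umap(comp, n_neighbors = min(n_neighbors, n - 1),
                       n_components = d, min_dist = M, spread = S,
                       init = init, n_threads = 1, n_sgd_threads = 0,
                       verbose = FALSE)
  coords <- scale(coords, center = TRUE, scale = FALSE)
  attr(coords, "scaled:center") <- NULL
  structure(list(coords = coords,
                 params = list(M = M, S = S, d = d, seed = seed,
                               n_neighbors = n_neighbors),
                 source = list(n = n, m = ncol(comp),
                               checksum = sum(comp^2))),
            class = "layout_embedding")
}

#' @exportS3Method print layout_embedding
print.layout_embedding <- function(x, ...) {
  cat(sprintf("layout_embedding: %d points in %d-D (min_dist = %g, spread = %g, seed = %d)\n",
              nrow(x$coords), ncol(x$coords), x$params$M, x$params$S,
              x$params$seed))
  invisible(x)
}

#' Plot a diffusion embedding layout
#'
#' Scatter of the 2-D layout, optionally colored by a per-cell covariate
#' (cluster labels or a gene's expression). A numeric `color_threshold`
#' saturates the color scale at a fixed expression level, mirroring
#' threshold-colored expression maps.
#'
#' @param x a `diffusion_space` (a layout is computed with defaults) or a
#'   `layout_embedding`.
#' @param color optional per-cell value: factor/character for discrete
#'   colors, numeric for a gradient.
#' @param color_threshold optional ceiling applied to numeric `color`.
#' @param pch,cex,main passed to [graphics::plot()].
#' @param ... further arguments to [graphics::plot()].
#' @return the layout used, invisibly.
#' @export
plot.diffusion_space <- function(x, color = NULL, color_threshold = NULL,
                                 pch = 16, cex = 0.4, main = "dbMAP layout",
                                 ...) {
  lay <- embed_layout(x)
  plot(lay, color = color, color_threshold = color_threshold, pch = pch,
       cex = cex, main = main, ...)
}

#' @rdname plot.diffusion_space
#' @export
plot.layout_embedding <- function(x, color = NULL, color_threshold = NULL,
                                  pch = 16, cex = 0.4,
                                  main = "dbMAP layout", ...) {
  co <- x$coords
  col <- "grey30"
  if (!is.null(color)) {
    if (is.numeric(color)) {
      if (!is.null(color_threshold)) color <- pmin(color, color_threshold)
      pal <- grDevices::colorRampPalette(c("grey85", "darkblue"))(100)
      rng <- range(color)
      idx <- if (diff(rng) == 0) rep(1L, length(color))
             else 1L + as.integer(99 * (color - rng[1]) / diff(rng))
      col <- pal[idx]
    } else {
      f <- as.factor(color)
      col <- grDevices::rainbow(nlevels(f))[as.integer(f)]
    }
  }
  graphics::plot(co[, 1], co[, 2], col = col, pch = pch, cex = cex,
                 xlab = "dbMAP 1", ylab = "dbMAP 2", main = main, ...)
  invisible(x)
}

#' Rank-based trustworthiness of a low-dimensional embedding
#'
#' For each point, low-space k-neighbors that are not among its high-space
#' k-neighbors are penalized by how far down the high-space ranking they
#' sit; the penalty is normalized so that 1 means every low-space neighbor
#' is a true neighbor and values near 0.5 arise under random embeddings.
#'
#' @param high numeric matrix, original space (rows = observations).
#' @param low numeric matrix, embedded space (same row count).
#' @param k neighborhood size, `1 <= k < n/2`.
#' @return trustworthiness score in `[0, 1]`.
#' @export
trustworthiness <- function(high, low, k = 15) {
  high <- as.matrix(high); low <- as.matrix(low)
  n <- nrow(high)
  stopifnot(nrow(low) == n, k >= 1, k < n / 2)
  Dh <- pairwise_distances(high, "euclidean")
  Dl <- pairwise_distances(low, "euclidean")
  diag(Dh) <- Inf; diag(Dl) <- Inf
  penalty <- 0
  for (i in seq_len(n)) {
    rh <- rank(Dh[i, ], ties.method = "first")   # 1 = nearest in high space
    nn_low <- order(Dl[i, ], seq_len(n))[seq_len(k)]
    r <- rh[nn_low]
    penalty <- penalty + sum(pmax(r - k, 0))
  }
  1 - 2 / (n * k * (2 * n - 3 * k - 1)) * penalty
}
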