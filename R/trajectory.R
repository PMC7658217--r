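#' Farthest-point waypoint selection
#'
#' Max-min sampling seeded at the start cell, run independently per
#' component dimension on that dimension's coordinate, union-deduplicated
#' and truncated to `n_waypoints`. The start cell is always included and
#' the result is deterministic.
#'
#' @param components numeric matrix (cells x components).
#' @param n_waypoints number of waypoints requested.
#' @param start_cell integer row index of the start cell.
#' @return integer vector of waypoint row indices (start cell first).
#' @export
select_waypoints <- function(components, n_waypoints, start_cell) {
  components <- as.matrix(components)
  n <- nrow(components)
  stopifnot(n_waypoints >= 1, start_cell >= 1, start_cell <= n)
  if (n_waypoints >= n) return(seq_len(n))
  per_dim <- ceiling(n_waypoints / ncol(components))
  picks <- lapply(seq_len(ncol(components)), function(j) {
    v <- components[, j]
    chosen <- start_cell
    dmin <- abs(v - v[start_cell])
    while (length(chosen) < per_dim + 1) {
      cand <- which.max(dmin)
      if (dmin[cand] == 0) break
      chosen <- c(chosen, cand)
      dmin <- pmin(dmin, abs(v - v[cand]))
    }
    chosen
  })
  # interleave dimensions so truncation keeps a balanced cover
  maxlen <- max(lengths(picks))
  inter <- unlist(lapply(seq_len(maxlen), function(r)
    unlist(lapply(picks, function(p) if (r <= length(p)) p[r] else NULL))))
  wp <- unique(c(start_cell, inter))
  wp[seq_len(min(n_waypoints, length(wp)))]
}

# kNN graph in multiscale space as a symmetric igraph with Euclidean edge
# lengths, plus the raw kNN structure.
multiscale_graph <- function(components, k) {
  n <- nrow(components)
  g <- build_knn(components, min(k, n - 1), "euclidean")
  ii <- rep(seq_len(n), each = g$K)
  jj <- as.integer(t(g$indices))
  dd <- as.numeric(t(g$distances))
  ig <- igraph::graph_from_data_frame(
    data.frame(from = ii, to = jj, weight = dd), directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  ig <- igraph::simplify(ig, edge.attr.comb = list(weight = "min"))
  list(graph = ig, knn = g)
}

#' Pseudotime from a start cell with waypoint refinement
#'
#' Initializes each cell's pseudotime as its shortest-path distance from
#' the start cell over the kNN graph of the multiscale components (edge
#' length = Euclidean distance). Waypoint refinement then replaces each
#' cell's value by the Gaussian-kernel-weighted average, over waypoints, of
#' the waypoint's pseudotime plus the signed graph distance to the cell
#' (positive beyond the waypoint, negative before it), iterating until the
#' largest change drops below `tol` (relative to the range) or 25
#' iterations. The start cell is pinned at 0 and the result min-max
#' normalized to `[0, 1]`.
#'
#' @param components numeric matrix (cells x components), typically the
#'   leading multiscale diffusion components.
#' @param start_cell integer row index of the start cell.
#' @param k neighbors for the graph (default 15).
#' @param n_waypoints waypoints for refinement (default 500).
#' @param tol convergence tolerance on the maximal change (default 1e-3).
#' @return numeric pseudotime per cell in `[0, 1]`, with attributes
#'   `waypoints` (indices used) and `raw_scale` (the pre-normalization
#'   range, the unit of graph distance).
#' @export
compute_pseudotime <- function(components, start_cell, k = 15,
                               n_waypoints = 500, tol = 1e-3) {
  components <- as.matrix(components)
  n <- nrow(components)
  ms <- multiscale_graph(components, k)
  ncomp <- igraph::components(ms$graph)$no
  if (ncomp > 1)
    stop("validation error: kNN graph is disconnected (", ncomp,
         " components); increase k", call. = FALSE)
  wp <- select_waypoints(components, n_waypoints, start_cell)
  D <- igraph::distances(ms$graph, v = as.character(wp),
                         weights = igraph::E(ms$graph)$weight)
  D <- D[, order(as.integer(colnames(D))), drop = FALSE]   # columns = cells 1..n
  pt <- D[1, ]                          # start cell is the first waypoint
  sigma <- apply(D, 1, stats::sd)
  sigma[sigma == 0] <- 1
  Wk <- exp(-(D / sigma)^2)
  Wk <- sweep(Wk, 2, colSums(Wk), "/")
  nw <- length(wp)
  for (it in seq_len(25)) {
    pt_wp <- pt[wp]
    # waypoint w's view of cell i: pt(w) + d(w,i) if i lies beyond w, else
    # pt(w) - d(w,i)
    sgn <- sign(matrix(pt, nw, n, byrow = TRUE) - pt_wp)
    sgn[sgn == 0] <- 1
    proposal <- pt_wp + sgn * D
    new_pt <- colSums(Wk * proposal)
    new_pt <- new_pt - new_pt[start_cell]
    new_pt[new_pt < 0] <- 0
    delta <- max(abs(new_pt - pt))
    pt <- new_pt
    if (delta < tol * max(max(pt), 1e-12)) break
  }
  rng <- max(pt)
  out <- if (rng > 0) pt / rng else pt
  names(out) <- NULL
  attr(out, "waypoints") <- wp
  attr(out, "raw_scale") <- rng
  out
}

#' Automatic terminal-state detection
#'
#' Candidates are the extremal cells (maximum and minimum) of each used
#' component — the boundary points of the diffusion geometry. A candidate is
#' kept when its pseudotime reaches the `pt_quantile` quantile of the
#' pseudotime distribution over all cells (dropping the start-side boundary)
#' and no already-retained candidate lies within its k-neighborhood
#' (candidates visited in decreasing pseudotime order). Detection is most
#' reliable on the eigengap-selected components, whose extrema are the true
#' boundary states rather than noise outliers. User-supplied terminal cells
#' bypass detection entirely.
#'
#' @param components numeric matrix (cells x components), ideally the
#'   eigengap-selected structure components.
#' @param pseudotime per-cell pseudotime.
#' @param k neighborhood size for deduplication (default 15).
#' @param terminal_cells optional user-specified terminal cell indices,
#'   returned verbatim.
#' @param pt_quantile pseudotime quantile a candidate must reach
#'   (default 0.75).
#' @return integer vector of terminal cell indices.
#' @export
find_terminal_states <- function(components, pseudotime, k = 15,
                                 terminal_cells = NULL, pt_quantile = 0.75) {
  if (!is.null(terminal_cells)) return(as.integer(terminal_cells))
  components <- as.matrix(components)
  cand <- unique(c(apply(components, 2, which.max),
                   apply(components, 2, which.min)))
  g <- build_knn(components, min(k, nrow(components) - 1), "euclidean")
  # judge candidates by their neighborhood's pseudotime, not their own: a
  # geometric outlier can carry an inflated path distance while sitting in
  # an early region
  pt_smooth <- vapply(cand, function(cell)
    stats::median(pseudotime[c(cell, g$indices[cell, ])]), numeric(1))
  q <- stats::quantile(pseudotime, pt_quantile, type = 7)
  keep_cand <- pt_smooth >= q
  cand <- cand[keep_cand]
  pt_smooth <- pt_smooth[keep_cand]
  if (!length(cand))
    stop("no terminal-state candidates found; supply terminal_cells manually",
         call. = FALSE)
  cand <- cand[order(-pt_smooth)]
  kept <- integer(0)
  for (cell in cand) {
    nbrs <- c(cell, g$indices[cell, ])
    overlap <- any(kept %in% nbrs) ||
      any(cell == g$indices[kept, , drop = FALSE])
    if (!overlap) kept <- c(kept, cell)
  }
  sort(kept)
}

#' Absorption probabilities of an absorbing Markov chain
#'
#' Rows of `P` are normalized over their outgoing weights; the listed
#' absorbing cells are fixed points. Absorption probabilities of the
#' transient cells are solved from the fundamental linear system
#' `(I - Q) B = R`. Transient cells with no path to any absorbing cell are
#' assigned to the nearest terminal in `components` (warning).
#'
#' @param P nonnegative square matrix (sparse or dense) of forward weights;
#'   rows need not be normalized. Self-loops allowed.
#' @param terminal_cells indices of absorbing cells; alternatively a list of
#'   disjoint index vectors, each an absorbing class (terminal region) whose
#'   members' absorption is pooled into one output column.
#' @param components optional coordinates used only to place unreachable
#'   cells with their nearest terminal.
#' @return list with `branch_probs` (n x number of terminal classes, rows
#'   sum to 1) and `entropy` (`-sum p ln p` per cell; 0 on absorbing cells).
#' @export
absorption_probabilities <- function(P, terminal_cells, components = NULL) {
  if (is.matrix(P)) P <- Matrix::Matrix(P, sparse = TRUE)
  P <- methods::as(methods::as(P, "generalMatrix"), "CsparseMatrix")
  n <- nrow(P)
  if (!is.list(terminal_cells)) terminal_cells <-
    as.list(sort(unique(as.integer(terminal_cells))))
  sets <- lapply(terminal_cells, as.integer)
  if (anyDuplicated(unlist(sets)))
    stop("validation error: terminal classes must be disjoint", call. = FALSE)
  nt <- length(sets)
  absorbing <- unlist(sets)
  class_of <- rep(seq_len(nt), lengths(sets))
  terminal_cells <- absorbing
  B <- matrix(0, n, nt)
  B[cbind(absorbing, class_of)] <- 1
  trans <- setdiff(seq_len(n), absorbing)
  if (length(trans)) {
    gdir <- igraph::graph_from_adjacency_matrix(P > 0, mode = "directed")
    dmat <- igraph::distances(gdir, v = terminal_cells, mode = "in")
    reach <- apply(is.finite(dmat), 2, any)   # columns follow vertex order
    bad <- trans[!reach[trans]]
    if (length(bad)) {
      warning(length(bad), " cell(s) cannot reach any terminal state; ",
              "assigned to the nearest terminal by coordinates")
      for (cell in bad) {
        j <- if (!is.null(components))
          class_of[which.min(rowSums(sweep(
            as.matrix(components)[absorbing, , drop = FALSE],
            2, as.matrix(components)[cell, ], "-")^2))]
        else 1L
        B[cell, j] <- 1
      }
      trans <- setdiff(trans, bad)
    }
    if (length(trans)) {
      absorbed <- setdiff(seq_len(n), trans)   # terminals + rescued cells
      rs <- Matrix::rowSums(P[trans, , drop = FALSE])
      if (any(rs == 0))
        stop("internal error: transient cell with no outgoing edge survived ",
             "reachability check", call. = FALSE)
      Pn <- Matrix::Diagonal(x = 1 / rs) %*% P[trans, , drop = FALSE]
      Q <- Pn[, trans, drop = FALSE]
      Rhat <- Pn[, absorbed, drop = FALSE] %*% B[absorbed, , drop = FALSE]
      I <- Matrix::Diagonal(length(trans))
      X <- as.matrix(Matrix::solve(I - Q, Rhat))
      B[trans, ] <- X
    }
  }
  ent <- apply(B, 1, function(p) {
    p <- p[p > 0]
    max(0, -sum(p * log(p)))   # round-off can leave -1e-16
  })
  ent[absorbing] <- 0
  colnames(B) <- vapply(sets, function(s) as.character(s[1]), "")
  list(branch_probs = B, entropy = ent)
}

#' Branch probabilities and differentiation entropy
#'
#' Builds a forward-biased directed chain on the multiscale kNN graph: the
#' edge i -> j is kept iff `pseudotime(j) > pseudotime(i) - s * sigma_i`,
#' where `sigma_i` is cell i's neighbor scale (the spread of pseudotime
#' over its neighborhood) and `s = 1`, so slight backward steps within the
#' local noise scale stay allowed. Edge weights are the adaptive Gaussian
#' kernel on component-space distance, rows normalized; terminal cells are
#' absorbing and the absorption probabilities solved exactly.
#' Differentiation potential is the entropy of each cell's absorption row.
#'
#' @param components numeric matrix (cells x components).
#' @param pseudotime per-cell pseudotime.
#' @param terminal_cells nonempty integer vector of absorbing cells.
#' @param k neighbors (default 15).
#' @param s forward slack multiplier (default 1).
#' @return list with `branch_probs` and `entropy` (see
#'   [absorption_probabilities()]).
#' @export
branch_probabilities <- function(components, pseudotime, terminal_cells,
                                 k = 15, s = 1) {
  components <- as.matrix(components)
  n <- nrow(components)
  stopifnot(length(terminal_cells) >= 1)
  g <- build_knn(components, min(k, n - 1), "euclidean")
  K <- g$K
  sigma_d <- g$distances[, ceiling(K / 2)]
  pos <- g$distances[g$distances > 0]
  sigma_d[sigma_d == 0] <- if (length(pos)) min(pos) else 1
  # per-cell pseudotime scale: sd of pseudotime over the neighborhood
  sigma_pt <- apply(matrix(pseudotime[g$indices], n, K), 1, stats::sd)
  sigma_pt[is.na(sigma_pt) | sigma_pt == 0] <- 1e-8
  ii <- rep(seq_len(n), each = K)
  jj <- as.integer(t(g$indices))
  dd <- as.numeric(t(g$distances))
  keep <- pseudotime[jj] > pseudotime[ii] - s * sigma_pt[ii]
  ii <- ii[keep]; jj <- jj[keep]; dd <- dd[keep]
  w <- exp(-dd^2 / sigma_d[ii]^2)
  P <- Matrix::sparseMatrix(i = ii, j = jj, x = w, dims = c(n, n))
  # absorb into the terminal's local state region, not the single cell: a
  # boundary cell can have negligible in-flow, its neighborhood cannot
  terminal_cells <- sort(unique(as.integer(terminal_cells)))
  taken <- terminal_cells
  sets <- lapply(terminal_cells, function(t) {
    nbrs <- setdiff(g$indices[t, ], taken)
    taken <<- c(taken, nbrs)
    c(t, nbrs)
  })
  absorption_probabilities(P, sets, components)
}

#' Diffusion imputation of expression values
#'
#' Smooths each gene over the cell graph by `t` applications of the
#' diffusion operator (`imputed = P^t expr`), computed by repeated sparse
#' matrix-vector products without materializing `P^t`. Each imputed value
#' is a convex combination of observed values, so it stays within the
#' gene's observed range; a constant gene is a fixed point.
#'
#' @param op a `diffusion_operator` (e.g. `dbmap(...)$operator`).
#' @param expr an `expression_matrix` with layer `"lognorm"`.
#' @param t number of diffusion steps (default 3).
#' @return an `expression_matrix` with layer `"imputed"` (dense).
#' @export
impute_diffusion <- function(op, expr, t = 3) {
  stopifnot(inherits(op, "diffusion_operator"),
            inherits(expr, "expression_matrix"), t >= 1)
  m <- expr$values
  out <- as.matrix(m)
  for (step in seq_len(t)) out <- as.matrix(op$P %*% out)
  expression_matrix(out, "imputed", expr$barcodes, expr$features)
}

#' Branch-weighted gene expression trend along pseudotime
#'
#' Weighted Gaussian kernel (Nadaraya-Watson) regression of a gene's
#' (imputed) expression on pseudotime, with per-cell weights given by the
#' branch probability of the queried terminal, evaluated on a uniform grid
#' over `[0, 1]`. The kernel bandwidth follows Silverman's rule on the
#' pseudotime values.
#'
#' @param values numeric expression per cell (typically imputed).
#' @param pseudotime per-cell pseudotime in `[0, 1]`.
#' @param branch_weights per-cell weights in `[0, 1]`; `NULL` = uniform.
#' @param grid number of grid points (default 500).
#' @return data.frame with columns `pseudotime` (grid) and `expression`.
#' @export
gene_trends <- function(values, pseudotime, branch_weights = NULL,
                        grid = 500) {
  n <- length(values)
  stopifnot(length(pseudotime) == n)
  if (is.null(branch_weights)) branch_weights <- rep(1, n)
  stopifnot(all(branch_weights >= 0), all(branch_weights <= 1))
  if (all(branch_weights == 0))
    stop("validation error: all branch weights are zero", call. = FALSE)
  sdev <- stats::sd(pseudotime)
  iqr <- stats::IQR(pseudotime) / 1.34
  bw <- 0.9 * min(sdev, if (iqr > 0) iqr else sdev) * n^(-1 / 5)
  if (!is.finite(bw) || bw <= 0) bw <- 0.05
  xg <- seq(0, 1, length.out = grid)
  fitted <- vapply(xg, function(x0) {
    w <- branch_weights * exp(-0.5 * ((pseudotime - x0) / bw)^2)
    sw <- sum(w)
    if (sw == 0) NA_real_ else sum(w * values) / sw
  }, numeric(1))
  # fill any empty-kernel grid points from the nearest evaluated point
  if (anyNA(fitted)) {
    ok <- which(!is.na(fitted))
    fitted <- fitted[ok][pmax(1, findInterval(seq_along(fitted), ok))]
  }
  data.frame(pseudotime = xg, expression = fitted)
}

#' Full trajectory analysis of a diffusion space
#'
#' Convenience wrapper running pseudotime estimation, terminal-state
#' detection and branch-probability/entropy computation on the leading
#' multiscale components of a fitted diffusion embedding.
#'
#' @param space a `diffusion_space` from [dbmap()].
#' @param start_cell integer index (or barcode position) of the start cell.
#' @param n_components diffusion components used (default 10).
#' @param k neighbors in multiscale space (default 15).
#' @param n_waypoints waypoints for refinement (default 500).
#' @param terminal_cells optional user-specified terminals (bypass
#'   detection).
#' @param tol pseudotime refinement tolerance (default 1e-3).
#' @return object of class `trajectory_result`: list with `pseudotime`,
#'   `start_cell`, `terminal_cells`, `branch_probs`, `entropy`, `params`.
#' @export
run_trajectory <- function(space, start_cell, n_components = 10, k = 15,
                           n_waypoints = 500, terminal_cells = NULL,
                           tol = 1e-3) {
  stopifnot(inherits(space, "diffusion_space"))
  comp <- space$components
  m <- min(n_components, ncol(comp))
  comp <- comp[, seq_len(m), drop = FALSE]
  pt <- compute_pseudotime(comp, start_cell, k = k,
                           n_waypoints = n_waypoints, tol = tol)
  # terminal candidates come from the eigengap-selected structure geometry;
  # noise components contribute spurious extrema
  sel <- comp[, seq_len(min(space$selected_m, m)), drop = FALSE]
  term <- find_terminal_states(sel, pt, k = k,
                               terminal_cells = terminal_cells)
  bp <- branch_probabilities(comp, pt, term, k = k)
  structure(list(pseudotime = as.numeric(pt), start_cell = start_cell,
                 terminal_cells = term, branch_probs = bp$branch_probs,
                 entropy = bp$entropy,
                 params = list(n_components = m, k = k,
                               n_waypoints = n_waypoints, tol = tol)),
            class = "trajectory_result")
}

#' @exportS3Method print trajectory_result
print.trajectory_result <- function(x, ...) {
  cat(sprintf("trajectory_result: %d cells, start cell %d, %d terminal state(s)\n",
              length(x$pseudotime), x$start_cell, length(x$terminal_cells)))
  cat("  terminal cells:", paste(x$terminal_cells, collapse = ", "), "\n")
  cat(sprintf("  entropy: median %.3f, max %.3f (bound ln(%d) = %.3f)\n",
              stats::median(x$entropy), max(x$entropy),
              length(x$terminal_cells), log(length(x$terminal_cells))))
  invisible(x)
}

#' @exportS3Method summary trajectory_result
summary.trajectory_result <- function(object, ...) {
  out <- list(n = length(object$pseudotime),
              start_cell = object$start_cell,
              terminal_cells = object$terminal_cells,
              pseudotime_quartiles = stats::quantile(object$pseudotime),
              mean_entropy = mean(object$entropy),
              branch_share = colMeans(object$branch_probs))
  class(out) <- "summary.trajectory_result"
  out
}

#' @exportS3Method print summary.trajectory_result
print.summary.trajectory_result <- function(x, ...) {
  cat(sprintf("Trajectory over %d cells from start cell %d\n", x$n,
              x$start_cell))
  cat("  terminal cells:", paste(x$terminal_cells, collapse = ", "), "\n")
  cat("  mean branch probability:",
      paste(sprintf("%s: %.3f", names(x$branch_share), x$branch_share),
            collapse = ", "), "\n")
  cat(sprintf("  mean differentiation entropy: %.3f\n", x$mean_entropy))
  invisible(x)
}
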