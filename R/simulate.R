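#' Isotropic Gaussian mixture in feature space
#'
#' `k` spherical Gaussian clusters with centers at mutual distance
#' `sep * sqrt(dim)` (orthogonal-axis construction when `k <= dim`, rescaled
#' random directions otherwise) and unit-variance noise.
#'
#' @param n_per cells per cluster.
#' @param k number of clusters.
#' @param dim feature dimensionality.
#' @param sep center separation per sqrt-dimension; 0 collapses all
#'   clusters.
#' @param seed integer seed.
#' @return list with `X` (n_per*k x dim matrix) and `labels` (integer).
#' @export
make_gaussian_mixture <- function(n_per, k, dim, sep, seed = 1) {
  stopifnot(k >= 1, sep >= 0, dim >= 1)
  set.seed(seed)
  centers <- if (k <= dim) {
    diag(1, k, dim) * sep * sqrt(dim) / sqrt(2)
  } else {
    C <- matrix(stats::rnorm(k * dim), k, dim)
    C <- C / sqrt(rowSums(C^2))
    C * sep * sqrt(dim) / sqrt(2)
  }
  X <- do.call(rbind, lapply(seq_len(k), function(i)
    matrix(stats::rnorm(n_per * dim), n_per, dim) +
      matrix(centers[i, ], n_per, dim, byrow = TRUE)))
  list(X = X, labels = rep(seq_len(k), each = n_per))
}

#' Noisy circular manifold
#'
#' Points `(cos theta, sin theta)` plus isotropic Gaussian noise, with
#' `theta` uniform on `[0, 2*pi)` and returned sorted, so consecutive rows
#' traverse the circle monotonically.
#'
#' @param n number of points.
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param seed integer seed.
#' @return list with `X` (n x 2) and `theta` (sorted true angles).
#' @export
make_noisy_circle <- function(n, noise_sd, seed = 1) {
  stopifnot(noise_sd >= 0)
  set.seed(seed)
  theta <- sort(stats::runif(n, 0, 2 * pi))
  X <- cbind(cos(theta), sin(theta)) +
    matrix(stats::rnorm(2 * n, sd = noise_sd), n, 2)
  list(X = X, theta = theta)
}

# negative-binomial (or Poisson) sampling around a mean matrix with
# per-cell library factors; nb_size = Inf selects Poisson
sample_counts <- function(mu, nb_size, lib_factor) {
  n <- nrow(mu); g <- ncol(mu)
  mu <- mu * lib_factor
  counts <- if (is.infinite(nb_size)) {
    matrix(stats::rpois(n * g, lambda = as.numeric(mu)), n, g)
  } else {
    matrix(stats::rnbinom(n * g, size = nb_size, mu = as.numeric(mu)), n, g)
  }
  counts
}

#' Simulate a branching single-cell lineage with NB counts
#'
#' A root expression program and `n_branches` leaf programs. Each cell
#' draws a true pseudotime `u ~ Uniform[0, 1]`; cells past the branch
#' point (`u > 0.3`) are assigned a branch. Gene means interpolate
#' log-linearly from the root program toward the assigned leaf program as
#' differentiation progresses; each branch owns `depth_genes_per_branch`
#' genes up-regulated by `fold` at full maturity, and a shared set of
#' trunk genes ramps monotonically with `u` to carry depth signal. Counts
#' are negative binomial with the given size parameter (`Inf` = Poisson)
#' under per-cell log-normal library factors.
#'
#' @param n_cells number of cells.
#' @param n_genes number of genes (>= 10 * n_branches recommended).
#' @param n_branches number of leaf branches (>= 1).
#' @param depth_genes_per_branch branch-specific genes per leaf; default
#'   `NULL` = 10% of `n_genes`, the conventional per-program share of
#'   differentially expressed genes in single-cell count simulators.
#' @param fold maximal fold change of branch genes (> 1, default 4).
#' @param nb_dispersion negative binomial size parameter theta
#'   (variance = mu + mu^2 / theta); `Inf` = Poisson (default 10).
#' @param lib_size_sd standard deviation of log library factors
#'   (default 0.2).
#' @param seed integer seed.
#' @return list with `counts` (a `count_matrix`) and `truth` (list:
#'   `labels` — branch id, 0 before the branch point; `pseudotime_true`;
#'   `doublet_flag` (all FALSE); `planted_markers` — gene symbol to branch
#'   map; `base_mu` — baseline per-gene means; `params`).
#' @export
simulate_branching_counts <- function(n_cells, n_genes, n_branches,
                                      depth_genes_per_branch = NULL, fold = 4,
                                      nb_dispersion = 10, lib_size_sd = 0.2,
                                      seed = 1) {
  stopifnot(n_branches >= 1, fold > 1, lib_size_sd >= 0)
  if (is.null(depth_genes_per_branch))
    depth_genes_per_branch <- max(1L, floor(0.1 * n_genes))
  stopifnot((n_branches + 2) * depth_genes_per_branch <= n_genes)
  set.seed(seed)
  u <- stats::runif(n_cells)
  branch <- ifelse(u > 0.3, sample.int(n_branches, n_cells, replace = TRUE),
                   0L)
  base_mu <- exp(stats::runif(n_genes, log(0.2), log(5)))
  # gene roles: per-branch markers, shared trunk ramp, rest constant
  bgenes <- lapply(seq_len(n_branches), function(b)
    ((b - 1) * depth_genes_per_branch + 1):(b * depth_genes_per_branch))
  ramp_up <- (n_branches * depth_genes_per_branch + 1):
    (n_branches * depth_genes_per_branch + depth_genes_per_branch)
  ramp_dn <- ramp_up + depth_genes_per_branch
  stopifnot(max(ramp_dn) <= n_genes)
  logmu <- matrix(log(base_mu), n_cells, n_genes, byrow = TRUE)
  w <- pmax(0, (u - 0.3) / 0.7)           # branch progression in [0, 1]
  for (b in seq_len(n_branches)) {
    rows <- which(branch == b)
    if (length(rows))
      logmu[rows, bgenes[[b]]] <- logmu[rows, bgenes[[b]]] +
        outer(w[rows], rep(log(fold), depth_genes_per_branch))
  }
  logmu[, ramp_up] <- logmu[, ramp_up] + outer(u, rep(log(fold), length(ramp_up)))
  logmu[, ramp_dn] <- logmu[, ramp_dn] - outer(u, rep(log(fold), length(ramp_dn)))
  lib <- exp(stats::rnorm(n_cells, 0, lib_size_sd))
  counts <- sample_counts(exp(logmu), nb_dispersion, lib)
  symbols <- sprintf("G%04d", seq_len(n_genes))
  cm <- count_matrix(counts,
                     barcodes = sprintf("cell_%05d", seq_len(n_cells)),
                     features = data.frame(id = symbols, symbol = symbols))
  planted <- stats::setNames(rep(seq_len(n_branches),
                                 each = depth_genes_per_branch),
                             symbols[unlist(bgenes)])
  truth <- list(labels = branch, pseudotime_true = u,
                doublet_flag = rep(FALSE, n_cells),
                planted_markers = planted, base_mu = base_mu,
                params = list(n_cells = n_cells, n_genes = n_genes,
                              n_branches = n_branches,
                              depth_genes_per_branch = depth_genes_per_branch,
                              fold = fold, nb_dispersion = nb_dispersion,
                              lib_size_sd = lib_size_sd, seed = seed))
  list(counts = cm, truth = truth)
}

#' Simulate well-separated cell clusters with planted marker genes
#'
#' `k` discrete expression programs, each up-regulating its own
#' `markers_per_cluster` genes by `fold` over a shared baseline; counts are
#' negative binomial with log-normal library factors, giving a mixture with
#' known labels and known markers for clustering and marker-recovery
#' validation.
#'
#' @param n_cells total cells (split as evenly as possible).
#' @param n_genes number of genes.
#' @param k number of clusters.
#' @param markers_per_cluster planted marker genes per cluster
#'   (default 20).
#' @param fold marker fold change (default 4).
#' @param nb_dispersion NB size theta; `Inf` = Poisson (default 10).
#' @param lib_size_sd sd of log library factors (default 0.2).
#' @param seed integer seed.
#' @return list with `counts` (a `count_matrix`) and `truth` (`labels`,
#'   `planted_markers` mapping gene symbol to cluster, `params`).
#' @export
simulate_cluster_counts <- function(n_cells, n_genes, k,
                                    markers_per_cluster = 20, fold = 4,
                                    nb_dispersion = 10, lib_size_sd = 0.2,
                                    seed = 1) {
  stopifnot(k >= 1, fold > 1, k * markers_per_cluster <= n_genes)
  set.seed(seed)
  labels <- rep(seq_len(k), length.out = n_cells)
  labels <- labels[order(stats::runif(n_cells))]
  base_mu <- exp(stats::runif(n_genes, log(0.2), log(5)))
  logmu <- matrix(log(base_mu), n_cells, n_genes, byrow = TRUE)
  mgenes <- split(seq_len(k * markers_per_cluster),
                  rep(seq_len(k), each = markers_per_cluster))
  for (cl in seq_len(k)) {
    rows <- which(labels == cl)
    logmu[rows, mgenes[[cl]]] <- logmu[rows, mgenes[[cl]]] + log(fold)
  }
  lib <- exp(stats::rnorm(n_cells, 0, lib_size_sd))
  counts <- sample_counts(exp(logmu), nb_dispersion, lib)
  symbols <- sprintf("G%04d", seq_len(n_genes))
  cm <- count_matrix(counts,
                     barcodes = sprintf("cell_%05d", seq_len(n_cells)),
                     features = data.frame(id = symbols, symbol = symbols))
  planted <- stats::setNames(rep(seq_len(k), each = markers_per_cluster),
                             symbols[seq_len(k * markers_per_cluster)])
  list(counts = cm,
       truth = list(labels = labels, planted_markers = planted,
                    base_mu = base_mu,
                    params = list(n_cells = n_cells, n_genes = n_genes,
                                  k = k,
                                  markers_per_cluster = markers_per_cluster,
                                  fold = fold, nb_dispersion = nb_dispersion,
                                  lib_size_sd = lib_size_sd, seed = seed)))
}

#' Inject synthetic doublets into a count matrix
#'
#' Appends `floor(rate * n)` artificial cells, each the entry-wise average
#' (rounded down) of two distinct random parent cells, emulating two-cell
#' droplets that mix expression programs.
#'
#' @param x a `count_matrix`.
#' @param rate doublet rate in `[0, 1)`.
#' @param seed integer seed.
#' @return list with `counts` (augmented `count_matrix`) and
#'   `doublet_flag` (logical per output cell).
#' @export
inject_doublets <- function(x, rate, seed = 1) {
  validate_count_matrix(x)
  stopifnot(rate >= 0, rate < 1)
  n <- nrow(x$counts)
  nd <- floor(rate * n)
  if (nd == 0)
    return(list(counts = x, doublet_flag = rep(FALSE, n)))
  set.seed(seed)
  parents <- t(replicate(nd, sample.int(n, 2)))
  dbl <- floor((x$counts[parents[, 1], , drop = FALSE] +
                  x$counts[parents[, 2], , drop = FALSE]) / 2)
  counts <- rbind(x$counts, dbl)
  cm <- count_matrix(counts,
                     barcodes = c(x$barcodes,
                                  sprintf("doublet_%04d", seq_len(nd))),
                     features = x$features,
                     sample_of = c(x$sample_of, rep("doublet", nd)))
  list(counts = cm, doublet_flag = c(rep(FALSE, n), rep(TRUE, nd)))
}
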