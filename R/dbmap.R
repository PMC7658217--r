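#' Exact k-nearest-neighbor graph
#'
#' Exact kNN search (kd-tree for Euclidean; brute force cross-products for
#' cosine) excluding self-matches, with ties broken by point index.
#'
#' @param X numeric matrix, observations in rows.
#' @param K neighbors per observation (`K < nrow(X)`).
#' @param metric `"euclidean"` or `"cosine"` (cosine distance
#'   `1 - x.y/(|x||y|)`).
#' @return object of class `neighbor_graph`: list with `indices` (n x K),
#'   `distances` (n x K, row-sorted ascending), `metric`, `K`.
#' @export
build_knn <- function(X, K, metric = c("euclidean", "cosine")) {
  metric <- match.arg(metric)
  X <- as.matrix(X)
  stopifnot(all(is.finite(X)))
  n <- nrow(X)
  if (K >= n) stop("validation error: K (", K, ") must be < number of points (",
                   n, ")", call. = FALSE)
  if (metric == "euclidean" && n > 2000) {
    nn <- RANN::nn2(X, k = K + 1)         # exact kd-tree search
    idx <- nn$nn.idx
    dst <- nn$nn.dists
    # drop the self column (not always first under exact ties)
    out_i <- matrix(0L, n, K); out_d <- matrix(0, n, K)
    for (i in seq_len(n)) {
      self <- which(idx[i, ] == i)[1]
      if (is.na(self)) self <- K + 1L
      keep <- setdiff(seq_len(K + 1L), self)[seq_len(K)]
      out_i[i, ] <- idx[i, keep]; out_d[i, ] <- dst[i, keep]
    }
    idx <- out_i; dst <- out_d
  } else {
    D <- pairwise_distances(X, metric)
    diag(D) <- Inf
    idx <- matrix(0L, n, K); dst <- matrix(0, n, K)
    for (i in seq_len(n)) {
      o <- order(D[i, ], seq_len(n))[seq_len(K)]  # ties by index
      idx[i, ] <- o
      dst[i, ] <- D[i, o]
    }
  }
  structure(list(indices = idx, distances = dst, metric = metric, K = K),
            class = "neighbor_graph")
}

pairwise_distances <- function(X, metric) {
  if (metric == "euclidean") {
    s <- rowSums(X^2)
    D2 <- outer(s, s, "+") - 2 * tcrossprod(X)
    sqrt(pmax(D2, 0))
  } else {
    nrm <- sqrt(rowSums(X^2))
    nrm[nrm == 0] <- 1
    Xn <- X / nrm
    pmin(pmax(1 - tcrossprod(Xn), 0), 2)
  }
}

#' Density-adaptive Gaussian affinity from a neighbor graph
#'
#' Each cell i gets its own kernel bandwidth `sigma_i`, the distance to its
#' `bandwidth_rank`-th nearest neighbor, so the kernel widens in sparse
#' regions and narrows in dense ones. Directed affinities
#' `w_ij = exp(-d_ij^2 / sigma_i^2)` are symmetrized by averaging,
#' `W = (w + w^T) / 2`, with zero diagonal. A zero bandwidth falls back to
#' the smallest positive neighbor distance of that row, or 1 when the whole
#' row is zero.
#'
#' @param graph a `neighbor_graph`.
#' @param bandwidth_rank neighbor rank defining the bandwidth; default
#'   `ceiling(K / 2)`.
#' @return symmetric sparse `dgCMatrix` of affinities.
#' @export
adaptive_affinity <- function(graph, bandwidth_rank = NULL) {
  stopifnot(inherits(graph, "neighbor_graph"))
  K <- graph$K
  if (is.null(bandwidth_rank) || is.na(bandwidth_rank))
    bandwidth_rank <- ceiling(K / 2)
  stopifnot(bandwidth_rank >= 1, bandwidth_rank <= K)
  n <- nrow(graph$indices)
  sigma <- graph$distances[, bandwidth_rank]
  fix <- which(sigma == 0)
  for (i in fix) {
    pos <- graph$distances[i, graph$distances[i, ] > 0]
    sigma[i] <- if (length(pos)) min(pos) else 1
  }
  ii <- rep(seq_len(n), each = K)
  jj <- as.integer(t(graph$indices))
  dd <- as.numeric(t(graph$distances))
  w <- exp(-dd^2 / sigma[ii]^2)
  W <- Matrix::sparseMatrix(i = ii, j = jj, x = w, dims = c(n, n))
  W <- (W + Matrix::t(W)) / 2
  Matrix::diag(W) <- 0
  Matrix::drop0(W)
}

#' Anisotropically normalized diffusion operator
#'
#' Divides affinities by the product of row/column degrees raised to
#' `alpha` before row normalization: with `q = rowSums(W)`,
#' `W~_ij = W_ij / (q_i^alpha q_j^alpha)` and `P = D^-1 W~` where
#' `D = diag(rowSums(W~))`. At `alpha = 1` this decouples the operator from
#' sampling density and approximates the Laplace-Beltrami operator of the
#' underlying manifold; `alpha = 0` is plain random-walk normalization.
#'
#' @param W symmetric nonnegative sparse affinity matrix with zero diagonal.
#' @param alpha anisotropy exponent in `[0, 1]` (default 1).
#' @return object of class `diffusion_operator`: list with `P` (sparse
#'   row-stochastic), `degrees` (rowSums of the normalized kernel, defining
#'   the symmetric conjugate), `alpha`.
#' @export
anisotropic_markov <- function(W, alpha = 1) {
  stopifnot(alpha >= 0, alpha <= 1)
  q <- Matrix::rowSums(W)
  if (any(q == 0))
    stop("validation error: isolated cell(s) with no affinity: ",
         paste(utils::head(which(q == 0), 10), collapse = ", "), call. = FALSE)
  Wt <- if (alpha > 0) {
    qa <- q^(-alpha)
    Matrix::Diagonal(x = qa) %*% W %*% Matrix::Diagonal(x = qa)
  } else W
  d <- Matrix::rowSums(Wt)
  P <- Matrix::Diagonal(x = 1 / d) %*% Wt
  structure(list(P = methods::as(P, "CsparseMatrix"), degrees = as.numeric(d),
                 alpha = alpha),
            class = "diffusion_operator")
}

#' @exportS3Method print diffusion_operator
print.diffusion_operator <- function(x, ...) {
  cat(sprintf("diffusion_operator: %d x %d, alpha = %g, %d nonzeros\n",
              nrow(x$P), ncol(x$P), x$alpha, length(x$P@x)))
  invisible(x)
}

#' Top eigenpairs of a diffusion operator
#'
#' Solves the symmetric conjugate `S = D^{1/2} P D^{-1/2}` (identical
#' spectrum, real by construction) and maps eigenvectors back to those of
#' `P`. Eigenvalues are returned in decreasing order; eigenvectors are
#' unit-norm with sign fixed so the largest-magnitude entry is positive.
#' A plain row-stochastic matrix is accepted, in which case the conjugation
#' weights are its stationary distribution (the operator must be reversible,
#' as every kernel-derived operator here is).
#'
#' @param op a `diffusion_operator` (or a row-stochastic matrix).
#' @param N number of eigenpairs (`N < n`).
#' @return list with `values` (length N) and `vectors` (n x N).
#' @export
eigendecompose <- function(op, N) {
  if (inherits(op, "diffusion_operator")) {
    P <- op$P; d <- op$degrees
  } else {
    P <- methods::as(methods::as(op, "generalMatrix"), "CsparseMatrix")
    d <- stationary_distribution(P)
  }
  n <- nrow(P)
  stopifnot(N <= n)
  rt <- sqrt(d)
  S <- Matrix::Diagonal(x = rt) %*% P %*% Matrix::Diagonal(x = 1 / rt)
  S <- (S + Matrix::t(S)) / 2              # clean round-off asymmetry
  if (n <= 64 || N >= n - 1) {
    es <- eigen(as.matrix(S), symmetric = TRUE)
    vals <- es$values[seq_len(N)]
    vecs <- es$vectors[, seq_len(N), drop = FALSE]
  } else {
    es <- tryCatch(
      RSpectra::eigs_sym(S, k = N, which = "LA"),
      error = function(e) stop("numerical error: eigendecomposition failed: ",
                               conditionMessage(e), call. = FALSE))
    if (length(es$values) < N)
      stop("numerical error: eigensolver converged for only ",
           length(es$values), " of ", N, " pairs", call. = FALSE)
    ord <- order(es$values, decreasing = TRUE)
    vals <- es$values[ord]
    vecs <- es$vectors[, ord, drop = FALSE]
  }
  vecs <- vecs / rt                        # conjugate back to eigenvectors of P
  nrm <- sqrt(colSums(vecs^2))
  vecs <- sweep(vecs, 2, nrm, "/")
  for (j in seq_len(ncol(vecs))) {
    k <- which.max(abs(vecs[, j]))
    if (vecs[k, j] < 0) vecs[, j] <- -vecs[, j]
  }
  list(values = as.numeric(vals), vectors = vecs)
}

stationary_distribution <- function(P, iter = 2000, tol = 1e-13) {
  n <- nrow(P)
  pi0 <- rep(1 / n, n)
  for (i in seq_len(iter)) {
    pi1 <- as.numeric(Matrix::crossprod(P, pi0))
    pi1 <- pi1 / sum(pi1)
    if (max(abs(pi1 - pi0)) < tol) break
    pi0 <- pi1
  }
  pi1
}

#' Multiscale diffusion components with eigengap selection
#'
#' Drops the trivial leading eigenpair, weights each remaining eigenvector
#' by `lambda / (1 - lambda)` — the closed-form sum of its contribution over
#' random walks of every length — and selects the number of structure
#' components at the largest consecutive eigengap of the nontrivial
#' spectrum, floored at 2. Eigenvalues at or above `1 - 1e-9` are capped
#' there before weighting.
#'
#' @param values eigenvalues, decreasing, `values[1]` within 1e-6 of 1.
#' @param vectors matching eigenvectors (columns).
#' @param selected_m optional manual override of the component count.
#' @param params optional parameter list echoed into the result.
#' @return object of class `diffusion_space`: list with `eigenvalues`
#'   (full spectrum), `components` (n x (N-1) multiscale-weighted nontrivial
#'   eigenvectors), `selected_m`, `gap_warning`, `params`.
#' @export
multiscale_select <- function(values, vectors, selected_m = NULL,
                              params = NULL) {
  N <- length(values)
  if (N < 3) stop("validation error: need at least 3 eigenpairs, got ", N,
                  call. = FALSE)
  stopifnot(abs(values[1] - 1) <= 1e-6)
  lam <- values[-1]
  vec <- vectors[, -1, drop = FALSE]
  lam_c <- pmin(lam, 1 - 1e-9)
  comp <- sweep(vec, 2, lam_c / (1 - lam_c), "*")
  gaps <- lam[-length(lam)] - lam[-1]
  gap_warning <- FALSE
  if (is.null(selected_m)) {
    # uniform decay has no informative gap: fall back to the floor
    if (max(gaps) - min(gaps) < 1e-9) {
      selected_m <- 2L
      gap_warning <- TRUE
    } else {
      selected_m <- which.max(gaps)
    }
  }
  selected_m <- min(max(selected_m, 2L), ncol(comp))
  structure(list(eigenvalues = values, components = comp,
                 selected_m = as.integer(selected_m),
                 gap_warning = gap_warning, params = params),
            class = "diffusion_space")
}

#' Fit an adaptive anisotropic diffusion embedding
#'
#' The core estimator: builds the exact kNN graph on the input matrix,
#' forms the density-adaptive Gaussian affinity, normalizes it
#' anisotropically into a Markov diffusion operator, extracts the top `N`
#' eigenpairs, weights the nontrivial eigenvectors by their multiscale
#' random-walk factor and selects the structure components at the dominant
#' eigengap. The result is deterministic for fixed input and parameters.
#'
#' The intended input is the scaled highly-variable-gene matrix from
#' [preprocess()] (in place of a PCA basis), but any numeric matrix of
#' observations in rows is accepted.
#'
#' @param X numeric matrix (cells x features), e.g. `preprocess(x)$scaled$values`.
#' @param N number of diffusion components to compute (default 50, reduced
#'   to `n - 2` on small inputs).
#' @param K nearest neighbors per cell (default 15).
#' @param metric `"euclidean"` (default) or `"cosine"`.
#' @param alpha anisotropy exponent (default 1: Laplace-Beltrami limit).
#' @param bandwidth_rank neighbor rank setting each cell's kernel bandwidth
#'   (default `ceiling(K/2)`).
#' @param selected_m optional manual override of the eigengap selection.
#' @return a `diffusion_space` (see [multiscale_select()]) whose `params`
#'   echoes the call and with the diffusion operator attached as
#'   `$operator`.
#' @export
dbmap <- function(X, N = 50, K = 15, metric = c("euclidean", "cosine"),
                  alpha = 1, bandwidth_rank = NULL, selected_m = NULL) {
  metric <- match.arg(metric)
  X <- as.matrix(X)
  n <- nrow(X)
  N <- min(N, n - 2L)
  stopifnot(N >= 3, K >= 2, K < n)
  g <- build_knn(X, K, metric)
  W <- adaptive_affinity(g, bandwidth_rank)
  op <- anisotropic_markov(W, alpha)
  eig <- eigendecompose(op, N)
  sp <- multiscale_select(eig$values, eig$vectors, selected_m = selected_m,
                          params = list(N = N, K = K, metric = metric,
                                        alpha = alpha,
                                        bandwidth_rank = bandwidth_rank))
  sp$operator <- op
  sp
}

#' @exportS3Method print diffusion_space
print.diffusion_space <- function(x, ...) {
  cat(sprintf("diffusion_space: %d cells, %d components (%d selected at eigengap)\n",
              nrow(x$components), ncol(x$components), x$selected_m))
  cat("  leading eigenvalues:",
      paste(sprintf("%.4f", utils::head(x$eigenvalues, 6)), collapse = ", "),
      "\n")
  if (isTRUE(x$gap_warning))
    cat("  note: no dominant eigengap; floor of 2 components applied\n")
  invisible(x)
}

#' @exportS3Method summary diffusion_space
summary.diffusion_space <- function(object, ...) {
  lam <- object$eigenvalues[-1]
  gaps <- lam[-length(lam)] - lam[-1]
  out <- list(n = nrow(object$components),
              n_components = ncol(object$components),
              selected_m = object$selected_m,
              eigenvalues = object$eigenvalues,
              gaps = gaps, params = object$params)
  class(out) <- "summary.diffusion_space"
  out
}

#' @exportS3Method print summary.diffusion_space
print.summary.diffusion_space <- function(x, ...) {
  cat(sprintf("Diffusion embedding of %d cells\n", x$n))
  cat(sprintf("  components computed: %d, selected by eigengap: %d\n",
              x$n_components, x$selected_m))
  cat("  nontrivial eigengaps:",
      paste(sprintf("%.4f", utils::head(x$gaps, 8)), collapse = ", "), "\n")
  invisible(x)
}

#' Selected structure components of a diffusion space
#'
#' @param space a `diffusion_space`.
#' @param all return all computed components instead of the eigengap
#'   selection.
#' @return numeric matrix of multiscale components.
#' @export
structure_components <- function(space, all = FALSE) {
  stopifnot(inherits(space, "diffusion_space"))
  if (all) space$components
  else space$components[, seq_len(space$selected_m), drop = FALSE]
}
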