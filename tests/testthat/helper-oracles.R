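# Shared fixtures (cached across test files) and independent oracles.

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# branching-lineage study fixture: 3000 cells x 1500 genes, 3 branches
branching_fixture <- function() {
  cached("branching", function() {
    sim <- simulate_branching_counts(3000, 1500, 3, fold = 4, seed = 5)
    pp <- preprocess(sim$counts,
                     run_config(list(preprocess = list(n_hvg = 800))))
    sp <- dbmap(pp$scaled$values, N = 30, K = 15)
    list(sim = sim, pp = pp, sp = sp)
  })
}

# 5-cluster marker study fixture: 2000 cells x 1000 genes, 4-fold markers
cluster_fixture <- function() {
  cached("cluster", function() {
    sim <- simulate_cluster_counts(2000, 1000, 5, markers_per_cluster = 20,
                                   fold = 4, seed = 7)
    pp <- preprocess(sim$counts,
                     run_config(list(preprocess = list(n_hvg = 500))))
    sp <- dbmap(pp$scaled$values, N = 30, K = 15)
    part <- cluster_cells(sp, seed = 1)
    list(sim = sim, pp = pp, sp = sp, part = part)
  })
}

# Fisher-Lee circular correlation: rotation/reflection invariant up to sign
circ_cor_fl <- function(a, b) {
  sa <- outer(a, a, "-"); sb <- outer(b, b, "-")
  sum(sin(sa) * sin(sb)) / sqrt(sum(sin(sa)^2) * sum(sin(sb)^2))
}

# brute-force kNN oracle over the full distance matrix
knn_oracle <- function(X, K) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  diag(D) <- Inf
  idx <- t(vapply(seq_len(n),
                  function(i) order(D[i, ], seq_len(n))[seq_len(K)],
                  integer(K)))
  list(indices = idx,
       distances = t(vapply(seq_len(n), function(i) D[i, idx[i, ]],
                            numeric(K))))
}

# exhaustive chord-distance knee oracle on the sorted log10 curve
knee_oracle <- function(values) {
  s <- sort(values, decreasing = TRUE)
  y <- log10(s); x <- seq_along(y); n <- length(y)
  best <- 1; bestd <- -1
  for (i in seq_len(n)) {
    # area of triangle (first, last, i) over chord length
    d <- abs((x[n] - x[1]) * (y[i] - y[1]) - (y[n] - y[1]) * (x[i] - x[1])) /
      sqrt((x[n] - x[1])^2 + (y[n] - y[1])^2)
    if (d > bestd) { bestd <- d; best <- i }
  }
  s[best]
}

# exact two-sided Wilcoxon rank-sum p by enumeration over value assignments
wilcox_oracle <- function(x, y) {
  n1 <- length(x); pooled <- c(x, y); n <- length(pooled)
  r <- rank(pooled)
  obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * (n - n1) / 2
  sets <- utils::combn(n, n1)
  stats <- apply(sets, 2, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
}

# dense absorbing-chain oracle: row-normalize, solve (I-Q)B = R directly
absorption_oracle <- function(P, absorbing) {
  P <- as.matrix(P)
  n <- nrow(P)
  trans <- setdiff(seq_len(n), absorbing)
  Pn <- P / rowSums(P)
  Q <- Pn[trans, trans, drop = FALSE]
  R <- Pn[trans, absorbing, drop = FALSE]
  B <- matrix(0, n, length(absorbing))
  B[cbind(absorbing, seq_along(absorbing))] <- 1
  B[trans, ] <- solve(diag(length(trans)) - Q, R)
  B
}

# post-branch-point assignment accuracy against simulator truth
branch_accuracy <- function(tr, truth) {
  post <- which(truth$pseudotime_true > 0.3 & truth$labels > 0)
  tb <- truth$labels[tr$terminal_cells]
  pred <- tb[max.col(tr$branch_probs[post, , drop = FALSE])]
  mean(pred == truth$labels[post])
}

make_lognorm <- function(values, symbols = NULL) {
  if (is.null(symbols)) symbols <- paste0("g", seq_len(ncol(values)))
  expression_matrix(values, "lognorm",
                    barcodes = paste0("c", seq_len(nrow(values))),
                    features = data.frame(id = symbols, symbol = symbols))
}
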