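test_that("exact kNN matches hand instances and the all-pairs oracle", {
  X <- matrix(c(0, 1, 3), 3, 1)
  g <- build_knn(X, 2)
  expect_equal(g$indices[1, ], c(2L, 3L))
  expect_equal(g$distances[1, ], c(1, 3))
  # duplicated point: nearest distance 0
  gd <- build_knn(matrix(c(0, 0, 5), 3, 1), 1)
  expect_equal(gd$distances[1, 1], 0)
  expect_error(build_knn(X, 3), "validation error")
  set.seed(10)
  Y <- matrix(rnorm(500 * 5), 500, 5)
  g2 <- build_knn(Y, 10)
  or <- knn_oracle(Y, 10)
  expect_identical(g2$indices, or$indices)
  expect_equal(g2$distances, unname(or$distances), tolerance = 1e-12)
  # the tree-search path used above n = 2000 agrees with the oracle too
  set.seed(11)
  Z <- matrix(rnorm(2100 * 3), 2100, 3)
  g3 <- build_knn(Z, 5)
  or3 <- knn_oracle(Z, 5)
  expect_identical(g3$indices, or3$indices)
})

test_that("adaptive affinity follows the per-cell bandwidth formula", {
  g <- build_knn(matrix(c(0, 1, 3), 3, 1), 2)
  W <- adaptive_affinity(g, bandwidth_rank = 1)
  # sigma = (1, 1, 2); w(0,1) symmetric average = e^-1
  expect_equal(W[1, 2], exp(-1), tolerance = 1e-12)
  expect_equal(W[1, 3], (exp(-9) + exp(-9 / 4)) / 2, tolerance = 1e-12)
  expect_equal(W[2, 3], (exp(-4) + exp(-1)) / 2, tolerance = 1e-12)
  expect_true(Matrix::isSymmetric(W))
  expect_equal(Matrix::diag(W), rep(0, 3))
  # equidistant points: all off-diagonal affinities equal
  sq <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  We <- adaptive_affinity(build_knn(sq, 2), 1)
  offd <- We[upper.tri(We)]
  expect_equal(max(offd) - min(offd), 0, tolerance = 1e-12)
})

test_that("anisotropic normalization yields a row-stochastic operator", {
  set.seed(12)
  X <- matrix(rnorm(60 * 4), 60, 4)
  W <- adaptive_affinity(build_knn(X, 8))
  for (alpha in c(0, 0.5, 1)) {
    op <- anisotropic_markov(W, alpha)
    expect_lt(max(abs(Matrix::rowSums(op$P) - 1)), 1e-10)
    expect_true(all(op$P@x >= 0))
  }
  # complete graph with constant affinity: uniform transition 1/(n-1)
  Wc <- Matrix::Matrix(1, 4, 4); Matrix::diag(Wc) <- 0
  Pc <- anisotropic_markov(Wc, 1)$P
  expect_equal(as.numeric(Pc[1, -1]), rep(1 / 3, 3), tolerance = 1e-12)
  # alpha = 0 is plain row normalization
  P0 <- anisotropic_markov(W, 0)$P
  expect_equal(as.matrix(P0), as.matrix(W / Matrix::rowSums(W)),
               tolerance = 1e-12, ignore_attr = TRUE)
  # isolated vertex rejected
  Wi <- Matrix::sparseMatrix(i = 1, j = 2, x = 1, dims = c(3, 3),
                             symmetric = TRUE)
  expect_error(anisotropic_markov(Matrix::drop0(Wi), 1), "isolated")
})

test_that("eigendecomposition matches closed forms and a dense oracle", {
  P <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE)
  e <- eigendecompose(P, 2)   # reversible 2-state chain
  expect_equal(e$values, c(1, 0.7), tolerance = 1e-10)
  # top eigenvector of a stochastic matrix is constant-sign
  expect_true(all(e$vectors[, 1] > 0) || all(e$vectors[, 1] < 0))

  set.seed(13)
  X <- matrix(rnorm(150 * 4), 150, 4)
  op <- anisotropic_markov(adaptive_affinity(build_knn(X, 10)), 1)
  e2 <- eigendecompose(op, 8)
  dense <- eigen(as.matrix(op$P))
  expect_lt(max(abs(e2$values - sort(Re(dense$values),
                                     decreasing = TRUE)[1:8])), 1e-8)
  expect_true(all(e2$values > -1 & e2$values <= 1 + 1e-10))
  expect_equal(sum(e2$values > 1 - 1e-6), 1)   # connected: single unit eigenvalue
  # sign convention: largest-magnitude entry positive
  for (j in 1:8) expect_gt(e2$vectors[which.max(abs(e2$vectors[, j])), j], 0)

  # two disconnected blocks: two unit eigenvalues
  blob <- rbind(matrix(rnorm(40 * 2), 40, 2),
                matrix(rnorm(40 * 2) + 100, 40, 2))
  opb <- anisotropic_markov(adaptive_affinity(build_knn(blob, 5)), 1)
  eb <- eigendecompose(opb, 4)
  expect_equal(sum(eb$values > 1 - 1e-8), 2)
})

test_that("multiscale weighting and eigengap selection", {
  vals <- c(1, 0.95, 0.93, 0.40, 0.35)
  vecs <- matrix(rnorm(50 * 5), 50, 5)
  sp <- multiscale_select(vals, vecs)
  expect_equal(sp$selected_m, 2L)   # dominant gap 0.93 -> 0.40
  expect_equal(sp$components[, 1], vecs[, 2] * 0.95 / 0.05, tolerance = 1e-12)
  expect_equal(sp$components[, 3], vecs[, 4] * 0.4 / 0.6, tolerance = 1e-12)
  # lambda/(1-lambda) spot values
  expect_equal(0.5 / (1 - 0.5), 1)
  expect_equal(0.9 / (1 - 0.9), 9, tolerance = 1e-12)
  # uniform decay: floor 2 with warning
  uni <- multiscale_select(c(1, seq(0.9, 0.5, by = -0.1)),
                           matrix(rnorm(20 * 6), 20, 6))
  expect_equal(uni$selected_m, 2L)
  expect_true(uni$gap_warning)
  # manual override and floor
  expect_equal(multiscale_select(vals, vecs, selected_m = 3)$selected_m, 3L)
  expect_error(multiscale_select(c(1, 0.5), matrix(0, 5, 2)),
               "validation error")
})

test_that("dbmap is deterministic and equivariant to cell permutation", {
  set.seed(14)
  # two overlapping groups: connected graph, eigenvalues well below 1
  X <- rbind(matrix(rnorm(60 * 3), 60, 3),
             matrix(rnorm(60 * 3) + 2, 60, 3))
  a <- dbmap(X, N = 8, K = 8)
  b <- dbmap(X, N = 8, K = 8)
  expect_identical(a$components, b$components)
  expect_identical(a$eigenvalues, b$eigenvalues)
  perm <- sample(nrow(X))
  p <- dbmap(X[perm, ], N = 8, K = 8)
  expect_equal(p$eigenvalues, a$eigenvalues, tolerance = 1e-8)
  # compare the well-separated leading components (higher ones can be
  # near-degenerate and rotate freely)
  expect_equal(p$components[order(perm), 1:2], a$components[, 1:2],
               tolerance = 1e-6)
})

test_that("the embedding recovers a cyclic manifold's angle", {
  cc <- make_noisy_circle(400, 0.05, seed = 3)
  sp <- dbmap(cc$X, N = 10, K = 15)
  ang <- atan2(sp$components[, 2], sp$components[, 1])
  expect_gt(abs(circ_cor_fl(ang, cc$theta)), 0.95)
})

test_that("well-separated mixtures place the eigengap after >= 2 components", {
  gm <- make_gaussian_mixture(100, 3, 10, sep = 10, seed = 2)
  sp <- dbmap(gm$X, N = 10, K = 15)
  expect_gte(sp$selected_m, 2)
  lam <- sp$eigenvalues[-1]
  gaps <- lam[-length(lam)] - lam[-1]
  expect_gte(which.max(gaps), 2)
})
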