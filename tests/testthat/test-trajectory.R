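test_that("waypoint selection is farthest-point, saturating and deterministic", {
  comp <- matrix(c(0, 1, 10), 3, 1)
  expect_equal(select_waypoints(comp, 5, 1), 1:3)        # saturation
  expect_equal(select_waypoints(comp, 2, 1), c(1L, 3L))  # farthest point
  big <- matrix(rnorm(200), 100, 2)
  expect_identical(select_waypoints(big, 20, 7), select_waypoints(big, 20, 7))
  expect_true(7 %in% select_waypoints(big, 5, 7))        # start always kept
})

test_that("pseudotime on a unit path is the normalized path distance", {
  comp <- matrix(c(0, 1, 2), 3, 1)
  pt <- compute_pseudotime(comp, 1, k = 2, n_waypoints = 3)
  expect_equal(as.numeric(pt), c(0, 0.5, 1), tolerance = 1e-9)
  expect_equal(pt[1], 0)
  # disconnected graph is rejected
  far <- matrix(c(0, 1, 100, 101), 4, 1)
  expect_error(compute_pseudotime(far, 1, k = 1), "disconnected")
})

test_that("terminal detection finds the far end of a path and honors overrides", {
  comp <- matrix(seq(0, 20), 21, 1)
  pt <- compute_pseudotime(comp, 1, k = 3)
  term <- find_terminal_states(comp, pt, k = 3)
  expect_equal(term, 21L)
  expect_equal(find_terminal_states(comp, pt, terminal_cells = c(4, 9)),
               c(4L, 9L))
})

test_that("absorption probabilities solve the hand-built chain exactly", {
  P <- rbind(c(0.5, 0.3, 0.2), c(0, 1, 0), c(0, 0, 1))
  r <- absorption_probabilities(P, c(2, 3))
  expect_equal(r$branch_probs[1, ], c(0.6, 0.4), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(r$entropy[1], -(0.6 * log(0.6) + 0.4 * log(0.4)),
               tolerance = 1e-12)
  expect_equal(round(r$entropy[1], 4), 0.6730)
  # absorbing rows: probability 1 to themselves, entropy 0
  expect_equal(r$branch_probs[2, ], c(1, 0), ignore_attr = TRUE)
  expect_equal(r$entropy[2:3], c(0, 0))
  # single terminal on a connected forward chain: all mass absorbs there
  P2 <- rbind(c(0.5, 0.3, 0.2), c(0, 0.5, 0.5), c(0, 0, 1))
  r1 <- absorption_probabilities(P2, 3)
  expect_equal(as.numeric(r1$branch_probs), rep(1, 3))
  expect_equal(r1$entropy, rep(0, 3))
})

test_that("absorption matches a dense linear-solve oracle on random chains", {
  set.seed(41)
  for (rep in 1:10) {
    n <- sample(10:50, 1)
    P <- matrix(runif(n * n) * (matrix(runif(n * n), n, n) < 0.2), n, n)
    diag(P) <- runif(n)
    abs_cells <- sort(sample(n, 2))   # output columns follow sorted order
    P[, abs_cells[1]] <- P[, abs_cells[1]] + 0.05   # all states reach a sink
    P[abs_cells, ] <- 0
    P[cbind(abs_cells, abs_cells)] <- 1
    got <- absorption_probabilities(P, abs_cells)
    want <- absorption_oracle(P, abs_cells)
    expect_lt(max(abs(got$branch_probs - want)), 1e-10)
    expect_lt(max(abs(rowSums(got$branch_probs) - 1)), 1e-8)
    expect_true(all(got$entropy >= 0 & got$entropy <= log(2) + 1e-12))
  }
})

test_that("diffusion imputation is a contraction with exact fixed points", {
  set.seed(42)
  X <- matrix(rnorm(80 * 3), 80, 3)
  op <- anisotropic_markov(adaptive_affinity(build_knn(X, 8)), 1)
  vals <- cbind(rep(2.5, 80), rnorm(80), rexp(80))
  expr <- make_lognorm(vals)
  im1 <- impute_diffusion(op, expr, t = 1)
  # constant gene is a fixed point for any t
  expect_equal(im1$values[, 1], rep(2.5, 80), tolerance = 1e-12)
  im5 <- impute_diffusion(op, expr, t = 5)
  expect_equal(im5$values[, 1], rep(2.5, 80), tolerance = 1e-12)
  # t = 1 equals one explicit product
  expect_lt(max(abs(im1$values - as.matrix(op$P %*% vals))), 1e-12)
  # values stay within the observed range; variance shrinks with t
  v <- vals[, 3]
  prev <- var(v)
  for (t in 1:4) {
    im <- impute_diffusion(op, expr, t = t)
    expect_true(all(im$values[, 3] >= min(v) - 1e-12 &
                      im$values[, 3] <= max(v) + 1e-12))
    expect_lte(var(im$values[, 3]), prev + 1e-12)
    prev <- var(im$values[, 3])
  }
  expect_equal(im1$layer, "imputed")
})

test_that("imputation preserves the stationary-weighted gene mean", {
  set.seed(43)
  X <- matrix(rnorm(60 * 2), 60, 2)
  op <- anisotropic_markov(adaptive_affinity(build_knn(X, 6)), 1)
  pi0 <- rep(1 / 60, 60)
  for (i in 1:500) pi0 <- as.numeric(Matrix::crossprod(op$P, pi0))
  pi0 <- pi0 / sum(pi0)
  v <- rexp(60)
  im <- impute_diffusion(op, make_lognorm(cbind(v)), t = 3)
  expect_equal(sum(pi0 * im$values[, 1]), sum(pi0 * v), tolerance = 1e-10)
})

test_that("gene trends follow the branch-weighted kernel regression", {
  n <- 500
  pt <- seq(0, 1, length.out = n)
  # constant gene: constant trend
  tr <- gene_trends(rep(3, n), pt, grid = 50)
  expect_equal(tr$expression, rep(3, 50), tolerance = 1e-10)
  # identity gene: fitted curve tracks the diagonal away from boundaries
  tr2 <- gene_trends(pt, pt, grid = 100)
  inner <- tr2$pseudotime >= 0.1 & tr2$pseudotime <= 0.9
  expect_lt(max(abs(tr2$expression[inner] - tr2$pseudotime[inner])), 0.05)
  # weights select the branch the trend follows
  w <- as.numeric(pt > 0.5)
  expr_b <- ifelse(pt > 0.5, 2, 0)
  tr3 <- gene_trends(expr_b, pt, branch_weights = w, grid = 20)
  expect_gt(min(tr3$expression[tr3$pseudotime > 0.7]), 1.9)
  expect_error(gene_trends(pt, pt, branch_weights = rep(0, n)),
               "branch weights")
})

test_that("full trajectory recovers a 3-branch lineage", {
  fx <- branching_fixture()
  u <- fx$sim$truth$pseudotime_true
  tr <- suppressWarnings(
    run_trajectory(fx$sp, which.min(u), n_components = 10, k = 15,
                   n_waypoints = 500))
  expect_equal(length(tr$terminal_cells), 3)
  # one terminal per true leaf
  expect_setequal(fx$sim$truth$labels[tr$terminal_cells], 1:3)
  expect_gte(cor(tr$pseudotime, u, method = "spearman"), 0.9)
  expect_gte(branch_accuracy(tr, fx$sim$truth), 0.9)
  expect_lt(max(abs(rowSums(tr$branch_probs) - 1)), 1e-8)
  expect_equal(tr$entropy[tr$terminal_cells], rep(0, 3))
  expect_true(all(tr$entropy <= log(3) + 1e-9))
  expect_equal(tr$pseudotime[which.min(u)], 0)
})
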