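test_that("SNN edge weights are Jaccard overlaps with pruning", {
  # 1-D points: neighbor sets are fully predictable
  comp <- cbind(c(1, 2, 3, 4, 10, 11, 12, 13), 0)
  K_c <- 2
  g <- snn_graph(comp, K_c = K_c, prune = 0)
  # independent oracle: recompute Jaccard of (self + 2NN) sets
  D <- as.matrix(dist(comp)); diag(D) <- Inf
  sets <- lapply(1:8, function(i) c(i, order(D[i, ])[1:K_c]))
  w_or <- function(i, j) {
    o <- length(intersect(sets[[i]], sets[[j]]))
    o / length(union(sets[[i]], sets[[j]]))
  }
  el <- igraph::as_data_frame(g)
  for (r in seq_len(nrow(el))) {
    i <- as.integer(el$from[r]); j <- as.integer(el$to[r])
    expect_equal(el$weight[r], w_or(i, j), tolerance = 1e-12)
  }
  # all positive-overlap pairs present when prune = 0
  pos <- sum(vapply(1:7, function(i)
    sum(vapply((i + 1):8, function(j) w_or(i, j) > 0, TRUE)), 0L))
  expect_equal(nrow(el), pos)
  # pruning removes weak edges
  gp <- snn_graph(comp, K_c = K_c, prune = 0.9)
  expect_lt(igraph::ecount(gp), igraph::ecount(g))
})

test_that("modularity clustering separates disconnected cliques and removes singletons", {
  g <- igraph::disjoint_union(igraph::make_full_graph(100),
                              igraph::make_full_graph(100))
  g <- igraph::add_vertices(g, 1)          # isolated vertex
  igraph::V(g)$name <- seq_len(201)
  igraph::E(g)$weight <- 1
  part <- cluster_snn(g, resolution = 0.8, seed = 1)
  expect_equal(length(part$sizes), 2)
  expect_equal(as.numeric(part$sizes), c(100, 100))
  expect_true(is.na(part$labels[201]))     # singleton removed
  expect_equal(part$labels[1:100], rep(part$labels[1], 100))
  # defaults documented in the interface
  expect_equal(formals(cluster_snn)$resolution, 0.8)
  expect_equal(formals(cluster_cells)$resolution, 0.8)
})

test_that("wilcoxon rank-sum matches enumeration exactly and approximately", {
  r <- wilcox_rank_sum(c(5, 6, 7), c(1, 2, 3))
  expect_equal(r$p_value, 0.1)
  expect_equal(r$statistic, 9)
  set.seed(31)
  for (i in 1:20) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    x <- sample(1:6, n1, replace = TRUE)   # ties on purpose
    y <- sample(1:6, n2, replace = TRUE)
    expect_equal(wilcox_rank_sum(x, y)$p_value, wilcox_oracle(x, y),
                 tolerance = 1e-12)
  }
  # sizes 20-25: normal approximation within 0.01 of the exact p
  for (i in 1:10) {
    x <- rnorm(22); y <- rnorm(24) + 0.3
    exact <- stats::wilcox.test(x, y, exact = TRUE, correct = FALSE)$p.value
    expect_lt(abs(wilcox_rank_sum(x, y)$p_value - exact), 0.01)
  }
})

test_that("marker ranking computes fold changes, percentages and BH per cluster", {
  set.seed(32)
  vals <- matrix(log1p(rpois(60 * 20, 1)), 60, 20)
  vals[1:30, 1] <- log1p(rpois(30, 12))    # gene 1 marks cluster 1
  expr <- make_lognorm(vals)
  part <- structure(list(labels = rep(1:2, each = 30),
                         sizes = table(rep(1:2, each = 30)),
                         resolution = 0.8),
                    class = "cluster_partition")
  mk <- rank_markers(expr, part, min_pct = 0.1, min_logfc = 0.25)
  g1 <- mk[mk$cluster == 1, ]
  expect_equal(g1$gene[1], "g1")
  # hand-check the log fold change of gene 1 in cluster 1
  lf <- log(mean(expm1(vals[1:30, 1])) + 1) -
    log(mean(expm1(vals[31:60, 1])) + 1)
  expect_equal(g1$log_fc[1], lf, tolerance = 1e-12)
  expect_equal(g1$pct_in[1], mean(vals[1:30, 1] > 0))
  # BH adjustment properties
  expect_true(all(mk$p_adjusted >= mk$p_value - 1e-15))
  expect_true(all(mk$p_adjusted <= 1))
  for (cl in unique(mk$cluster)) {
    sub <- mk[mk$cluster == cl, ]
    expect_equal(sub$p_adjusted,
                 stats::p.adjust(sub$p_value, "BH"), tolerance = 1e-12)
    expect_true(all(diff(sub$log_fc) <= 1e-12))   # sorted by log_fc
  }
  # a gene with identical distributions is excluded by the fold filter
  expect_false("g20" %in% g1$gene[abs(g1$log_fc) < 0.25])
  # top-2 helper returns the two largest fold changes per cluster
  t2 <- top_markers(mk, 2)
  expect_equal(sum(t2$cluster == 1), 2)
  expect_equal(t2$log_fc[t2$cluster == 1],
               sort(g1$log_fc, decreasing = TRUE)[1:2])
})

test_that("dot-plot statistics count expressing fractions per cluster", {
  vals <- matrix(0, 10, 3)
  vals[1:3, 1] <- 1                        # gene g1 in 3 of 10 cells
  expr <- make_lognorm(vals)
  part <- structure(list(labels = rep(1L, 10), sizes = table(rep(1, 10)),
                         resolution = 0.8), class = "cluster_partition")
  # single cluster is fine for dotplot statistics
  st <- dotplot_stats(expr, part, c("g1", "g2", "absent"))
  expect_equal(st$fraction_expressing[st$gene == "g1"], 0.3)
  expect_equal(st$mean_expression[st$gene == "g1"], 0.3)
  expect_equal(st$fraction_expressing[st$gene == "g2"], 0)
  expect_identical(attr(st, "missing"), "absent")
})

test_that("cell-cycle scores classify phases by the score rules", {
  set.seed(33)
  sim <- simulate_cluster_counts(600, 500, 3, markers_per_cluster = 15,
                                 fold = 4, seed = 9)
  ln <- lognormalize(sim$counts)
  s_genes <- sprintf("G%04d", 1:15)        # cluster-1 program = S signature
  g2m_genes <- sprintf("G%04d", 16:30)     # cluster-2 program = G2M signature
  cs <- score_cell_cycle(ln, s_genes, g2m_genes, seed = 4)
  expect_gte(mean(cs$phase[sim$truth$labels == 1] == "S"), 0.9)
  expect_gte(mean(cs$phase[sim$truth$labels == 2] == "G2M"), 0.9)
  # rule checks on synthetic scores via an all-zero matrix: G1 everywhere
  zero <- make_lognorm(matrix(0, 20, 40))
  cz <- score_cell_cycle(zero, paste0("g", 1:3), paste0("g", 4:6), seed = 1)
  expect_true(all(cz$phase == "G1"))
  expect_true(all(cz$s_score == 0 & cz$g2m_score == 0))
  expect_error(score_cell_cycle(zero, "nope", paste0("g", 4:6)),
               "validation error")
})

test_that("clusters without a specific program are flagged as doublet candidates", {
  set.seed(34)
  sim <- simulate_cluster_counts(400, 300, 2, markers_per_cluster = 15,
                                 fold = 4, seed = 17, lib_size_sd = 0)
  # build a third cluster by 50/50 averaging the two parent profiles
  cm <- sim$counts
  p1 <- which(sim$truth$labels == 1)[1:100]
  p2 <- which(sim$truth$labels == 2)[1:100]
  dbl <- floor((cm$counts[p1, ] + cm$counts[p2, ]) / 2)
  mixed <- count_matrix(rbind(cm$counts, dbl),
                        barcodes = c(cm$barcodes, paste0("dbl", 1:100)),
                        features = cm$features)
  labels <- c(sim$truth$labels, rep(3L, 100))
  part <- structure(list(labels = labels, sizes = table(labels),
                         resolution = 0.8), class = "cluster_partition")
  mk <- rank_markers(lognormalize(mixed), part)
  fl <- flag_doublet_clusters(mk, part, min_top_logfc = 0.5)
  expect_true(fl$doublet_candidate[fl$cluster == 3])
  expect_false(any(fl$doublet_candidate[fl$cluster %in% 1:2]))
  expect_false(any(flag_doublet_clusters(mk, part, 0)$doublet_candidate))
})

test_that("detected-gene counts are stable across clusters of a homogeneous mixture", {
  fx <- cluster_fixture()
  ng <- qc_metrics(fx$sim$counts)$ngenes
  per <- tapply(ng, fx$sim$truth$labels, mean)
  expect_lt((max(per) - min(per)) / mean(per), 0.10)
})
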