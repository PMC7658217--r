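#' Shared-nearest-neighbor graph on structure components
#'
#' Builds a kNN graph on the component matrix and reweights each edge by the
#' Jaccard overlap of the two endpoints' neighbor sets (each set including
#' the point itself); edges below the pruning threshold are dropped.
#'
#' @param components numeric matrix (cells x components, >= 2 columns), e.g.
#'   [structure_components()].
#' @param K_c neighbors per cell (default 20).
#' @param prune minimum Jaccard weight kept (default 1/15).
#' @return an [igraph::graph] (undirected, weighted) on the cells.
#' @export
snn_graph <- function(components, K_c = 20, prune = 1 / 15) {
  components <- as.matrix(components)
  stopifnot(ncol(components) >= 2, prune >= 0, prune < 1)
  n <- nrow(components)
  K_c <- min(K_c, n - 1)
  g <- build_knn(components, K_c, "euclidean")
  # neighbor sets as a sparse indicator (self included), Jaccard via counts
  A <- Matrix::sparseMatrix(i = c(rep(seq_len(n), each = K_c), seq_len(n)),
                            j = c(as.integer(t(g$indices)), seq_len(n)),
                            x = 1, dims = c(n, n))
  inter <- Matrix::tcrossprod(A)           # |S_i intersect S_j|
  inter <- methods::as(methods::as(inter, "generalMatrix"), "TsparseMatrix")
  sz <- K_c + 1
  keep <- inter@i < inter@j
  ii <- inter@i[keep] + 1L; jj <- inter@j[keep] + 1L
  jac <- inter@x[keep] / (2 * sz - inter@x[keep])
  ok <- jac >= prune
  igraph::graph_from_data_frame(
    data.frame(from = ii[ok], to = jj[ok], weight = jac[ok]),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
}

#' Modularity clustering of an SNN graph
#'
#' Louvain modularity optimization at the given resolution. Communities of
#' size 1 (and isolated vertices) are relabeled `NA` ("removed" singletons);
#' remaining clusters are renumbered 1, 2, ... by decreasing size.
#'
#' @param graph an [igraph::graph] as from [snn_graph()].
#' @param resolution modularity resolution (default 0.8; 0.3 merges into
#'   coarser main types).
#' @param seed integer seed for the optimizer.
#' @return object of class `cluster_partition`: list with `labels` (integer
#'   per cell, `NA` = removed singleton), `sizes` (named vector), and
#'   `resolution`.
#' @export
cluster_snn <- function(graph, resolution = 0.8, seed = 42) {
  stopifnot(igraph::vcount(graph) > 0, resolution > 0)
  set.seed(seed)
  cl <- igraph::cluster_louvain(graph, resolution = resolution)
  memb <- igraph::membership(cl)
  labels <- integer(igraph::vcount(graph))
  labels[as.integer(igraph::V(graph)$name)] <- as.integer(memb)
  tab <- table(labels)
  singles <- as.integer(names(tab)[tab < 2])
  labels[labels %in% singles] <- NA_integer_
  # renumber by decreasing size, ties by original id for determinism
  tab <- table(labels)
  ord <- order(-as.integer(tab), as.integer(names(tab)))
  remap <- stats::setNames(seq_along(ord), names(tab)[ord])
  labels <- unname(remap[as.character(labels)])
  structure(list(labels = as.integer(labels),
                 sizes = table(labels, useNA = "no"),
                 resolution = resolution, seed = seed),
            class = "cluster_partition")
}

#' @exportS3Method print cluster_partition
print.cluster_partition <- function(x, ...) {
  cat(sprintf("cluster_partition: %d cells, %d clusters (resolution %g), %d removed\n",
              length(x$labels), length(x$sizes), x$resolution,
              sum(is.na(x$labels))))
  invisible(x)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact p-value by enumeration of all group assignments when feasible
#' (handles ties exactly); tie-corrected normal approximation with
#' continuity correction otherwise.
#'
#' @param x,y numeric vectors for the two groups.
#' @param exact_limit maximum number of assignments enumerated (default 2e5).
#' @return list with `statistic` (U for group x) and `p_value`.
#' @export
wilcox_rank_sum <- function(x, y, exact_limit = 2e5) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (choose(n, n1) <= exact_limit) {
    combs <- utils::combn(n, n1)
    rs <- colSums(matrix(r[combs], nrow = n1))
    Us <- rs - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-9)
  } else {
    mu <- n1 * n2 / 2
    ties <- table(r)
    sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sig2 <= 0) return(list(statistic = U, p_value = 1))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(statistic = U, p_value = p)
}

#' One-vs-rest marker genes per cluster
#'
#' For every retained cluster, compares each gene's log-normalized
#' expression in the cluster against all remaining cells with a two-sided
#' Wilcoxon rank-sum test. Genes are pre-filtered on detection fraction and
#' fold change; the log fold change is
#' `ln(mean(expm1(in)) + 1) - ln(mean(expm1(out)) + 1)` (natural log,
#' pseudocount 1 on the de-logged scale). P-values are Benjamini-Hochberg
#' adjusted per cluster and rows sorted within cluster by decreasing
#' `log_fc`.
#'
#' @param expr an `expression_matrix` with layer `"lognorm"`.
#' @param partition a `cluster_partition` (>= 2 retained clusters).
#' @param min_pct minimum detection fraction in either group (default 0.1).
#' @param min_logfc minimum absolute log fold change (default 0.25).
#' @return a `data.frame` of class `marker_table` with columns `gene`,
#'   `cluster`, `log_fc`, `p_value`, `p_adjusted`, `pct_in`, `pct_out`.
#' @export
rank_markers <- function(expr, partition, min_pct = 0.1, min_logfc = 0.25) {
  stopifnot(inherits(expr, "expression_matrix"), expr$layer == "lognorm",
            inherits(partition, "cluster_partition"))
  labels <- partition$labels
  clusters <- sort(unique(labels[!is.na(labels)]))
  if (length(clusters) < 2)
    stop("validation error: need >= 2 retained clusters", call. = FALSE)
  m <- expr$values
  dense <- as.matrix(m)
  em <- expm1(dense)
  out <- list()
  for (cl in clusters) {
    inc <- which(!is.na(labels) & labels == cl)
    outc <- which(!is.na(labels) & labels != cl)
    if (length(inc) < 3) {
      warning("cluster ", cl, " has fewer than 3 cells; skipped")
      next
    }
    pct_in <- colMeans(dense[inc, , drop = FALSE] > 0)
    pct_out <- colMeans(dense[outc, , drop = FALSE] > 0)
    log_fc <- log(colMeans(em[inc, , drop = FALSE]) + 1) -
      log(colMeans(em[outc, , drop = FALSE]) + 1)
    pass <- which((pct_in >= min_pct | pct_out >= min_pct) &
                    abs(log_fc) >= min_logfc)
    if (!length(pass)) next
    pv <- vapply(pass, function(j)
      wilcox_rank_sum(dense[inc, j], dense[outc, j])$p_value, numeric(1))
    padj <- stats::p.adjust(pv, method = "BH")
    df <- data.frame(gene = expr$features$symbol[pass], cluster = cl,
                     log_fc = log_fc[pass], p_value = pv, p_adjusted = padj,
                     pct_in = pct_in[pass], pct_out = pct_out[pass],
                     stringsAsFactors = FALSE)
    out[[as.character(cl)]] <- df[order(-df$log_fc), ]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("marker_table", "data.frame")
  res
}

#' Top markers per cluster by log fold change
#'
#' @param markers a `marker_table`.
#' @param n_top markers kept per cluster (default 2).
#' @return subset of `markers` with the `n_top` largest `log_fc` rows per
#'   cluster.
#' @export
top_markers <- function(markers, n_top = 2) {
  stopifnot(inherits(markers, "marker_table"))
  res <- do.call(rbind, lapply(split(markers, markers$cluster), function(df)
    df[order(-df$log_fc)[seq_len(min(n_top, nrow(df)))], ]))
  rownames(res) <- NULL
  res
}

#' Dot-plot statistics for a gene panel
#'
#' The numeric content of an expression dot plot: per (cluster, gene), the
#' fraction of cluster cells expressing the gene above a threshold and the
#' mean log-normalized expression over the cluster.
#'
#' @param expr an `expression_matrix` with layer `"lognorm"` (or
#'   `"imputed"`).
#' @param partition a `cluster_partition`.
#' @param genes character vector of gene symbols; missing symbols are
#'   reported in `attr(, "missing")`, not fatal.
#' @param expr_threshold expression floor for "expressing" (default 0).
#' @return data.frame (cluster, gene, fraction_expressing, mean_expression).
#' @export
dotplot_stats <- function(expr, partition, genes, expr_threshold = 0) {
  stopifnot(inherits(expr, "expression_matrix"),
            inherits(partition, "cluster_partition"))
  idx <- match_symbols(expr$features, genes)
  if (length(attr(idx, "missing")))
    message("genes not in matrix: ",
            paste(attr(idx, "missing"), collapse = ", "))
  labels <- partition$labels
  clusters <- sort(unique(labels[!is.na(labels)]))
  rows <- list()
  for (cl in clusters) {
    cells <- which(!is.na(labels) & labels == cl)
    sub <- as.matrix(expr$values[cells, idx, drop = FALSE])
    rows[[as.character(cl)]] <- data.frame(
      cluster = cl, gene = expr$features$symbol[idx],
      fraction_expressing = colMeans(sub > expr_threshold),
      mean_expression = colMeans(sub), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  attr(res, "missing") <- attr(idx, "missing")
  res
}

#' Cell-cycle phase scores and classification
#'
#' Module score per cell for an S-phase and a G2/M gene set: the mean
#' expression of the set minus the mean of a seeded control set drawn, for
#' each set gene, as `n_ctrl` genes from the same average-expression bin
#' (`n_bins` equal-frequency bins over all genes). Phase is `G1` when both
#' scores are <= 0, otherwise the phase of the larger score.
#'
#' @param expr an `expression_matrix` with layer `"lognorm"`.
#' @param s_genes,g2m_genes character vectors of phase marker symbols.
#' @param n_bins expression bins for control matching (default 24).
#' @param n_ctrl control genes drawn per signature gene (default 100).
#' @param seed integer seed for the control draw.
#' @return data.frame (barcode, s_score, g2m_score, phase).
#' @export
score_cell_cycle <- function(expr, s_genes, g2m_genes, n_bins = 24,
                             n_ctrl = 100, seed = 42) {
  stopifnot(inherits(expr, "expression_matrix"))
  scores <- lapply(list(S = s_genes, G2M = g2m_genes), function(gs) {
    module_score(expr, gs, n_bins = n_bins, n_ctrl = n_ctrl, seed = seed)
  })
  s <- scores$S; g2m <- scores$G2M
  phase <- ifelse(s <= 0 & g2m <= 0, "G1", ifelse(s > g2m, "S", "G2M"))
  data.frame(barcode = expr$barcodes, s_score = s, g2m_score = g2m,
             phase = phase, stringsAsFactors = FALSE)
}

#' Expression-matched module score for a gene set
#'
#' @inheritParams score_cell_cycle
#' @param genes gene-set symbols; must intersect the matrix features.
#' @return numeric score per cell.
#' @export
module_score <- function(expr, genes, n_bins = 24, n_ctrl = 100, seed = 42) {
  idx <- match_symbols(expr$features, genes)
  if (!length(idx))
    stop("validation error: no gene-set members found in the matrix; missing: ",
         paste(attr(idx, "missing"), collapse = ", "), call. = FALSE)
  m <- expr$values
  avg <- Matrix::colMeans(m)
  n_bins_eff <- min(n_bins, max(1, length(unique(avg))))
  br <- unique(stats::quantile(avg, probs = seq(0, 1,
                                                length.out = n_bins_eff + 1)))
  bin <- if (length(br) < 2) factor(rep(1L, length(avg)))
         else cut(avg, breaks = br, include.lowest = TRUE)
  set.seed(seed)
  ctrl <- unlist(lapply(idx, function(j) {
    pool <- which(bin == bin[j])
    pool[sample.int(length(pool), min(n_ctrl, length(pool)))]
  }))
  sig <- Matrix::rowMeans(m[, idx, drop = FALSE])
  bg <- Matrix::rowMeans(m[, ctrl, drop = FALSE])
  as.numeric(sig - bg)
}

#' Flag candidate doublet clusters by marker absence
#'
#' A cluster whose best marker's log fold change falls below a threshold has
#' no specific expression program — the signature of a doublet-driven
#' mixture cluster. The flags are advisory; removal is an explicit user
#' decision.
#'
#' @param markers a `marker_table`.
#' @param partition a `cluster_partition` (supplies clusters with no
#'   passing marker at all, which are always flagged when
#'   `min_top_logfc > 0`).
#' @param min_top_logfc threshold on the best marker log fold change
#'   (default 0.5); 0 flags nothing.
#' @return data.frame (cluster, top_logfc, doublet_candidate).
#' @export
flag_doublet_clusters <- function(markers, partition, min_top_logfc = 0.5) {
  stopifnot(inherits(partition, "cluster_partition"))
  clusters <- sort(unique(partition$labels[!is.na(partition$labels)]))
  best <- vapply(clusters, function(cl) {
    lf <- markers$log_fc[markers$cluster == cl]
    if (length(lf)) max(lf) else 0
  }, numeric(1))
  data.frame(cluster = clusters, top_logfc = best,
             doublet_candidate = if (min_top_logfc <= 0)
               rep(FALSE, length(clusters)) else best < min_top_logfc)
}

#' Cluster cells of a fitted diffusion embedding
#'
#' Convenience wrapper: SNN graph on the multiscale structure components of
#' a [dbmap()] fit, then modularity clustering. The graph is built on the
#' full computed component set (the structure space of the first stage);
#' the eigengap selection only governs layout and trajectory geometry.
#'
#' @param space a `diffusion_space`.
#' @param K_c neighbors for the cluster graph (default 20).
#' @param prune minimum SNN Jaccard weight (default 1/15).
#' @param resolution modularity resolution (default 0.8).
#' @param seed integer seed.
#' @return a `cluster_partition`.
#' @export
cluster_cells <- function(space, K_c = 20, prune = 1 / 15, resolution = 0.8,
                          seed = 42) {
  stopifnot(inherits(space, "diffusion_space"))
  g <- snn_graph(structure_components(space, all = TRUE), K_c = K_c,
                 prune = prune)
  cluster_snn(g, resolution = resolution, seed = seed)
}
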