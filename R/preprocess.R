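#' Per-cell quality-control metrics
#'
#' Computes the three standard droplet QC metrics: total counts (`nreads`),
#' number of detected genes (`ngenes`) and the percentage of counts on
#' mitochondrial genes (`mito_pc`), identified by a symbol prefix.
#'
#' @param x a `count_matrix`.
#' @param mito_prefix prefix identifying mitochondrial gene symbols
#'   (default `"MT-"`).
#' @return data.frame with columns `barcode`, `nreads`, `ngenes`, `mito_pc`.
#' @export
qc_metrics <- function(x, mito_prefix = "MT-") {
  validate_count_matrix(x)
  stopifnot(nzchar(mito_prefix))
  nreads <- Matrix::rowSums(x$counts)
  ngenes <- Matrix::rowSums(x$counts > 0)
  mito <- startsWith(x$features$symbol, mito_prefix)
  mreads <- if (any(mito)) Matrix::rowSums(x$counts[, mito, drop = FALSE])
            else numeric(nrow(x$counts))
  mito_pc <- ifelse(nreads > 0, 100 * mreads / nreads, 0)
  data.frame(barcode = x$barcodes, nreads = as.numeric(nreads),
             ngenes = as.numeric(ngenes), mito_pc = as.numeric(mito_pc),
             stringsAsFactors = FALSE)
}

#' Knee-point detection on a ranked log-scale metric curve
#'
#' Sorts a positive per-cell metric in decreasing order, takes log10, and
#' finds the rank at maximal perpendicular distance from the chord joining
#' the first and last points of the (rank, log10 value) curve. The value at
#' that rank is returned as a suggested lower filtering threshold. When the
#' curve is log-linear (no knee) or all values are equal, the returned value
#' carries `attr(, "warning") = TRUE`.
#'
#' @param values positive numeric vector, one entry per cell (length >= 3).
#' @return the threshold value, with attributes `index` (rank of the knee on
#'   the sorted curve) and `warning` (no usable knee).
#' @export
detect_knee <- function(values) {
  stopifnot(length(values) >= 3, all(values > 0))
  s <- sort(values, decreasing = TRUE)
  if (max(s) == min(s)) {
    out <- min(s)
    attr(out, "index") <- length(s)
    attr(out, "warning") <- TRUE
    return(out)
  }
  y <- log10(s)
  x <- seq_along(y)
  d <- chord_distances(x, y)
  i <- which.max(d)
  out <- s[i]
  attr(out, "index") <- i
  # a log-linear curve has essentially zero interior distance: no knee
  attr(out, "warning") <- max(d) < 1e-6 * abs(y[1] - y[length(y)])
  out
}

# perpendicular distance of each point to the chord from first to last point
chord_distances <- function(x, y) {
  n <- length(x)
  dx <- x[n] - x[1]; dy <- y[n] - y[1]
  abs(dx * (y - y[1]) - dy * (x - x[1])) / sqrt(dx^2 + dy^2)
}

#' Filter cells on QC thresholds
#'
#' Keeps exactly the cells satisfying every threshold that is set (`NA`
#' thresholds are ignored); genes are never removed and cell order is
#' preserved.
#'
#' @param x a `count_matrix`.
#' @param min_nreads,max_nreads bounds on total counts.
#' @param min_ngenes,max_ngenes bounds on detected genes.
#' @param max_mito_pc ceiling on mitochondrial percentage (0-100).
#' @param mito_prefix symbol prefix for mitochondrial genes.
#' @return list with `matrix` (filtered `count_matrix`) and `keep`
#'   (logical per input cell).
#' @export
apply_qc <- function(x, min_nreads = NA, max_nreads = NA, min_ngenes = NA,
                     max_ngenes = NA, max_mito_pc = NA, mito_prefix = "MT-") {
  for (nm in c("min_nreads", "min_ngenes")) {
    lo <- get(nm); hi <- get(sub("min", "max", nm))
    if (!is.na(lo) && !is.na(hi) && lo > hi)
      stop("validation error: ", nm, " exceeds its upper bound", call. = FALSE)
  }
  if (!is.na(max_mito_pc))
    stopifnot(max_mito_pc >= 0, max_mito_pc <= 100)
  qc <- qc_metrics(x, mito_prefix)
  keep <- rep(TRUE, nrow(qc))
  binding <- character(0)
  chk <- function(keep, ok, label) {
    if (!any(keep & ok)) binding <<- c(binding, label)
    keep & ok
  }
  if (!is.na(min_nreads)) keep <- chk(keep, qc$nreads >= min_nreads, "min_nreads")
  if (!is.na(max_nreads)) keep <- chk(keep, qc$nreads <= max_nreads, "max_nreads")
  if (!is.na(min_ngenes)) keep <- chk(keep, qc$ngenes >= min_ngenes, "min_ngenes")
  if (!is.na(max_ngenes)) keep <- chk(keep, qc$ngenes <= max_ngenes, "max_ngenes")
  if (!is.na(max_mito_pc)) keep <- chk(keep, qc$mito_pc <= max_mito_pc, "max_mito_pc")
  if (!any(keep))
    stop("validation error: no cells survive QC; binding constraint(s): ",
         paste(binding, collapse = ", "), call. = FALSE)
  list(matrix = subset_cells(x, cells = which(keep)), keep = keep)
}

#' Log-normalize counts by a per-cell size factor
#'
#' Each count is scaled so every cell totals `size_factor` and then
#' log1p-transformed: `value = ln(1 + count * size_factor / cell_total)`.
#' The sparsity pattern is preserved.
#'
#' @param x a `count_matrix` with no zero-total cells (apply QC first).
#' @param size_factor normalization target, default 10000 counts per cell.
#' @return an `expression_matrix` with layer `"lognorm"`.
#' @export
lognormalize <- function(x, size_factor = 10000) {
  validate_count_matrix(x)
  stopifnot(size_factor > 0)
  totals <- Matrix::rowSums(x$counts)
  if (any(totals == 0))
    stop("validation error: zero-total cell(s): ",
         paste(utils::head(x$barcodes[totals == 0], 5), collapse = ", "),
         call. = FALSE)
  m <- x$counts
  m@x <- log1p(m@x * size_factor / totals[m@i + 1L])
  expression_matrix(m, "lognorm", x$barcodes, x$features)
}

#' Select highly variable genes by binned normalized dispersion
#'
#' Computes per-gene mean and dispersion (variance/mean) on the `expm1`
#' scale of log-normalized values, bins genes into `n_mean_bins`
#' equal-frequency mean bins, z-standardizes dispersion within each bin, and
#' returns the top `n_hvg` genes by standardized dispersion. Zero-variance
#' genes are never ranked ahead of a positive-dispersion gene; ties break by
#' gene index.
#'
#' @param expr an `expression_matrix` with layer `"lognorm"`.
#' @param n_hvg number of genes to select (default 5000).
#' @param n_mean_bins number of mean bins (default 20).
#' @return integer vector of gene column indices ranked by decreasing
#'   standardized dispersion; `attr(, "warning")` set when fewer than
#'   `n_hvg` eligible genes exist.
#' @export
select_hvg <- function(expr, n_hvg = 5000, n_mean_bins = 20) {
  stopifnot(inherits(expr, "expression_matrix"), expr$layer == "lognorm",
            n_hvg >= 1, n_mean_bins >= 1)
  m <- expr$values
  e <- if (inherits(m, "sparseMatrix")) {
    tmp <- m; tmp@x <- expm1(tmp@x); tmp
  } else expm1(m)
  n <- nrow(e)
  mu <- Matrix::colMeans(e)
  ex2 <- Matrix::colMeans(e^2)
  v <- (ex2 - mu^2) * n / max(1, n - 1)
  disp <- ifelse(mu > 0, v / mu, 0)
  eligible <- which(mu > 0)
  if (length(eligible) < n_mean_bins)
    stop("validation error: fewer genes with nonzero mean (",
         length(eligible), ") than mean bins (", n_mean_bins, ")",
         call. = FALSE)
  # equal-frequency bins over eligible genes' means
  br <- unique(stats::quantile(mu[eligible],
                               probs = seq(0, 1, length.out = n_mean_bins + 1)))
  bin <- cut(mu[eligible], breaks = br, include.lowest = TRUE)
  z <- numeric(length(eligible))
  for (b in levels(bin)) {
    idx <- which(bin == b)
    dv <- disp[eligible[idx]]
    sdv <- stats::sd(dv)
    z[idx] <- if (is.na(sdv) || sdv == 0) 0 else (dv - mean(dv)) / sdv
  }
  # zero-dispersion genes must never outrank positive-dispersion ones
  z[disp[eligible] == 0] <- -Inf
  ord <- eligible[order(-z, eligible)]
  warn <- FALSE
  if (n_hvg > length(ord)) { warn <- TRUE; n_hvg <- length(ord) }
  out <- ord[seq_len(n_hvg)]
  attr(out, "warning") <- warn
  out
}

#' Z-score scale selected genes across cells
#'
#' Per selected gene: subtract the mean and divide by the population standard
#' deviation over all cells; zero-variance genes map to all zeros; results
#' are clipped to `[-clip, clip]`.
#'
#' @param expr an `expression_matrix` with layer `"lognorm"`.
#' @param genes nonempty integer vector of gene column indices.
#' @param clip maximum absolute scaled value (default 10).
#' @return an `expression_matrix` with layer `"scaled"` (dense), restricted
#'   to `genes`.
#' @export
scale_genes <- function(expr, genes, clip = 10) {
  stopifnot(inherits(expr, "expression_matrix"), expr$layer == "lognorm",
            length(genes) >= 1, clip > 0)
  m <- as.matrix(expr$values[, genes, drop = FALSE])
  n <- nrow(m)
  mu <- colMeans(m)
  sdev <- sqrt(pmax(0, colMeans(m^2) - mu^2))   # population sd
  z <- sweep(m, 2, mu, "-")
  pos <- sdev > 0
  z[, pos] <- sweep(z[, pos, drop = FALSE], 2, sdev[pos], "/")
  z[, !pos] <- 0
  z[z > clip] <- clip
  z[z < -clip] <- -clip
  expression_matrix(z, "scaled", expr$barcodes,
                    expr$features[genes, , drop = FALSE])
}

#' Run the standard preprocessing chain
#'
#' QC filtering (explicit thresholds, with optional knee-detected lower
#' bounds on `nreads`/`ngenes`), log-normalization, highly-variable-gene
#' selection and scaling, in one call.
#'
#' @param x a `count_matrix`.
#' @param config a `run_config` (or the output of [run_config()]).
#' @param auto_knee character vector among `c("nreads", "ngenes")`: metrics
#'   whose lower threshold should be knee-detected when not set explicitly.
#' @return list with `counts` (filtered), `lognorm`, `scaled`
#'   (`expression_matrix` objects), `hvg` (gene indices into the filtered
#'   matrix), `qc` (metrics of the input cells), `keep` (logical).
#' @export
preprocess <- function(x, config = run_config(), auto_knee = character(0)) {
  p <- config$preprocess
  qc <- qc_metrics(x, p$mito_prefix)
  if ("nreads" %in% auto_knee && is.na(p$min_nreads))
    p$min_nreads <- as.numeric(detect_knee(qc$nreads[qc$nreads > 0]))
  if ("ngenes" %in% auto_knee && is.na(p$min_ngenes))
    p$min_ngenes <- as.numeric(detect_knee(qc$ngenes[qc$ngenes > 0]))
  f <- apply_qc(x, p$min_nreads, p$max_nreads, p$min_ngenes, p$max_ngenes,
                p$max_mito_pc, p$mito_prefix)
  ln <- lognormalize(f$matrix, p$size_factor)
  hvg <- select_hvg(ln, n_hvg = min(p$n_hvg, ncol(ln$values)),
                    n_mean_bins = p$n_mean_bins)
  sc <- scale_genes(ln, hvg, clip = p$scale_clip)
  list(counts = f$matrix, lognorm = ln, scaled = sc, hvg = hvg, qc = qc,
       keep = f$keep)
}
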