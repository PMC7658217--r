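#' Read a 10x-style Matrix Market directory
#'
#' Reads `matrix.mtx`, `barcodes.tsv` and `features.tsv` (or `genes.tsv`),
#' each optionally gzip-compressed, from a directory and returns a
#' [count_matrix()] with cells as rows. On disk the 10x convention stores
#' genes as rows and cells as columns; orientation is detected by matching
#' the matrix dimensions against the barcode and feature counts and the
#' matrix is transposed when needed, so the result is always cells x genes.
#'
#' @param path directory containing the three files.
#' @return a `count_matrix`.
#' @export
read_mtx_dir <- function(path) {
  if (!dir.exists(path)) stop("input error: no such directory: ", path,
                              call. = FALSE)
  mtx <- find_member(path, c("matrix.mtx", "matrix.mtx.gz"))
  bcf <- find_member(path, c("barcodes.tsv", "barcodes.tsv.gz"))
  ftf <- find_member(path, c("features.tsv", "features.tsv.gz",
                             "genes.tsv", "genes.tsv.gz"))
  m <- Matrix::readMM(mtx)
  if (methods::is(m, "nMatrix"))   # zero-entry/pattern file
    m <- methods::as(m, "dMatrix") * 1
  if (length(m@x) && any(abs(m@x - round(m@x)) > 1e-8))
    stop("validation error: non-integer values in ", mtx, call. = FALSE)
  barcodes <- read_lines_tsv(bcf)[[1]]
  if (anyDuplicated(barcodes))
    stop("validation error: duplicate barcodes in ", bcf, call. = FALSE)
  ft <- read_lines_tsv(ftf)
  # 1 col: id only; 2: id+symbol; 3+: id+symbol+type (extra columns ignored)
  features <- data.frame(id = ft[[1]],
                         symbol = if (ncol(ft) >= 2) ft[[2]] else ft[[1]],
                         stringsAsFactors = FALSE)
  if (nrow(m) == nrow(features) && ncol(m) == length(barcodes)) {
    m <- Matrix::t(m)                      # genes x cells on disk (10x)
  } else if (!(nrow(m) == length(barcodes) && ncol(m) == nrow(features))) {
    stop("validation error: matrix dimensions (", nrow(m), " x ", ncol(m),
         ") match neither orientation of ", length(barcodes), " barcodes x ",
         nrow(features), " features", call. = FALSE)
  }
  count_matrix(m, barcodes = barcodes, features = features)
}

find_member <- function(path, candidates) {
  for (f in candidates) {
    p <- file.path(path, f)
    if (file.exists(p)) return(p)
  }
  stop("input error: missing file, looked for ",
       paste(candidates, collapse = " or "), " in ", path, call. = FALSE)
}

read_lines_tsv <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  on.exit(close(con), add = TRUE)
  lines <- readLines(con)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(data.frame(V1 = character(0), stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- max(lengths(parts))
  out <- lapply(seq_len(ncols), function(j)
    vapply(parts, function(p) if (length(p) >= j) p[[j]] else p[[1]], ""))
  as.data.frame(out, col.names = paste0("V", seq_len(ncols)),
                stringsAsFactors = FALSE)
}

#' Write a count_matrix as a Matrix Market directory
#'
#' Emits `matrix.mtx` (genes x cells, the 10x on-disk convention),
#' `barcodes.tsv` and `features.tsv`, readable by [read_mtx_dir()].
#'
#' @param x a `count_matrix`.
#' @param path output directory, created if needed.
#' @return `path`, invisibly.
#' @export
write_mtx_dir <- function(x, path) {
  validate_count_matrix(x)
  if (!dir.exists(path) && !dir.create(path, recursive = TRUE))
    stop("I/O error: cannot create directory ", path, call. = FALSE)
  m <- Matrix::t(x$counts)
  dimnames(m) <- NULL
  Matrix::writeMM(m, file.path(path, "matrix.mtx"))
  writeLines(x$barcodes, file.path(path, "barcodes.tsv"))
  ft <- x$features
  writeLines(paste(ft$id, ft$symbol, "Gene Expression", sep = "\t"),
             file.path(path, "features.tsv"))
  invisible(path)
}

#' Read a dense count table (TSV/CSV)
#'
#' Expects a header row of gene symbols and a first column of cell barcodes.
#'
#' @param path file path; comma separation inferred from a `.csv` extension.
#' @return a `count_matrix`.
#' @export
read_dense_counts <- function(path) {
  if (!file.exists(path)) stop("input error: no such file: ", path,
                               call. = FALSE)
  sep <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                           check.names = FALSE)
  count_matrix(as.matrix(tab), barcodes = rownames(tab),
               features = colnames(tab))
}

#' Read a gene set file
#'
#' One symbol per line; `#` starts a comment; duplicates dropped keeping the
#' first occurrence; case preserved.
#'
#' @param path file path.
#' @return character vector of symbols in file order.
#' @export
read_gene_set <- function(path) {
  if (!file.exists(path)) stop("input error: no such file: ", path,
                               call. = FALSE)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  lines <- lines[!duplicated(lines)]
  if (!length(lines))
    stop("validation error: gene set file contains no symbols: ", path,
         call. = FALSE)
  lines
}

#' Read a flat key=value configuration file
#'
#' Sections are introduced by `[name]` headers; keys within a section are
#' returned as `name$key`. Values are converted to numeric where possible and
#' to logical for `true`/`false`. Unknown keys are kept, so the per-dataset
#' thresholds and embedding parameters of a run can be supplied freely.
#'
#' @param path file path.
#' @return nested named list of sections.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("input error: no such file: ", path,
                               call. = FALSE)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  cfg <- list(); section <- "global"
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      next
    }
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("validation error: malformed config line: ", ln,
                             call. = FALSE)
    key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    if (!is.na(num)) val <- num
    else if (tolower(val) %in% c("true", "false")) val <- tolower(val) == "true"
    cfg[[section]][[key]] <- val
  }
  cfg
}

#' Assemble a validated run configuration
#'
#' Merges user-supplied values (e.g. from [read_config()]) over the package
#' defaults for every stage and validates the invariants of each block.
#'
#' @param config nested list as returned by [read_config()]; may be empty.
#' @return a named list with elements `preprocess`, `dbmap`, `cluster`,
#'   `trajectory`, `seed`, `log_level`, of class `run_config`.
#' @export
run_config <- function(config = list()) {
  defaults <- list(
    preprocess = list(size_factor = 10000, n_hvg = 5000, n_mean_bins = 20,
                      scale_clip = 10, min_nreads = NA, max_nreads = NA,
                      min_ngenes = NA, max_ngenes = NA, max_mito_pc = NA,
                      mito_prefix = "MT-"),
    dbmap = list(N = 50, K = 15, M = 0.3, S = 1.0, metric = "euclidean",
                 alpha = 1, bandwidth_rank = NA),
    cluster = list(K_c = 20, prune = 1 / 15, resolution = 0.8),
    trajectory = list(n_components = 10, k = 15, n_waypoints = 500,
                      t_impute = 3, trend_grid = 500, tol = 1e-3),
    seed = 42, log_level = "info")
  for (s in names(config)) {
    if (s %in% c("seed", "log_level")) next
    for (k in names(config[[s]])) defaults[[s]][[k]] <- config[[s]][[k]]
  }
  if (!is.null(config$global$seed)) defaults$seed <- config$global$seed
  if (!is.null(config$global$log_level))
    defaults$log_level <- config$global$log_level
  p <- defaults$preprocess
  stopifnot(p$size_factor > 0, p$n_hvg >= 1, p$n_mean_bins >= 1,
            p$scale_clip > 0)
  if (!is.na(p$max_mito_pc))
    stopifnot(p$max_mito_pc >= 0, p$max_mito_pc <= 100)
  d <- defaults$dbmap
  stopifnot(d$N >= 2, d$K >= 2, d$M > 0, d$S > 0, d$alpha >= 0, d$alpha <= 1,
            d$metric %in% c("euclidean", "cosine"))
  cl <- defaults$cluster
  stopifnot(cl$prune >= 0, cl$prune < 1, cl$resolution > 0)
  tr <- defaults$trajectory
  stopifnot(tr$n_components >= 1, tr$k >= 1, tr$n_waypoints >= 1,
            tr$t_impute >= 1, tr$trend_grid >= 1, tr$tol > 0)
  stopifnot(defaults$seed >= 0)
  structure(defaults, class = "run_config")
}

#' Write a data.frame as headered TSV
#'
#' @param df data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
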