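#' Construct a cell-by-gene count matrix container
#'
#' The central exchange object of the package: a sparse nonnegative integer
#' count matrix with cells as rows and genes as columns, together with the
#' per-cell barcodes, the per-gene (id, symbol) feature table and an optional
#' per-cell sample tag. All downstream stages consume this container; readers
#' of on-disk formats produce it.
#'
#' @param counts matrix or sparse Matrix of nonnegative integer counts,
#'   cells in rows, genes in columns.
#' @param barcodes character vector of unique per-cell identifiers; defaults
#'   to existing rownames or `cell_1 ... cell_n`.
#' @param features data.frame with columns `id` and `symbol` (a character
#'   vector is accepted and used for both); defaults to existing colnames.
#' @param sample_of optional per-cell sample tag, recycled if length 1.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (a `dgCMatrix`), `barcodes`, `features`, `sample_of`.
#' @export
count_matrix <- function(counts, barcodes = NULL, features = NULL,
                         sample_of = NULL) {
  if (is.matrix(counts)) counts <- Matrix::Matrix(counts, sparse = TRUE)
  counts <- methods::as(methods::as(counts, "generalMatrix"), "CsparseMatrix")
  if (!methods::is(counts, "dMatrix"))
    counts <- methods::as(counts, "dMatrix")
  counts <- Matrix::drop0(counts)
  if (is.null(barcodes)) {
    barcodes <- rownames(counts)
    if (is.null(barcodes)) barcodes <- paste0("cell_", seq_len(nrow(counts)))
  }
  if (is.null(features)) {
    features <- colnames(counts)
    if (is.null(features)) features <- paste0("gene_", seq_len(ncol(counts)))
  }
  if (!is.data.frame(features)) {
    features <- data.frame(id = as.character(features),
                           symbol = as.character(features),
                           stringsAsFactors = FALSE)
  }
  if (is.null(features$symbol)) features$symbol <- features$id
  if (is.null(sample_of)) sample_of <- rep("sample_1", nrow(counts))
  if (length(sample_of) == 1L) sample_of <- rep(sample_of, nrow(counts))
  obj <- structure(
    list(counts = counts, barcodes = as.character(barcodes),
         features = features[, c("id", "symbol")],
         sample_of = as.character(sample_of)),
    class = "count_matrix")
  validate_count_matrix(obj)
  dimnames(obj$counts) <- list(obj$barcodes, obj$features$id)
  obj
}

#' Validate a count_matrix object's invariants
#'
#' Checks nonnegativity and integrality of counts, uniqueness of barcodes and
#' feature ids, and dimension agreement.
#'
#' @param x a `count_matrix`.
#' @return `x`, invisibly; stops on violation.
#' @export
validate_count_matrix <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  v <- x$counts@x
  if (length(v) && (any(v < 0) || any(abs(v - round(v)) > 1e-8)))
    stop("counts must be nonnegative integers", call. = FALSE)
  if (anyDuplicated(x$barcodes))
    stop("duplicate barcodes: ",
         paste(unique(x$barcodes[duplicated(x$barcodes)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(x$features$id))
    stop("duplicate feature ids", call. = FALSE)
  if (nrow(x$counts) != length(x$barcodes))
    stop("barcode count does not match matrix rows", call. = FALSE)
  if (ncol(x$counts) != nrow(x$features))
    stop("feature count does not match matrix columns", call. = FALSE)
  if (length(x$sample_of) != length(x$barcodes))
    stop("sample_of length does not match cell count", call. = FALSE)
  invisible(x)
}

#' @exportS3Method print count_matrix
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d cells x %d genes, %d nonzero entries\n",
              nrow(x$counts), ncol(x$counts), length(x$counts@x)))
  cat(sprintf("  samples: %s\n",
              paste(utils::head(unique(x$sample_of), 5), collapse = ", ")))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Subset cells and/or genes of a count_matrix
#'
#' @param x a `count_matrix`.
#' @param cells integer or logical index of cells to keep.
#' @param genes integer or logical index of genes to keep.
#' @return a `count_matrix` restricted to the requested cells/genes, order
#'   preserved.
#' @export
subset_cells <- function(x, cells = NULL, genes = NULL) {
  validate_count_matrix(x)
  if (is.null(cells)) cells <- seq_len(nrow(x$counts))
  if (is.null(genes)) genes <- seq_len(ncol(x$counts))
  count_matrix(x$counts[cells, genes, drop = FALSE],
               barcodes = x$barcodes[cells],
               features = x$features[genes, , drop = FALSE],
               sample_of = x$sample_of[cells])
}

#' Construct a normalized/scaled expression matrix container
#'
#' Holds a dense or sparse real-valued cell-by-gene matrix derived from
#' counts, tagged with the processing layer it represents.
#'
#' @param values cell-by-gene numeric matrix (sparse allowed for `lognorm`).
#' @param layer one of `"lognorm"`, `"scaled"`, `"imputed"`.
#' @param barcodes,features carried over from the source `count_matrix`.
#' @return an object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, layer = c("lognorm", "scaled", "imputed"),
                              barcodes, features) {
  layer <- match.arg(layer)
  structure(list(values = values, layer = layer,
                 barcodes = as.character(barcodes), features = features),
            class = "expression_matrix")
}

#' @exportS3Method print expression_matrix
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix [%s]: %d cells x %d genes\n",
              x$layer, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

# Resolve gene symbols to column indices; unmatched symbols are reported via
# attribute "missing" rather than an error.
match_symbols <- function(features, symbols) {
  idx <- match(symbols, features$symbol)
  miss <- symbols[is.na(idx)]
  idx <- idx[!is.na(idx)]
  attr(idx, "missing") <- miss
  idx
}
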