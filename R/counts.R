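#' Construct a feature-by-cell count matrix container
#'
#' Thin S3 container holding a sparse non-negative integer matrix of
#' features (genes or peaks) by cells, with identifiers and optional
#' per-cell / per-feature annotation tables.
#'
#' @param counts matrix or dgCMatrix, features in rows, cells in columns;
#'   entries must be non-negative integers (within numerical tolerance).
#' @param feature_ids character vector of unique feature identifiers;
#'   defaults to rownames of `counts`.
#' @param cell_ids character vector of unique cell identifiers; defaults
#'   to colnames of `counts`.
#' @param cell_meta optional data.frame of per-cell annotations (e.g.
#'   `lineage`, `stage`, `genotype`), one row per cell.
#' @param feature_meta optional data.frame of per-feature annotations
#'   (e.g. logical `is_mitochondrial`, `is_housekeeping`), one row per
#'   feature.
#' @return An object of class `sct_counts` with elements `counts`
#'   (dgCMatrix), `feature_ids`, `cell_ids`, `cell_meta`, `feature_meta`.
#' @export
count_matrix <- function(counts, feature_ids = rownames(counts),
                         cell_ids = colnames(counts),
                         cell_meta = NULL, feature_meta = NULL) {
  counts <- methods::as(methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                                "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (is.null(feature_ids)) feature_ids <- paste0("feature_", seq_len(nrow(counts)))
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(ncol(counts)))
  feature_ids <- as.character(feature_ids)
  cell_ids <- as.character(cell_ids)
  if (length(feature_ids) != nrow(counts))
    stop("feature_ids length (", length(feature_ids), ") != nrow(counts) (",
         nrow(counts), ")")
  if (length(cell_ids) != ncol(counts))
    stop("cell_ids length (", length(cell_ids), ") != ncol(counts) (",
         ncol(counts), ")")
  if (anyDuplicated(feature_ids))
    stop("duplicate feature ids: e.g. ",
         paste(head(feature_ids[duplicated(feature_ids)], 3), collapse = ", "))
  if (anyDuplicated(cell_ids))
    stop("duplicate cell ids: e.g. ",
         paste(head(cell_ids[duplicated(cell_ids)], 3), collapse = ", "))
  x <- counts@x
  if (length(x) && (min(x) < 0 || max(abs(x - round(x))) > 1e-8))
    stop("counts must be non-negative integers")
  if (!is.null(cell_meta)) {
    cell_meta <- as.data.frame(cell_meta)
    if (nrow(cell_meta) != ncol(counts)) stop("cell_meta rows != number of cells")
  }
  if (!is.null(feature_meta)) {
    feature_meta <- as.data.frame(feature_meta)
    if (nrow(feature_meta) != nrow(counts)) stop("feature_meta rows != number of features")
  }
  dimnames(counts) <- list(feature_ids, cell_ids)
  structure(list(counts = counts, feature_ids = feature_ids,
                 cell_ids = cell_ids, cell_meta = cell_meta,
                 feature_meta = feature_meta),
            class = "sct_counts")
}

#' @export
print.sct_counts <- function(x, ...) {
  cat("sct_counts: ", nrow(x$counts), " features x ", ncol(x$counts),
      " cells (", format(100 * (1 - Matrix::nnzero(x$counts) /
                                  prod(dim(x$counts))), digits = 3),
      "% zeros)\n", sep = "")
  invisible(x)
}

#' @export
dim.sct_counts <- function(x) dim(x$counts)

# Subset features/cells keeping ids and metadata in sync.
#' @export
`[.sct_counts` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  if (is.character(i)) i <- match(i, x$feature_ids)
  if (is.character(j)) j <- match(j, x$cell_ids)
  count_matrix(x$counts[i, j, drop = FALSE],
               feature_ids = x$feature_ids[i], cell_ids = x$cell_ids[j],
               cell_meta = if (!is.null(x$cell_meta)) x$cell_meta[j, , drop = FALSE],
               feature_meta = if (!is.null(x$feature_meta)) x$feature_meta[i, , drop = FALSE])
}

# Accept either an sct_counts or a bare matrix; return dgCMatrix.
as_count_mat <- function(x) {
  if (inherits(x, "sct_counts")) return(x$counts)
  methods::as(methods::as(methods::as(Matrix::Matrix(x, sparse = TRUE),
                                      "dMatrix"), "generalMatrix"), "CsparseMatrix")
}
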