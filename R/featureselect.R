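#' Per-gene summary statistics for heterogeneous-gene detection
#'
#' Computes, per gene, the mean normalized expression, the coefficient of
#' variation (sd/mean of normalized values) and the dropout rate
#' (fraction of cells with zero expression). Genes with zero mean have an
#' undefined CV (`NaN`).
#'
#' @param norm_matrix genes-by-cells matrix of normalized expression
#'   (e.g. from [normalize_counts()]).
#' @return data.frame with columns `gene_id`, `mean_g`, `cv_g`, `drop_g`.
#' @export
compute_gene_stats <- function(norm_matrix) {
  if (is.null(dim(norm_matrix)) || ncol(norm_matrix) < 2 || nrow(norm_matrix) < 1)
    stop("need a non-empty matrix with at least 2 cells")
  m <- as_count_mat_any(norm_matrix)
  mu <- Matrix::rowMeans(m)
  ex2 <- Matrix::rowMeans(m^2)
  v <- pmax(0, (ex2 - mu^2)) * ncol(m) / (ncol(m) - 1)
  cv <- sqrt(v) / mu
  cv[mu == 0] <- NaN
  mnz <- methods::as(Matrix::drop0(m), "CsparseMatrix")
  drop <- 1 - tabulate(mnz@i + 1L, nrow(m)) / ncol(m)
  ids <- rownames(m)
  if (is.null(ids)) ids <- paste0("gene_", seq_len(nrow(m)))
  data.frame(gene_id = ids, mean_g = as.numeric(mu), cv_g = as.numeric(cv),
             drop_g = as.numeric(drop), stringsAsFactors = FALSE)
}

# like as_count_mat but without the integer restriction
as_count_mat_any <- function(x) {
  if (inherits(x, "sct_counts")) return(x$counts)
  if (inherits(x, "sparseMatrix")) return(x)
  Matrix::Matrix(x, sparse = TRUE)
}

#' Select heterogeneous genes by windowed percentile of CV and dropout
#'
#' Genes are ordered by mean expression and partitioned into consecutive
#' windows of `window` genes (a trailing remainder is merged into the
#' last full window). Within each window the CV and the dropout rate are
#' z-scored, and a gene is called heterogeneous when either scaled
#' statistic strictly exceeds the within-window empirical `q` quantile
#' (type-7) of that statistic. Genes with undefined CV (mean 0) are
#' excluded before windowing.
#'
#' @param stats data.frame from [compute_gene_stats()].
#' @param window window size in genes (default 200).
#' @param q selection percentile within windows (default 0.99).
#' @return data.frame of selected genes with their statistics, window
#'   index and z-scores; the full annotated table is in attribute
#'   `"all_genes"`.
#' @export
select_heterogeneous <- function(stats, window = 200, q = 0.99) {
  stopifnot(is.data.frame(stats))
  stats <- stats[!is.na(stats$cv_g), , drop = FALSE]
  if (nrow(stats) < 2) stop("need at least 2 genes with defined CV")
  ord <- order(stats$mean_g, stats$gene_id)
  stats <- stats[ord, , drop = FALSE]
  n <- nrow(stats)
  n_windows <- max(1L, n %/% window)
  win <- pmin(ceiling(seq_len(n) / window), n_windows)
  zscale <- function(x) if (sd(x) == 0) rep(0, length(x)) else (x - mean(x)) / sd(x)
  stats$window <- win
  stats$z_cv <- ave(stats$cv_g, win, FUN = zscale)
  stats$z_drop <- ave(stats$drop_g, win, FUN = zscale)
  sel <- logical(n)
  for (w in unique(win)) {
    i <- win == w
    sel[i] <- stats$z_cv[i] > quantile(stats$z_cv[i], q, type = 7) |
      stats$z_drop[i] > quantile(stats$z_drop[i], q, type = 7)
  }
  stats$heterogeneous <- sel
  out <- stats[sel, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "all_genes") <- stats
  out
}
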