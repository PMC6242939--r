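#' QC verdicts for scATAC cells
#'
#' Gates cells on three metrics with MAD-2 outlier detection:
#' mitochondrial content (upper-tailed), number of accessible peaks and
#' log-scaled total counts (both two-sided). Cells failing more than
#' `max_failures` criteria (default 1) are discarded. Further metrics
#' (mapping rate, FRiP, duplication level, fraction of accessible peaks)
#' may be present as diagnostic columns but are never gated.
#'
#' @param metrics data.frame with columns `mito_content`,
#'   `n_accessible_peaks`, `log_total_counts` (and optionally `cell_id`).
#' @param mads MAD multiplier (default 2).
#' @param max_failures tolerated criterion failures (default 1).
#' @return `metrics` augmented with `fail_*` flags, `n_failed`, `keep`.
#' @export
atac_cell_qc <- function(metrics, mads = 2, max_failures = 1) {
  stopifnot(is.data.frame(metrics))
  need <- c("mito_content", "n_accessible_peaks", "log_total_counts")
  miss <- setdiff(need, names(metrics))
  if (length(miss))
    stop("missing gated metric(s): ", paste(miss, collapse = ", "))
  metrics$fail_mito <- mad_outlier(metrics$mito_content, mads, "upper")
  metrics$fail_peaks <- mad_outlier(metrics$n_accessible_peaks, mads, "both")
  metrics$fail_counts <- mad_outlier(metrics$log_total_counts, mads, "both")
  metrics$n_failed <- metrics$fail_mito + metrics$fail_peaks + metrics$fail_counts
  metrics$keep <- metrics$n_failed <= max_failures
  metrics
}

#' Filter scATAC peaks on support and coverage
#'
#' A peak is kept when it is accessible (nonzero) in strictly more than
#' `min_cells` cells and its average count across all cells is strictly
#' below `max_mean` (removing peaks with exceedingly high coverage).
#'
#' @param counts peaks-by-cells matrix or [count_matrix()] object.
#' @param min_cells support threshold (default 35, strict).
#' @param max_mean mean-count ceiling (default 15, strict).
#' @return Character vector of kept peak ids (row indices as character
#'   when unnamed).
#' @export
filter_peaks <- function(counts, min_cells = 35, max_mean = 15) {
  m <- as_count_mat(counts)
  ids <- rownames(m)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(m)))
  support <- Matrix::rowSums(m > 0)
  keep <- support > min_cells & Matrix::rowMeans(m) < max_mean
  ids[keep]
}

#' Binarize an accessibility count matrix
#'
#' Transforms counts greater than 0 to 1. Idempotent; negative entries
#' are an error.
#'
#' @param counts peaks-by-cells matrix or [count_matrix()] object.
#' @return Sparse 0/1 matrix of the same shape.
#' @export
binarize <- function(counts) {
  m <- if (inherits(counts, "sct_counts")) counts$counts else
    methods::as(methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                        "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (length(m@x) && min(m@x) < 0) stop("negative entries cannot be binarized")
  m@x[] <- 1
  Matrix::drop0(m)
}

#' TF-IDF weighting of binarized accessibility
#'
#' Term frequency is each cell's accessibility divided by its total
#' accessible peaks; the smoothed inverse document frequency of a peak is
#' `log(1 + n_cells / (1 + n_cells_with_peak))`, finite and positive for
#' all occupancies. The weight is their product.
#'
#' @param binary peaks-by-cells 0/1 matrix (see [binarize()]). Cells with
#'   no accessible peaks are an error.
#' @return Sparse peaks-by-cells weight matrix with attribute `"idf"`.
#' @export
tfidf <- function(binary) {
  m <- as_count_mat_any(binary)
  totals <- Matrix::colSums(m)
  if (any(totals == 0))
    stop("cell(s) with no accessible peaks: ",
         paste(head(which(totals == 0), 3), collapse = ", "))
  n <- ncol(m)
  df <- Matrix::rowSums(m > 0)
  idf <- log(1 + n / (1 + df))
  w <- Matrix::Diagonal(x = idf) %*% m %*% Matrix::Diagonal(x = 1 / totals)
  dimnames(w) <- dimnames(m)
  attr(w, "idf") <- idf
  w
}

#' Truncated SVD embedding of TF-IDF weights
#'
#' Computes the top `k` singular triplets of the weighted matrix and
#' returns the cell-side factors scaled by the singular values. The first
#' component tracks per-cell sequencing depth and is excluded by default.
#'
#' @param weights peaks-by-cells TF-IDF matrix from [tfidf()].
#' @param k number of singular vectors (default 50); must be below
#'   `min(dim(weights))`.
#' @param drop_first exclude component 1 (default TRUE).
#' @return cells-by-(k or k-1) coordinate matrix; singular values in
#'   attribute `"d"`, the full (undropped) cell factors in `"all_components"`.
#' @export
svd_embed <- function(weights, k = 50, drop_first = TRUE) {
  if (k >= min(dim(weights)))
    stop("k = ", k, " must be smaller than min(dim) = ", min(dim(weights)))
  sv <- irlba::irlba(weights, nv = k)
  cells <- sv$v %*% diag(sv$d)
  rownames(cells) <- colnames(weights)
  colnames(cells) <- paste0("SVD_", seq_len(k))
  out <- if (drop_first) cells[, -1, drop = FALSE] else cells
  attr(out, "d") <- sv$d
  attr(out, "all_components") <- cells
  out
}

#' Cluster scATAC cells from an SVD embedding
#'
#' Projects the SVD coordinates to two dimensions with t-SNE (perplexity
#' 21, 2000 iterations, seeded) and clusters the projection with HDBSCAN
#' (minimum cluster size 11, min_samples 9); `-1` marks outliers.
#'
#' @param coordinates cells-by-components matrix from [svd_embed()].
#' @param perplexity t-SNE perplexity (default 21).
#' @param iterations t-SNE iterations (default 2000).
#' @param min_cluster_size,min_samples HDBSCAN parameters (11, 9).
#' @param seed RNG seed.
#' @return An `sct_clusters` object (see [cluster_hdbscan()]).
#' @export
cluster_atac <- function(coordinates, perplexity = 21, iterations = 2000,
                         min_cluster_size = 11, min_samples = 9, seed = 1) {
  emb <- embed_tsne(coordinates, perplexity = perplexity,
                    iterations = iterations, seed = seed)
  cluster_hdbscan(emb, min_cluster_size = min_cluster_size,
                  min_samples = min_samples)
}

#' Cluster-specific peaks by one-sided enrichment
#'
#' For each peak and cluster, tests whether accessibility is enriched in
#' the cluster versus the rest with a one-sided hypergeometric (Fisher)
#' test on binarized accessibility, adjusts p-values across peaks within
#' each cluster (Benjamini-Hochberg), assigns each peak to its
#' lowest-p cluster, and reports peaks whose adjusted p-value is below
#' `alpha`.
#'
#' @param binary peaks-by-cells 0/1 matrix.
#' @param labels per-cell cluster labels (`-1` excluded); singleton
#'   clusters are skipped with a warning.
#' @param alpha adjusted-p threshold (default 1e-5).
#' @return data.frame with `peak_id`, `cluster`, `p`, `p_adj` for
#'   significant peaks; the full peak-by-cluster p-value matrix is in
#'   attribute `"p_matrix"`.
#' @export
cluster_specific_peaks <- function(binary, labels, alpha = 1e-5) {
  if (inherits(labels, "sct_clusters")) labels <- labels$labels
  m <- as_count_mat_any(binary)
  ids <- rownames(m)
  if (is.null(ids)) ids <- paste0("peak_", seq_len(nrow(m)))
  keep <- labels != -1
  m <- m[, keep, drop = FALSE]; labels <- labels[keep]
  clusters <- sort(unique(labels))
  sizes <- table(labels)
  clusters <- clusters[sizes[as.character(clusters)] >= 2]
  if (length(setdiff(sort(unique(labels)), clusters)))
    warning("singleton cluster(s) skipped")
  if (length(clusters) < 2) stop("need at least 2 clusters of >= 2 cells")
  n <- ncol(m)
  tot <- Matrix::rowSums(m)
  pmat <- padj <- matrix(NA_real_, nrow(m), length(clusters),
                         dimnames = list(ids, as.character(clusters)))
  for (j in seq_along(clusters)) {
    idx <- labels == clusters[j]
    n1 <- sum(idx)
    a <- Matrix::rowSums(m[, idx, drop = FALSE])
    # P(X >= a) for X ~ Hypergeometric(total open, total closed, n1)
    pmat[, j] <- phyper(a - 1, tot, n - tot, n1, lower.tail = FALSE)
    padj[, j] <- p.adjust(pmat[, j], method = "BH")
  }
  best <- max.col(-pmat, ties.method = "first")
  best_padj <- padj[cbind(seq_len(nrow(m)), best)]
  sig <- which(best_padj < alpha)
  out <- data.frame(peak_id = ids[sig],
                    cluster = clusters[best[sig]],
                    p = pmat[cbind(sig, best[sig])],
                    p_adj = best_padj[sig],
                    stringsAsFactors = FALSE)
  attr(out, "p_matrix") <- pmat
  out
}

#' Motif accessibility deviation Z-scores
#'
#' chromVAR-style deviations: the expected accessibility of cell i in the
#' peaks carrying motif m is the cell's depth times the summed expected
#' peak fractions; the raw deviation is the relative difference between
#' observed and expected. Each motif's deviation is standardized against
#' `B` background peak sets of equal size sampled (seeded) from the same
#' expected-accessibility deciles, yielding a Z-score per motif/cell
#' pair.
#'
#' @param counts peaks-by-cells count matrix (e.g. counts in
#'   500-bp-resized cluster-specific peaks).
#' @param motif_hits motifs-by-peaks logical/0-1 matrix; motifs hitting
#'   fewer than `min_peaks` peaks are skipped with a warning.
#' @param B number of background sets (default 50).
#' @param seed RNG seed for background sampling.
#' @param min_peaks minimum peaks per motif (default 5).
#' @return List of class `sct_deviations` with `z` (motifs x cells),
#'   `raw` (motifs x cells), `B`, `seed`.
#' @export
motif_deviation_zscores <- function(counts, motif_hits, B = 50, seed = 1,
                                    min_peaks = 5) {
  m <- as_count_mat_any(counts)
  hits <- as.matrix(motif_hits) > 0
  if (ncol(hits) != nrow(m))
    stop("motif_hits columns (", ncol(hits), ") must match peaks (", nrow(m), ")")
  motif_ids <- rownames(hits)
  if (is.null(motif_ids)) motif_ids <- paste0("motif_", seq_len(nrow(hits)))
  depth <- Matrix::colSums(m)
  peak_tot <- Matrix::rowSums(m)
  e_p <- peak_tot / sum(peak_tot)
  decile <- cut(rank(e_p, ties.method = "first"), breaks = 10, labels = FALSE)
  by_decile <- split(seq_len(nrow(m)), decile)
  n_peaks_per_motif <- rowSums(hits)
  usable <- n_peaks_per_motif >= min_peaks
  if (any(!usable))
    warning(sum(!usable), " motif(s) with < ", min_peaks, " peaks skipped")
  dev_of <- function(peak_idx) {
    obs <- Matrix::colSums(m[peak_idx, , drop = FALSE])
    expd <- depth * sum(e_p[peak_idx])
    as.numeric((obs - expd) / expd)
  }
  z <- raw <- matrix(NA_real_, sum(usable), ncol(m),
                     dimnames = list(motif_ids[usable], colnames(m)))
  row <- 0L
  for (mi in which(usable)) {
    peak_idx <- which(hits[mi, ])
    expd_sum <- sum(e_p[peak_idx])
    if (expd_sum == 0) {
      warning("motif ", motif_ids[mi], " has zero expected accessibility; skipped")
      next
    }
    row <- row + 1L
    d <- dev_of(peak_idx)
    # background seed derives from the motif's peak content so identical
    # motifs get identical background sets under one call seed
    set.seed(as.integer((as.numeric(seed) * 1009 + sum(peak_idx)) %% 2147483647))
    bg <- matrix(0, B, ncol(m))
    dec <- decile[peak_idx]
    for (b in seq_len(B)) {
      bg_idx <- vapply(dec, function(dc) {
        pool <- by_decile[[dc]]
        pool[sample.int(length(pool), 1L)]
      }, integer(1))
      bg[b, ] <- dev_of(bg_idx)
    }
    mu_b <- colMeans(bg)
    sd_b <- apply(bg, 2, sd)
    raw[row, ] <- d
    z[row, ] <- (d - mu_b) / sd_b
  }
  if (row < nrow(z)) { z <- z[seq_len(row), , drop = FALSE]
                       raw <- raw[seq_len(row), , drop = FALSE] }
  structure(list(z = z, raw = raw, B = B, seed = seed),
            class = "sct_deviations")
}

#' Resize peaks to a fixed width around their midpoints
#'
#' Returns peaks re-centered to `width` bases around the original
#' midpoint (0-based half-open coordinates), as used before motif
#' deviation scoring (500 bp fixed-size peaks).
#'
#' @param peaks data.frame with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param width fixed width (default 500).
#' @return The peak table with adjusted `start`/`end` (clipped at 0).
#' @export
resize_peaks <- function(peaks, width = 500) {
  mid <- (peaks$start + peaks$end) %/% 2
  peaks$start <- pmax(0L, as.integer(mid - width %/% 2))
  peaks$end <- peaks$start + as.integer(width)
  peaks
}

#' Diffusion pseudotime within an ATAC cluster
#'
#' Runs a diffusion map on the TF-IDF weighted accessibility of one
#' cluster's cells restricted to significant cluster-specific peaks and
#' returns diffusion pseudotime from a root cell.
#'
#' @param weights peaks-by-cells TF-IDF matrix restricted to
#'   cluster-specific peaks (adjusted p below the chosen cutoff).
#' @param root_cell root cell id or index (default: first cell).
#' @param k diffusion components (default 10, reduced for small
#'   clusters). Requires at least 12 cells.
#' @return Named pseudotime vector in [0, 1].
#' @export
atac_pseudotime <- function(weights, root_cell = 1L, k = 10) {
  n <- ncol(weights)
  if (n < 12) stop("need at least 12 cells in the cluster; got ", n)
  k <- min(k, n - 2L)
  dm <- diffusion_map(as.matrix(weights), k = k)
  diffusion_pseudotime(dm, root_cell)
}
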