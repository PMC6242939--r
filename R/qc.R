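#' Quality-control criteria for scRNA-seq cells
#'
#' Thresholds are expressed as multiples of the normal-consistent median
#' absolute deviation (MAD, scaled by 1.4826) around the per-metric
#' median. Directions follow the usual reading of each metric: high
#' mitochondrial content, high dropout and low housekeeping expression
#' indicate damaged cells, while feature counts and percent of genes
#' detected are gated on both sides.
#'
#' @param mito_mads MADs above the median for mitochondrial percentage.
#' @param features_mads two-sided MADs for the number of features
#'   detected with at least 10 counts.
#' @param dropout_mads MADs above the median for the dropout percentage.
#' @param housekeeping_mads MADs below the median for housekeeping-gene
#'   expression.
#' @param genes_pct_mads two-sided MADs for the percentage of genes
#'   detected.
#' @param max_failures number of criteria a kept cell may fail; cells
#'   failing more than this many are discarded.
#' @return A list of class `sct_qc_criteria`.
#' @export
qc_criteria <- function(mito_mads = 1.5, features_mads = 2, dropout_mads = 2,
                        housekeeping_mads = 2, genes_pct_mads = 1.5,
                        max_failures = 1) {
  for (f in c("mito_mads", "features_mads", "dropout_mads",
              "housekeeping_mads", "genes_pct_mads"))
    check_positive(get(f), f)
  if (max_failures < 0) stop("configuration error: `max_failures` must be >= 0")
  structure(list(mito_mads = mito_mads, features_mads = features_mads,
                 dropout_mads = dropout_mads,
                 housekeeping_mads = housekeeping_mads,
                 genes_pct_mads = genes_pct_mads,
                 max_failures = max_failures),
            class = "sct_qc_criteria")
}

#' Compute per-cell quality-control metrics
#'
#' Produces the five per-cell metrics used to gate cells: percentage of
#' counts in mitochondrial genes, number of features detected with at
#' least 10 counts, percentage of gene dropouts (features with zero
#' counts), housekeeping-gene expression, and percentage of genes
#' detected.
#'
#' @param counts an [count_matrix()] object; `feature_meta` should carry
#'   logical columns `is_mitochondrial` and `is_housekeeping`. If either
#'   flag set is absent or empty, the corresponding metric is `NA` with a
#'   warning and its criterion is skipped downstream.
#' @return A data.frame (one row per cell) with columns `cell_id`,
#'   `mito_pct`, `n_features_ge10`, `dropout_pct`, `housekeeping_expr`,
#'   `genes_pct`. Cells with zero total counts get `NA` mitochondrial
#'   percentage.
#' @export
compute_cell_qc <- function(counts) {
  stopifnot(inherits(counts, "sct_counts"))
  m <- counts$counts
  totals <- Matrix::colSums(m)
  n_feat <- nrow(m)
  mito <- which(isTRUE_vec(counts$feature_meta$is_mitochondrial, n_feat))
  hk <- which(isTRUE_vec(counts$feature_meta$is_housekeeping, n_feat))
  mito_pct <- if (length(mito)) {
    100 * Matrix::colSums(m[mito, , drop = FALSE]) / totals
  } else {
    warning("no mitochondrial features flagged; mito_pct set to NA and its criterion will be skipped")
    rep(NA_real_, ncol(m))
  }
  mito_pct[totals == 0] <- NA_real_
  hk_expr <- if (length(hk)) {
    Matrix::colSums(m[hk, , drop = FALSE])
  } else {
    warning("no housekeeping features flagged; housekeeping_expr set to NA and its criterion will be skipped")
    rep(NA_real_, ncol(m))
  }
  n_ge10 <- Matrix::colSums(m >= 10)
  n_detected <- Matrix::colSums(m > 0)
  data.frame(cell_id = counts$cell_ids,
             mito_pct = as.numeric(mito_pct),
             n_features_ge10 = as.numeric(n_ge10),
             dropout_pct = 100 * (n_feat - as.numeric(n_detected)) / n_feat,
             housekeeping_expr = as.numeric(hk_expr),
             genes_pct = 100 * as.numeric(n_detected) / n_feat,
             stringsAsFactors = FALSE)
}

isTRUE_vec <- function(x, n) {
  if (is.null(x)) return(logical(n))
  as.logical(x) %in% TRUE & !is.na(x)
}

#' Flag low-quality cells from QC metrics
#'
#' Applies the per-criterion MAD rules of [qc_criteria()] to a metric
#' table from [compute_cell_qc()]. A cell is kept when the number of
#' criteria it fails does not exceed `max_failures` (default 1: cells
#' failing more than one criterion are discarded). Metrics that are `NA`
#' for every cell (e.g. no mitochondrial genes annotated) are skipped;
#' metrics that are `NA` for individual cells count as failures for those
#' cells.
#'
#' @param report data.frame from [compute_cell_qc()].
#' @param criteria an [qc_criteria()] object.
#' @return `report` augmented with logical columns `fail_mito`,
#'   `fail_features`, `fail_dropout`, `fail_housekeeping`,
#'   `fail_genes_pct`, integer `n_failed`, and logical `keep`, plus an
#'   attribute `"thresholds"` recording the numeric cutoffs applied.
#' @export
flag_low_quality_cells <- function(report, criteria = qc_criteria()) {
  stopifnot(is.data.frame(report))
  if (nrow(report) < 5)
    stop("need at least 5 cells for stable MAD thresholds (got ", nrow(report), ")")
  rules <- list(
    mito = list(metric = "mito_pct", mads = criteria$mito_mads, side = "upper"),
    features = list(metric = "n_features_ge10", mads = criteria$features_mads, side = "both"),
    dropout = list(metric = "dropout_pct", mads = criteria$dropout_mads, side = "upper"),
    housekeeping = list(metric = "housekeeping_expr", mads = criteria$housekeeping_mads, side = "lower"),
    genes_pct = list(metric = "genes_pct", mads = criteria$genes_pct_mads, side = "both"))
  thresholds <- list()
  n_failed <- integer(nrow(report))
  for (nm in names(rules)) {
    r <- rules[[nm]]
    x <- report[[r$metric]]
    col <- paste0("fail_", nm)
    if (all(is.na(x))) {
      report[[col]] <- FALSE
      thresholds[[nm]] <- c(lo = NA_real_, hi = NA_real_)
      next
    }
    report[[col]] <- mad_outlier(x, r$mads, r$side)
    med <- median(x, na.rm = TRUE); dev <- mad(x, na.rm = TRUE)
    thresholds[[nm]] <- c(lo = med - r$mads * dev, hi = med + r$mads * dev)
    n_failed <- n_failed + report[[col]]
  }
  report$n_failed <- n_failed
  report$keep <- n_failed <= criteria$max_failures
  attr(report, "thresholds") <- thresholds
  report
}

#' Filter genes by lineage-wise expression support
#'
#' A gene is kept when, in at least one lineage, it both (1) accumulates
#' more than `min_total` counts across the lineage's cells and (2) is
#' expressed above `min_count` counts in at least `min_cells` cells of
#' that lineage. Cells of excluded genotypes (knockout / overexpression
#' experiments) are ignored when evaluating the criteria.
#'
#' @param counts an [count_matrix()] object.
#' @param lineage per-cell lineage labels (length = number of cells);
#'   defaults to the `lineage` column of `cell_meta`, or a single lineage
#'   when absent.
#' @param exclude_genotypes genotype labels (matched against
#'   `cell_meta$genotype`) whose cells are ignored for the test.
#' @param min_total total-count threshold (strictly exceeded; default 2000).
#' @param min_cells minimum number of supporting cells (default 10).
#' @param min_count per-cell count a supporting cell must exceed (default 10).
#' @return Character vector of kept feature ids.
#' @export
filter_genes <- function(counts, lineage = NULL, exclude_genotypes = NULL,
                         min_total = 2000, min_cells = 10, min_count = 10) {
  stopifnot(inherits(counts, "sct_counts"))
  m <- counts$counts
  if (is.null(lineage)) {
    lineage <- if (!is.null(counts$cell_meta$lineage))
      as.character(counts$cell_meta$lineage) else rep("all", ncol(m))
  }
  if (length(lineage) != ncol(m))
    stop("unknown lineage labels: length ", length(lineage),
         " does not match ", ncol(m), " cells")
  use <- rep(TRUE, ncol(m))
  if (!is.null(exclude_genotypes) && !is.null(counts$cell_meta$genotype))
    use <- !(as.character(counts$cell_meta$genotype) %in% exclude_genotypes)
  keep <- rep(FALSE, nrow(m))
  for (lin in unique(lineage[use])) {
    cols <- which(use & lineage == lin)
    sub <- m[, cols, drop = FALSE]
    pass1 <- Matrix::rowSums(sub) > min_total
    pass2 <- Matrix::rowSums(sub > min_count) >= min_cells
    keep <- keep | (pass1 & pass2)
  }
  counts$feature_ids[keep]
}
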