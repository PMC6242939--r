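#' Critical transition index of a cell cluster
#'
#' The index is the ratio of the mean absolute Pearson gene-to-gene
#' correlation to the mean absolute Pearson cell-to-cell correlation
#' within a cluster, self-pairs excluded. Transition (unstable) states
#' show reduced gene-gene coordination and elevated cell-cell
#' variability, hence a lower index than stable attractor states.
#'
#' @param expr marker-genes-by-cells matrix of log-normalized expression
#'   for the cells of one cluster (at least 3 genes and 3 cells).
#'   Zero-variance rows and columns are dropped with a warning.
#' @return The index value (positive scalar); `NaN` with an `"error"`
#'   attribute when undefined (all-constant input).
#' @export
critical_transition_index <- function(expr) {
  x <- as.matrix(expr)
  gv <- apply(x, 1, sd)
  cv <- apply(x, 2, sd)
  if (any(gv == 0)) {
    warning(sum(gv == 0), " zero-variance gene(s) dropped")
    x <- x[gv > 0, , drop = FALSE]
  }
  if (any(cv == 0)) {
    warning(sum(cv == 0), " zero-variance cell(s) dropped")
    x <- x[, cv > 0, drop = FALSE]
  }
  if (nrow(x) < 3 || ncol(x) < 3) {
    out <- NaN
    attr(out, "error") <- "fewer than 3 variable genes or cells"
    return(out)
  }
  mean_abs_offdiag(cor(t(x))) / mean_abs_offdiag(cor(x))
}

mean_abs_offdiag <- function(r) {
  mean(abs(r[upper.tri(r)]))
}

#' Bootstrap the critical transition index per cluster
#'
#' Equalizes the influence of differing cluster sizes by repeatedly
#' drawing `n_cells` cells without replacement from each cluster and
#' recomputing the index on each draw. Clusters smaller than `n_cells`
#' are drawn with replacement and flagged.
#'
#' @param expr marker-genes-by-cells matrix over all cells.
#' @param labels per-cell cluster labels (`-1` outliers excluded).
#' @param n_cells bootstrap sample size (30 or 20 in typical lineages).
#' @param reps bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @return data.frame (one row per cluster) with `cluster`, `ic`
#'   (full-cluster index), `ic_boot_median`, `n_cells_drawn`,
#'   `with_replacement`; replicate values in attribute
#'   `"bootstrap_values"` (list of numeric vectors).
#' @export
bootstrap_ic <- function(expr, labels, n_cells = 30, reps = 1000, seed = 1) {
  if (reps < 1) stop("reps must be >= 1")
  if (inherits(labels, "sct_clusters")) labels <- labels$labels
  x <- as.matrix(expr)
  stopifnot(ncol(x) == length(labels))
  clusters <- sort(unique(labels[labels != -1]))
  set.seed(seed)
  rows <- list(); boots <- list()
  for (cl in clusters) {
    idx <- which(labels == cl)
    replace <- length(idx) < n_cells
    if (replace)
      warning("cluster ", cl, " has ", length(idx), " < ", n_cells,
              " cells; sampling with replacement")
    vals <- vapply(seq_len(reps), function(r) {
      draw <- sample(idx, n_cells, replace = replace)
      suppressWarnings(as.numeric(critical_transition_index(x[, draw, drop = FALSE])))
    }, numeric(1))
    rows[[length(rows) + 1L]] <- data.frame(
      cluster = cl,
      ic = suppressWarnings(as.numeric(critical_transition_index(x[, idx, drop = FALSE]))),
      ic_boot_median = median(vals, na.rm = TRUE),
      n_cells_drawn = n_cells, with_replacement = replace)
    boots[[as.character(cl)]] <- vals
  }
  out <- do.call(rbind, rows)
  attr(out, "bootstrap_values") <- boots
  out
}

#' Pairwise cell-to-cell distance distributions per cluster
#'
#' Distances between cells are `1 - Spearman rank correlation` of their
#' expression profiles over heterogeneous genes (robust to monotone
#' per-cell transforms); `1 - Pearson` and Euclidean metrics are
#' available. Distributions are summarized per cluster by median and
#' boxplot hinges.
#'
#' @param expr heterogeneous-genes-by-cells matrix.
#' @param labels per-cell cluster labels (`-1` excluded).
#' @param method distance flavour: `"spearman"`, `"pearson"`, `"euclidean"`.
#' @return data.frame per cluster with `cluster`, `n_cells`, `n_pairs`,
#'   `median`, `hinge_lo`, `hinge_hi`; raw upper-triangle distances in
#'   attribute `"distances"` (list per cluster).
#' @export
pairwise_cell_distances <- function(expr, labels,
                                    method = c("spearman", "pearson", "euclidean")) {
  method <- match.arg(method)
  if (inherits(labels, "sct_clusters")) labels <- labels$labels
  x <- as.matrix(expr)
  stopifnot(ncol(x) == length(labels))
  clusters <- sort(unique(labels[labels != -1]))
  rows <- list(); dists <- list()
  for (cl in clusters) {
    idx <- which(labels == cl)
    if (length(idx) < 2) next
    sub <- x[, idx, drop = FALSE]
    if (method == "euclidean") {
      dvec <- as.numeric(dist(t(sub)))
    } else {
      const <- apply(sub, 2, sd) == 0
      if (any(const)) {
        warning(sum(const), " constant cell profile(s) in cluster ", cl,
                " excluded")
        sub <- sub[, !const, drop = FALSE]
      }
      if (ncol(sub) < 2) next
      r <- cor(sub, method = method)
      dvec <- 1 - r[upper.tri(r)]
    }
    q <- quantile(dvec, c(0.25, 0.5, 0.75), type = 7)
    rows[[length(rows) + 1L]] <- data.frame(
      cluster = cl, n_cells = length(idx), n_pairs = length(dvec),
      median = q[[2]], hinge_lo = q[[1]], hinge_hi = q[[3]])
    dists[[as.character(cl)]] <- dvec
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "distances") <- dists
  out
}
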