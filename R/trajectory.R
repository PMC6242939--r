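#' Diffusion map of cells
#'
#' Builds a Gaussian kernel with per-cell local scaling (the bandwidth of
#' cell i is its distance to the `local_k`-th nearest neighbour), applies
#' density normalization to remove sampling-density effects, and
#' eigendecomposes the resulting transition operator. The trivial
#' constant eigenvector is dropped; the top `k` nontrivial components are
#' returned with their eigenvalues.
#'
#' @param expr marker-genes-by-cells matrix of log-normalized expression.
#' @param k number of diffusion components (default 10); needs at least
#'   `k + 2` cells.
#' @param local_k neighbour index for local kernel scaling (default 5).
#' @return List of class `sct_diffmap`: `evec` (cells x k), `eval`
#'   (descending, all <= 1), `kernel_sigma`, `cell_ids`.
#' @export
diffusion_map <- function(expr, k = 10, local_k = 5) {
  x <- as.matrix(expr)
  n <- ncol(x)
  if (n < k + 2) stop("need at least k + 2 = ", k + 2, " cells; got ", n)
  d <- as.matrix(dist(t(x)))
  sigma <- vapply(seq_len(n), function(i) {
    sort(d[i, -i], partial = min(local_k, n - 1))[min(local_k, n - 1)]
  }, numeric(1))
  sigma <- pmax(sigma, 1e-8)
  K <- exp(-d^2 / outer(sigma, sigma))
  comp <- kernel_components(K > 1e-12)
  if (max(comp) > 1)
    stop("kernel graph is disconnected into ", max(comp),
         " components (sizes ", paste(table(comp), collapse = ", "), ")")
  # density normalization (alpha = 1), then symmetric operator
  q <- rowSums(K)
  W <- K / outer(q, q)
  dd <- rowSums(W)
  S <- W / sqrt(outer(dd, dd))
  eig <- eigen(S, symmetric = TRUE)
  psi <- eig$vectors / sqrt(dd)   # right eigenvectors of the row-stochastic operator
  # drop the trivial constant component
  evec <- psi[, 2:(k + 1), drop = FALSE]
  eval <- eig$values[2:(k + 1)]
  # fix sign for reproducibility
  for (j in seq_len(ncol(evec))) {
    s <- sign(evec[which.max(abs(evec[, j])), j])
    if (s != 0) evec[, j] <- evec[, j] * s
  }
  rownames(evec) <- colnames(x)
  structure(list(evec = evec, eval = eval, kernel_sigma = sigma,
                 cell_ids = colnames(x)),
            class = "sct_diffmap")
}

kernel_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Diffusion pseudotime from a root cell
#'
#' The pseudotime of a cell is its Euclidean distance from the root in
#' diffusion-component space with each component rescaled by
#' `lambda / (1 - lambda)`, min-max scaled to [0, 1] (root at 0).
#'
#' @param dm an [diffusion_map()] result.
#' @param root_cell cell id (or index) used as the trajectory origin.
#' @return Named numeric vector of pseudotimes in [0, 1].
#' @export
diffusion_pseudotime <- function(dm, root_cell) {
  stopifnot(inherits(dm, "sct_diffmap"))
  if (is.character(root_cell)) {
    ri <- match(root_cell, dm$cell_ids)
    if (is.na(ri)) stop("root cell '", root_cell, "' not found")
  } else ri <- as.integer(root_cell)
  w <- dm$eval / (1 - pmin(dm$eval, 1 - 1e-12))
  z <- sweep(dm$evec, 2, w, `*`)
  dpt <- sqrt(colSums((t(z) - z[ri, ])^2))
  rng <- range(dpt)
  if (diff(rng) > 0) dpt <- (dpt - rng[1]) / diff(rng)
  names(dpt) <- dm$cell_ids
  dpt
}

#' Project query cells onto a reference trajectory
#'
#' Assigns each query cell the inverse-distance-weighted mean pseudotime
#' (and optionally 2-D embedding position) of its `k_neighbors` nearest
#' reference cells in marker-gene expression space. A query cell at zero
#' distance from a reference cell inherits that cell's values exactly.
#'
#' @param ref_expr marker-genes-by-cells reference expression matrix.
#' @param ref_dpt per-reference-cell pseudotime.
#' @param query_expr genes-by-cells query matrix; its genes must
#'   intersect the reference genes (the intersection is used).
#' @param ref_embedding optional reference cells-by-2 coordinates to
#'   project positions as well.
#' @param k_neighbors neighbourhood size (default 10).
#' @return data.frame with `cell_id`, `dpt`, and `x`, `y` when an
#'   embedding is given.
#' @export
project_cells <- function(ref_expr, ref_dpt, query_expr,
                          ref_embedding = NULL, k_neighbors = 10) {
  ref <- as.matrix(ref_expr); query <- as.matrix(query_expr)
  genes <- intersect(rownames(ref), rownames(query))
  if (!length(genes)) stop("no genes shared between reference and query")
  ref <- ref[genes, , drop = FALSE]; query <- query[genes, , drop = FALSE]
  k <- min(k_neighbors, ncol(ref))
  out <- matrix(NA_real_, nrow = ncol(query),
                ncol = if (is.null(ref_embedding)) 1L else 3L)
  for (i in seq_len(ncol(query))) {
    d <- sqrt(colSums((ref - query[, i])^2))
    nn <- order(d)[seq_len(k)]
    if (d[nn[1]] == 0) {
      w <- as.numeric(d[nn] == 0)
    } else {
      w <- 1 / d[nn]
    }
    w <- w / sum(w)
    out[i, 1] <- sum(w * ref_dpt[nn])
    if (!is.null(ref_embedding)) {
      out[i, 2] <- sum(w * ref_embedding[nn, 1])
      out[i, 3] <- sum(w * ref_embedding[nn, 2])
    }
  }
  res <- data.frame(cell_id = colnames(query), dpt = out[, 1],
                    stringsAsFactors = FALSE)
  if (!is.null(ref_embedding)) { res$x <- out[, 2]; res$y <- out[, 3] }
  res
}

#' Genes correlated with pseudotime
#'
#' Computes per gene the global Spearman correlation of expression with
#' pseudotime over all cells and the maximum-magnitude local Spearman
#' correlation within clusters of at least `min_cluster_cells` cells. A
#' gene is `correlated` when |global| >= `global_min` (default 0.7) or
#' |local| >= `local_min` (default 0.5). Constant genes get `NA`
#' correlations and are never flagged.
#'
#' @param norm_expr genes-by-cells matrix.
#' @param dpt per-cell pseudotime.
#' @param labels optional per-cell cluster labels for local correlations.
#' @param global_min,local_min correlation thresholds.
#' @param min_cluster_cells smallest cluster used for local correlation
#'   (default 10).
#' @return data.frame with `gene_id`, `rho_global`, `rho_local_max`,
#'   `correlated`.
#' @export
correlated_genes <- function(norm_expr, dpt, labels = NULL,
                             global_min = 0.7, local_min = 0.5,
                             min_cluster_cells = 10) {
  x <- as.matrix(norm_expr)
  stopifnot(ncol(x) == length(dpt))
  if (is.null(rownames(x))) rownames(x) <- paste0("gene_", seq_len(nrow(x)))
  rg <- suppressWarnings(as.numeric(cor(t(x), dpt, method = "spearman")))
  rl <- rep(NA_real_, nrow(x))
  if (!is.null(labels)) {
    if (inherits(labels, "sct_clusters")) labels <- labels$labels
    for (cl in unique(labels[labels != -1])) {
      idx <- which(labels == cl)
      if (length(idx) < min_cluster_cells) next
      r <- suppressWarnings(as.numeric(cor(t(x[, idx, drop = FALSE]),
                                           dpt[idx], method = "spearman")))
      upd <- !is.na(r) & (is.na(rl) | abs(r) > abs(rl))
      rl[upd] <- r[upd]
    }
  }
  correlated <- (!is.na(rg) & abs(rg) >= global_min) |
    (!is.na(rl) & abs(rl) >= local_min)
  data.frame(gene_id = rownames(x), rho_global = rg, rho_local_max = rl,
             correlated = correlated, stringsAsFactors = FALSE)
}

#' Smooth values along a pseudotime ordering
#'
#' Centered moving mean over cells ordered by pseudotime, with windows
#' truncated at the boundaries. `window = 1` is the identity.
#'
#' @param values numeric vector, one value per cell.
#' @param order integer ranking of cells by pseudotime (e.g.
#'   `order(dpt)`); defaults to the input order.
#' @param window odd window length in cells (default 11).
#' @return Smoothed vector aligned with the input cell order.
#' @export
smooth_along_pseudotime <- function(values, order = seq_along(values),
                                    window = 11) {
  if (window < 1) stop("window must be >= 1")
  if (window %% 2 == 0) stop("window must be odd")
  if (window > length(values)) stop("window exceeds the number of cells")
  sm_ordered <- moving_mean(values[order], window)
  out <- numeric(length(values))
  out[order] <- sm_ordered
  out
}

#' Categorize gene dynamics along a trajectory
#'
#' Labels each correlated gene by its smoothed trend: `priming` when the
#' mean of the early third of the trajectory exceeds the mean of the late
#' third (expression declining from multipotent stages), `de_novo` for
#' the reverse (expression arising at fate-restricted stages), otherwise
#' `unclassified`.
#'
#' @param trends genes-by-ordered-cells matrix of smoothed expression
#'   (columns in pseudotime order).
#' @param min_delta minimum early/late mean difference to call a
#'   direction (default 0: any difference counts).
#' @return data.frame with `gene_id` and `category`.
#' @export
categorize_dynamics <- function(trends, min_delta = 0) {
  x <- as.matrix(trends)
  if (is.null(rownames(x))) rownames(x) <- paste0("gene_", seq_len(nrow(x)))
  n <- ncol(x)
  third <- max(1L, floor(n / 3))
  early <- rowMeans(x[, seq_len(third), drop = FALSE])
  late <- rowMeans(x[, (n - third + 1):n, drop = FALSE])
  category <- ifelse(early - late > min_delta, "priming",
                     ifelse(late - early > min_delta, "de_novo",
                            "unclassified"))
  data.frame(gene_id = rownames(x), category = category,
             stringsAsFactors = FALSE)
}
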