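#' Train a self-organizing map of gene expression profiles
#'
#' Reduces a scaled genes-by-cells expression matrix to metagenes: genes
#' are placed onto a rectangular grid of tiles whose prototypes live in
#' cell space, so each tile's prototype is a metagene expression profile
#' and every gene is assigned to its best-matching tile. Training is
#' classic online Kohonen learning: per epoch genes are visited in a
#' seeded random order, the best-matching tile minimizes Euclidean
#' distance (ties to the lowest tile index), and prototypes are updated
#' with a Gaussian grid neighbourhood. The learning rate decays linearly
#' 0.05 to 0.01 and the neighbourhood radius from half the grid diagonal
#' to 0.5 over the epochs.
#'
#' @param scaled_expr genes-by-cells matrix of z-scored expression of
#'   heterogeneous genes.
#' @param grid_shape integer c(rows, cols); `NULL` picks a square grid
#'   with roughly one tile per two genes, capped at 8x8. The tile count
#'   must be smaller than the gene count.
#' @param epochs training epochs (default 2000).
#' @param seed RNG seed; identical seeds give identical models.
#' @param trace record total quantization error after each epoch.
#' @return An object of class `sct_som`: `grid_shape`, `prototypes`
#'   (tiles x cells), `assignment` (named gene -> tile index),
#'   `epochs_trained`, `seed`, `quantization_error`, and `qtrace` when
#'   requested.
#' @export
train_som <- function(scaled_expr, grid_shape = NULL, epochs = 2000,
                      seed = 1, trace = FALSE) {
  x <- as.matrix(scaled_expr)
  n_genes <- nrow(x)
  if (is.null(grid_shape)) {
    side <- max(2L, min(8L, ceiling(sqrt(n_genes / 2))))
    while (side > 2L && side^2 >= n_genes) side <- side - 1L
    grid_shape <- c(side, side)
  }
  grid_shape <- as.integer(grid_shape)
  ntiles <- prod(grid_shape)
  if (ntiles >= n_genes)
    stop("grid has ", ntiles, " tiles but only ", n_genes,
         " genes; the map must have fewer tiles than genes")
  sigma0 <- sqrt(sum((grid_shape - 1)^2)) / 2
  sigma0 <- max(sigma0, 0.5)
  set.seed(seed)
  fit <- som_train_cpp(x, grid_shape[1], grid_shape[2], as.integer(epochs),
                       0.05, 0.01, sigma0, 0.5, isTRUE(trace))
  assignment <- as.integer(fit$assignment)
  names(assignment) <- rownames(x)
  structure(list(grid_shape = grid_shape,
                 prototypes = fit$prototypes,
                 assignment = assignment,
                 epochs_trained = as.integer(epochs),
                 seed = seed,
                 quantization_error = sum(fit$qerror),
                 qtrace = if (isTRUE(trace)) as.numeric(fit$qtrace)),
            class = "sct_som")
}

#' @export
print.sct_som <- function(x, ...) {
  cat("sct_som: ", x$grid_shape[1], "x", x$grid_shape[2], " grid, ",
      length(x$assignment), " genes, ", x$epochs_trained, " epochs\n", sep = "")
  invisible(x)
}

#' Metagene expression matrix from a trained SOM
#'
#' Collapses a genes-by-cells expression matrix to a cells-by-tiles
#' matrix where each entry is the mean (scaled) expression of the genes
#' assigned to that tile in that cell. Tiles with no assigned genes are
#' zero-filled and listed in the `"empty_tiles"` attribute.
#'
#' @param model an [train_som()] model.
#' @param expr genes-by-cells matrix; every row name must appear in the
#'   model's gene assignment.
#' @return cells-by-tiles numeric matrix.
#' @export
metagene_matrix <- function(model, expr) {
  stopifnot(inherits(model, "sct_som"))
  x <- as.matrix(expr)
  idx <- model$assignment[rownames(x)]
  if (anyNA(idx))
    stop("genes without a tile assignment: ",
         paste(head(rownames(x)[is.na(idx)], 3), collapse = ", "))
  ntiles <- prod(model$grid_shape)
  out <- matrix(0, nrow = ncol(x), ncol = ntiles,
                dimnames = list(colnames(x), paste0("tile_", seq_len(ntiles))))
  counts <- tabulate(idx, ntiles)
  sums <- rowsum(x, group = idx)
  filled <- as.integer(rownames(sums))
  out[, filled] <- t(sums / counts[filled])
  attr(out, "empty_tiles") <- which(counts == 0)
  out
}
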