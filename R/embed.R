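#' Two-dimensional t-SNE embedding of cells
#'
#' Deterministic (seeded) Barnes-Hut t-SNE of a cells-by-features matrix
#' (typically SOM metagenes or SVD components), without an internal PCA
#' step. Duplicate rows are allowed.
#'
#' @param matrix cells-by-features numeric matrix.
#' @param perplexity t-SNE perplexity (default 15 for the RNA arm; the
#'   ATAC arm uses 21). Requires `nrow > 3 * perplexity`.
#' @param iterations gradient iterations (default 2000).
#' @param seed RNG seed.
#' @return cells-by-2 coordinate matrix with the input rownames.
#' @export
embed_tsne <- function(matrix, perplexity = 15, iterations = 2000, seed = 1) {
  x <- as.matrix(matrix)
  n <- nrow(x)
  if (n <= 3 * perplexity)
    stop("t-SNE needs more than 3 * perplexity = ", 3 * perplexity,
         " cells; got ", n)
  set.seed(seed)
  fit <- Rtsne::Rtsne(x, dims = 2, perplexity = perplexity,
                      max_iter = as.integer(iterations), pca = FALSE,
                      check_duplicates = FALSE, verbose = FALSE)
  coords <- fit$Y
  rownames(coords) <- rownames(x)
  colnames(coords) <- c("tsne_1", "tsne_2")
  coords
}
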