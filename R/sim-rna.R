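#' Configuration for the clustered scRNA-seq generator
#'
#' Defaults describe a moderately deep plate-based experiment: 2000
#' genes, 300 cells in 5 discrete clusters, 10% of genes differential
#' per cluster at a log2 effect of 2, negative-binomial dispersion 0.1,
#' logistic mean-dependent dropout with midpoint at log-mean 1, and
#' per-cell library sizes between 20,000 and 100,000.
#'
#' @param n_genes,n_cells,n_clusters dimensions of the experiment.
#' @param de_fraction fraction of genes differential per cluster.
#' @param lfc_scale log2 effect size of differential genes.
#' @param nb_dispersion negative-binomial dispersion (1/size).
#' @param dropout_midpoint natural-log mean at which dropout = 0.5.
#' @param depth_range min/max per-cell library size.
#' @param seed RNG seed; identical configs give bit-identical output.
#' @return A list of class `sct_rna_sim_config`.
#' @export
rna_sim_config <- function(n_genes = 2000, n_cells = 300, n_clusters = 5,
                           de_fraction = 0.1, lfc_scale = 2,
                           nb_dispersion = 0.1, dropout_midpoint = 1,
                           depth_range = c(20000, 100000), seed = 1) {
  check_count(n_genes, "n_genes", 10)
  check_count(n_cells, "n_cells", 2)
  check_count(n_clusters, "n_clusters", 1)
  check_fraction(de_fraction, "de_fraction", open = FALSE)
  if (lfc_scale < 0) stop("configuration error: `lfc_scale` must be >= 0")
  check_positive(nb_dispersion, "nb_dispersion")
  if (!is.numeric(dropout_midpoint) || length(dropout_midpoint) != 1)
    stop("configuration error: `dropout_midpoint` must be a number")
  if (length(depth_range) != 2 || any(depth_range <= 0) ||
      depth_range[1] > depth_range[2])
    stop("configuration error: `depth_range` must be positive c(min, max)")
  structure(list(n_genes = n_genes, n_cells = n_cells,
                 n_clusters = n_clusters, de_fraction = de_fraction,
                 lfc_scale = lfc_scale, nb_dispersion = nb_dispersion,
                 dropout_midpoint = dropout_midpoint,
                 depth_range = depth_range, seed = seed),
            class = "sct_rna_sim_config")
}

#' Simulate clustered scRNA-seq counts with ground truth
#'
#' Draws negative-binomial counts with cluster-specific means for a
#' planted fraction of genes and Bernoulli dropout whose probability is a
#' logistic decreasing function of the natural-log mean,
#' `p_drop = 1 / (1 + exp((log(mu) - midpoint) / 0.5))`. A small block of
#' genes is flagged mitochondrial and one high, stable gene is flagged
#' housekeeping so the QC module is exercisable.
#'
#' @param config an [rna_sim_config()].
#' @return List with `counts` (an [count_matrix()]) and `truth` (list
#'   with `cell_cluster`, `de_genes` per cluster, `lfc` matrix of
#'   per-cluster log2 effects, `depths`, `dropout_prob` summary).
#' @export
generate_rna_counts <- function(config = rna_sim_config()) {
  stopifnot(inherits(config, "sct_rna_sim_config"))
  with_seed(config$seed, {
    G <- config$n_genes; N <- config$n_cells; K <- config$n_clusters
    gene_ids <- sprintf("gene_%04d", seq_len(G))
    n_mito <- max(2L, round(0.02 * G))
    mito_idx <- seq_len(n_mito)
    gene_ids[mito_idx] <- sprintf("mt-gene_%03d", seq_len(n_mito))
    hk_idx <- n_mito + 1L
    gene_ids[hk_idx] <- "Rplp0"
    base_log2 <- rnorm(G, mean = 1, sd = 2)
    base_log2[hk_idx] <- 7  # high, stable housekeeping expression
    lfc <- matrix(0, G, K)
    de_genes <- vector("list", K)
    eligible <- setdiff(seq_len(G), c(mito_idx, hk_idx))
    for (k in seq_len(K)) {
      de <- sample(eligible, round(config$de_fraction * G))
      lfc[de, k] <- sample(c(-1, 1), length(de), replace = TRUE) *
        config$lfc_scale
      de_genes[[k]] <- gene_ids[de]
    }
    cluster <- sort(rep_len(seq_len(K), N))
    depths <- round(runif(N, config$depth_range[1], config$depth_range[2]))
    rel <- 2^(base_log2 + lfc[, cluster, drop = FALSE])  # G x N
    mu <- sweep(rel, 2, colSums(rel), `/`) %*% diag(depths)
    counts <- matrix(rnbinom(G * N, mu = as.numeric(mu),
                             size = 1 / config$nb_dispersion), G, N)
    p_drop <- 1 / (1 + exp((log(pmax(mu, 1e-8)) - config$dropout_midpoint) / 0.5))
    keep <- matrix(rbinom(G * N, 1, 1 - as.numeric(p_drop)), G, N)
    counts <- counts * keep
    feature_meta <- data.frame(
      is_mitochondrial = seq_len(G) %in% mito_idx,
      is_housekeeping = seq_len(G) == hk_idx)
    cm <- count_matrix(counts, feature_ids = gene_ids,
                       cell_ids = sprintf("cell_%04d", seq_len(N)),
                       cell_meta = data.frame(cluster = cluster,
                                              lineage = "simulated",
                                              genotype = "wt"),
                       feature_meta = feature_meta)
    list(counts = cm,
         truth = list(cell_cluster = cluster,
                      de_genes = stats::setNames(de_genes, paste0("cluster_", seq_len(K))),
                      lfc = lfc, depths = depths,
                      mean_dropout = mean(p_drop)))
  })
}
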