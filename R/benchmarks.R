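#' Recovery benchmarks on synthetic data
#'
#' Each benchmark regenerates ground-truthed synthetic data and runs the
#' relevant slice of the pipeline from scratch, returning the raw
#' per-seed measurements so that calibration and recovery claims are
#' recomputed rather than cached.
#'
#' @name benchmarks
NULL

#' Transition-state signature recovery across seeds
#'
#' For each seed, simulates a bifurcating trajectory with a planted
#' transition state, normalizes, computes the bootstrap critical
#' transition index and the per-cluster cell-cell distance
#' distributions on the dynamic program genes, and records whether the
#' transition cluster shows the joint signature: lowest bootstrap-median
#' index AND highest median cell-cell distance among its flanking
#' clusters.
#'
#' @param n_seeds number of simulated datasets.
#' @param seed0 base seed; dataset s uses `seed0 + s`.
#' @param reps bootstrap replicates per cluster (default 100 here; the
#'   full analysis default is 1000).
#' @param n_cells_boot bootstrap draw size (default 30).
#' @param config_args overrides for [trajectory_sim_config()].
#' @return data.frame per seed with `ic_lowest`, `dist_highest`, `joint`.
#' @export
benchmark_transition_signature <- function(n_seeds = 100, seed0 = 0,
                                           reps = 100, n_cells_boot = 30,
                                           config_args = list()) {
  res <- lapply(seq_len(n_seeds), function(s) {
    cfg <- do.call(trajectory_sim_config,
                   c(config_args, list(seed = seed0 + s)))
    sim <- generate_trajectory_counts(cfg)
    norm <- as.matrix(normalize_counts(sim$counts,
                                       estimate_size_factors(sim$counts)))
    truth <- sim$truth
    x <- norm[truth$dynamic_genes, , drop = FALSE]
    use <- truth$cell_cluster %in% c(truth$transition_cluster,
                                     truth$flanking_clusters)
    labels <- ifelse(use, truth$cell_cluster, -1L)
    ic <- suppressWarnings(bootstrap_ic(x, labels, n_cells = n_cells_boot,
                                        reps = reps, seed = seed0 + s))
    dd <- pairwise_cell_distances(x, labels)
    tc <- truth$transition_cluster
    fl <- truth$flanking_clusters
    ic_low <- ic$ic_boot_median[ic$cluster == tc] <
      min(ic$ic_boot_median[ic$cluster %in% fl])
    d_high <- dd$median[dd$cluster == tc] >
      max(dd$median[dd$cluster %in% fl])
    data.frame(seed = seed0 + s, ic_lowest = ic_low,
               dist_highest = d_high, joint = ic_low && d_high)
  })
  do.call(rbind, res)
}

#' RNA clustering recovery across seeds
#'
#' Runs the full RNA arm (QC, gene filter, size factors, normalization,
#' heterogeneous genes, SOM metagenes, t-SNE, HDBSCAN) on simulated
#' clustered counts and scores the adjusted Rand index against the
#' planted clusters, excluding outlier calls.
#'
#' @param n_seeds number of simulated datasets.
#' @param seed0 base seed.
#' @param som_epochs SOM training epochs (default 2000).
#' @param config_args overrides for [rna_sim_config()].
#' @return data.frame per seed with `ari` and `n_clusters`.
#' @export
benchmark_rna_clustering <- function(n_seeds = 20, seed0 = 0,
                                     som_epochs = 2000, config_args = list()) {
  res <- lapply(seq_len(n_seeds), function(s) {
    cfg <- do.call(rna_sim_config, c(config_args, list(seed = seed0 + s)))
    sim <- generate_rna_counts(cfg)
    qc <- flag_low_quality_cells(compute_cell_qc(sim$counts))
    cm <- sim$counts[, which(qc$keep)]
    truth <- sim$truth$cell_cluster[qc$keep]
    norm <- normalize_counts(cm, estimate_size_factors(cm))
    het <- select_heterogeneous(compute_gene_stats(norm))
    scaled <- t(scale(t(as.matrix(norm[het$gene_id, , drop = FALSE]))))
    som <- train_som(scaled, epochs = som_epochs, seed = seed0 + s)
    mg <- metagene_matrix(som, scaled)
    emb <- embed_tsne(mg, perplexity = 15, iterations = 1000,
                      seed = seed0 + s)
    cl <- cluster_hdbscan(emb, 7, 9)
    keep <- cl$labels != -1
    data.frame(seed = seed0 + s,
               ari = adjusted_rand_index(cl$labels[keep], truth[keep]),
               n_clusters = length(unique(cl$labels[keep])))
  })
  do.call(rbind, res)
}

#' ATAC clustering recovery across seeds
#'
#' Runs the ATAC arm (peak filter, binarization, TF-IDF, SVD without the
#' first component, t-SNE, HDBSCAN) on simulated accessibility and
#' scores the ARI against planted clusters.
#'
#' @inheritParams benchmark_rna_clustering
#' @param config_args overrides for [atac_sim_config()].
#' @return data.frame per seed with `ari` and `n_clusters`.
#' @export
benchmark_atac_clustering <- function(n_seeds = 20, seed0 = 0,
                                      config_args = list()) {
  res <- lapply(seq_len(n_seeds), function(s) {
    cfg <- do.call(atac_sim_config, c(config_args, list(seed = seed0 + s)))
    sim <- generate_atac_counts(cfg)
    kept <- filter_peaks(sim$counts)
    bin <- binarize(sim$counts[kept, ])
    ok <- Matrix::colSums(bin) > 0
    bin <- bin[, ok, drop = FALSE]
    sv <- svd_embed(tfidf(bin), k = min(50, min(dim(bin)) - 1))
    cl <- cluster_atac(sv, seed = seed0 + s)
    keep <- cl$labels != -1
    truth <- sim$truth$cell_cluster[ok]
    data.frame(seed = seed0 + s,
               ari = adjusted_rand_index(cl$labels[keep], truth[keep]),
               n_clusters = length(unique(cl$labels[keep])))
  })
  do.call(rbind, res)
}

#' Parameter-recovery benchmark
#'
#' One pass over the generators measuring: Pearson correlation of
#' estimated size factors with planted depths; sensitivity and false
#' positive rate of pseudotime-correlated gene selection (planted
#' monotone reporters vs genes carrying no program); Spearman agreement
#' of diffusion pseudotime with ground truth; and cell-cycle
#' classification accuracy.
#'
#' @param seed RNG seed for the simulated datasets.
#' @return Named list with `size_factor_cor`, `correlated_sensitivity`,
#'   `correlated_fpr`, `dpt_rho`, `cycling_accuracy`.
#' @export
benchmark_parameter_recovery <- function(seed = 1) {
  rna <- generate_rna_counts(rna_sim_config(seed = seed))
  sf <- estimate_size_factors(rna$counts)
  sf_cor <- cor(as.numeric(sf), rna$truth$depths)

  sim <- generate_trajectory_counts(trajectory_sim_config(seed = seed))
  norm <- as.matrix(normalize_counts(sim$counts,
                                     estimate_size_factors(sim$counts)))
  truth <- sim$truth
  prog <- c(truth$dynamic_genes, unlist(truth$arm_genes))
  dm <- diffusion_map(norm[prog, , drop = FALSE], k = 10)
  dpt <- diffusion_pseudotime(dm, which.min(truth$cell_pseudotime))
  dpt_rho <- abs(cor(dpt, truth$cell_pseudotime, method = "spearman"))
  tab <- correlated_genes(norm, dpt, truth$cell_cluster)
  planted <- truth$monotone_genes
  nulls <- setdiff(rownames(norm), c(prog, truth$module_genes))
  sens <- mean(tab$correlated[tab$gene_id %in% planted])
  fpr <- mean(tab$correlated[tab$gene_id %in% nulls])

  cc <- generate_cellcycle_fixture(seed = seed)
  sc <- cellcycle_scores(cc$expr, cc$gene_sets)
  acc <- mean(classify_cycling(sc) == cc$cycling)

  list(size_factor_cor = sf_cor, correlated_sensitivity = sens,
       correlated_fpr = fpr, dpt_rho = dpt_rho, cycling_accuracy = acc)
}

#' Motif-deviation calibration benchmark
#'
#' Null calibration: Z-scores of motifs hitting random peak subsets
#' should be approximately standard normal across cells. Directional
#' recovery: motifs planted as enriched in one cluster's specific peaks
#' should score higher in that cluster than elsewhere.
#'
#' @param n_null_seeds datasets for the null summary (default 3).
#' @param n_dir_seeds datasets for the directional rate (default 100).
#' @param seed0 base seed.
#' @param B background sets per motif.
#' @return List with `null_abs_mean`, `null_sd`, `direction_rate`.
#' @export
benchmark_deviation_calibration <- function(n_null_seeds = 3,
                                            n_dir_seeds = 100, seed0 = 0,
                                            B = 50) {
  null_stats <- lapply(seq_len(n_null_seeds), function(s) {
    sim <- generate_atac_counts(atac_sim_config(seed = seed0 + s))
    kept <- filter_peaks(sim$counts)
    counts <- sim$counts[kept, ]$counts
    planted <- names(sim$truth$motif_cluster_enrichment)
    hits <- as.matrix(sim$motif_hits[setdiff(rownames(sim$motif_hits),
                                             planted)[1:10], kept])
    dev <- motif_deviation_zscores(counts, hits, B = B, seed = seed0 + s)
    c(mean = mean(abs(rowMeans(dev$z))), sd = mean(apply(dev$z, 1, sd)))
  })
  null_stats <- do.call(rbind, null_stats)
  dir_ok <- vapply(seq_len(n_dir_seeds), function(s) {
    sim <- generate_atac_counts(atac_sim_config(seed = seed0 + 100 + s))
    kept <- filter_peaks(sim$counts)
    counts <- sim$counts[kept, ]$counts
    planted <- names(sim$truth$motif_cluster_enrichment)
    hits <- as.matrix(sim$motif_hits[planted, kept, drop = FALSE])
    dev <- motif_deviation_zscores(counts, hits, B = B, seed = seed0 + s)
    all(vapply(planted, function(mo) {
      k <- sim$truth$motif_cluster_enrichment[[mo]]
      incl <- sim$truth$cell_cluster == k
      mean(dev$z[mo, incl]) > mean(dev$z[mo, !incl])
    }, logical(1)))
  }, logical(1))
  list(null_abs_mean = mean(null_stats[, "mean"]),
       null_sd = mean(null_stats[, "sd"]),
       direction_rate = mean(dir_ok))
}

#' Depth correlation of the first SVD component
#'
#' On strongly depth-varying synthetic accessibility, correlates the
#' first SVD component's cell scores with the log-scaled accessible-peak
#' count per cell — the standard diagnostic motivating the exclusion of
#' component 1 before clustering.
#'
#' @param seed RNG seed.
#' @param depth_range per-cell total-count range; the default spans
#'   roughly a 20-fold spread.
#' @return List with `r_log` (vs log accessible peaks) and `r_raw`
#'   (vs raw accessible peaks).
#' @export
benchmark_depth_correlation <- function(seed = 1,
                                        depth_range = c(100, 2000)) {
  sim <- generate_atac_counts(atac_sim_config(depth_range = depth_range,
                                              seed = seed))
  kept <- filter_peaks(sim$counts)
  bin <- binarize(sim$counts[kept, ])
  ok <- Matrix::colSums(bin) > 0
  bin <- bin[, ok, drop = FALSE]
  sv <- svd_embed(tfidf(bin), k = 50)
  comp1 <- attr(sv, "all_components")[, 1]
  np <- Matrix::colSums(bin)
  list(r_log = abs(cor(comp1, log(np))), r_raw = abs(cor(comp1, np)))
}
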