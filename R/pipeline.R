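#' Assemble a pipeline configuration
#'
#' Collects every tunable parameter of the RNA and ATAC arms with its
#' default, plus a global seed from which per-stage seeds are derived
#' (stage-name hashed), so that stages are individually reproducible.
#' Unknown parameter names are rejected.
#'
#' @param seed global RNG seed.
#' @param simulate which synthetic preset to analyse: `"trajectory"`,
#'   `"rna"`, `"atac"`, or `"both"` (trajectory RNA + ATAC).
#' @param out_dir output directory for result tables and the manifest.
#' @param ... overrides for named parameters; see Details.
#' @details Parameters (defaults): `hetero_window` (200), `hetero_q`
#'   (0.99), `som_epochs` (2000), `som_grid` (NULL = auto),
#'   `tsne_perplexity_rna` (15), `tsne_perplexity_atac` (21),
#'   `tsne_iterations` (2000), `hdbscan_rna` (c(7, 9)), `hdbscan_atac`
#'   (c(11, 9)), `bootstrap_cells` (30), `bootstrap_reps` (1000),
#'   `rho_global` (0.7), `rho_local` (0.5), `smooth_window` (11),
#'   `pair_rna_window` (15), `pair_atac_window` (13), `peak_min_cells`
#'   (35), `peak_max_mean` (15), `svd_k` (50), `deviation_z` (1.5),
#'   `specific_alpha` (1e-5), `tss_threshold_kb` (2.5), plus the
#'   simulation configs `sim_rna`, `sim_trajectory`, `sim_atac`
#'   (argument lists for the generators).
#' @return A list of class `sct_pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, simulate = "trajectory",
                            out_dir = "sct_out", ...) {
  defaults <- list(
    hetero_window = 200, hetero_q = 0.99,
    som_epochs = 2000, som_grid = NULL,
    tsne_perplexity_rna = 15, tsne_perplexity_atac = 21,
    tsne_iterations = 2000,
    hdbscan_rna = c(7, 9), hdbscan_atac = c(11, 9),
    bootstrap_cells = 30, bootstrap_reps = 1000,
    rho_global = 0.7, rho_local = 0.5,
    smooth_window = 11, pair_rna_window = 15, pair_atac_window = 13,
    peak_min_cells = 35, peak_max_mean = 15,
    svd_k = 50, deviation_z = 1.5, specific_alpha = 1e-5,
    tss_threshold_kb = 2.5,
    sim_rna = list(), sim_trajectory = list(), sim_atac = list())
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  defaults[names(overrides)] <- overrides
  if (!simulate %in% c("trajectory", "rna", "atac", "both"))
    stop("simulate must be one of 'trajectory', 'rna', 'atac', 'both'")
  structure(c(list(seed = seed, simulate = simulate, out_dir = out_dir),
              defaults),
            class = "sct_pipeline_config")
}

#' Run the full analysis pipeline on simulated data
#'
#' Executes the RNA arm (QC, gene filtering, normalization,
#' heterogeneous-gene selection, SOM metagenes, t-SNE + HDBSCAN,
#' markers, transition index, cell distances, diffusion pseudotime, gene
#' dynamics) and/or the ATAC arm (peak filtering, TF-IDF, SVD, t-SNE +
#' HDBSCAN, cluster-specific peaks, motif deviations) on the configured
#' synthetic preset, writing result tables (TSV) and a deterministic
#' JSON run manifest (parameters, seeds, per-stage summaries; no
#' timestamps) under `out_dir`.
#'
#' @param config an [pipeline_config()].
#' @return Invisibly, a list with the in-memory results and the manifest.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "sct_pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "scTransit",
                   version = as.character(utils::packageVersion("scTransit")),
                   seed = config$seed, simulate = config$simulate,
                   parameters = config[setdiff(names(config),
                                               c("seed", "simulate", "out_dir"))],
                   stages = list())
  results <- list()
  run_rna <- config$simulate %in% c("trajectory", "rna", "both")
  run_atac <- config$simulate %in% c("atac", "both")

  if (run_rna) {
    preset <- if (config$simulate == "rna") "rna" else "trajectory"
    sim <- if (preset == "rna") {
      cfg <- do.call(rna_sim_config,
                     c(config$sim_rna[setdiff(names(config$sim_rna), "seed")],
                       list(seed = stage_seed(config$seed, "sim_rna"))))
      generate_rna_counts(cfg)
    } else {
      cfg <- do.call(trajectory_sim_config,
                     c(config$sim_trajectory[setdiff(names(config$sim_trajectory), "seed")],
                       list(seed = stage_seed(config$seed, "sim_trajectory"))))
      generate_trajectory_counts(cfg)
    }
    counts <- sim$counts
    # cell QC (trajectory preset has no mito/housekeeping flags: metrics
    # whose inputs are absent are skipped by design)
    qc <- suppressWarnings(compute_cell_qc(counts))
    qc <- flag_low_quality_cells(qc)
    kept_cells <- which(qc$keep)
    counts_f <- counts[, kept_cells]
    truth_cluster <- sim$truth$cell_cluster[kept_cells]
    genes_kept <- filter_genes(counts_f, min_total = 200, min_cells = 5)
    if (length(genes_kept) < 50) genes_kept <- counts_f$feature_ids
    counts_f <- counts_f[genes_kept, ]
    sf <- estimate_size_factors(counts_f)
    norm <- normalize_counts(counts_f, sf)
    stats <- compute_gene_stats(norm)
    window <- min(config$hetero_window, max(50, nrow(norm) %/% 4))
    hetero <- select_heterogeneous(stats, window = window, q = config$hetero_q)
    hg <- hetero$gene_id
    # the metagene map needs a workable basis: top up very small
    # selections by within-window z-score rank
    if (length(hg) < 50) {
      all_genes <- attr(hetero, "all_genes")
      ranked <- all_genes$gene_id[order(-pmax(all_genes$z_cv,
                                              all_genes$z_drop))]
      hg <- union(hg, head(ranked, 50))
    }
    manifest$stages$rna_qc <- list(cells_in = ncol(counts$counts),
                                   cells_kept = length(kept_cells),
                                   genes_kept = length(genes_kept),
                                   heterogeneous_genes = length(hg))
    scaled <- t(scale(t(as.matrix(norm[hg, , drop = FALSE]))))
    scaled[is.na(scaled)] <- 0
    som <- train_som(scaled, grid_shape = config$som_grid,
                     epochs = config$som_epochs,
                     seed = stage_seed(config$seed, "som"))
    mg <- metagene_matrix(som, scaled)
    perp <- min(config$tsne_perplexity_rna, (nrow(mg) - 2) %/% 3)
    emb <- embed_tsne(mg, perplexity = perp,
                      iterations = config$tsne_iterations,
                      seed = stage_seed(config$seed, "tsne_rna"))
    cl <- cluster_hdbscan(emb, min_cluster_size = config$hdbscan_rna[1],
                          min_samples = config$hdbscan_rna[2])
    manifest$stages$rna_cluster <- list(
      n_clusters = length(unique(cl$labels[cl$labels != -1])),
      n_outliers = sum(cl$labels == -1),
      ari_vs_truth = round(adjusted_rand_index(
        cl$labels[cl$labels != -1], truth_cluster[cl$labels != -1]), 4))
    markers <- tryCatch(find_markers_auroc(as.matrix(norm), cl$labels),
                        error = function(e) NULL)
    marker_genes <- if (!is.null(markers) && any(markers$marker))
      unique(markers$gene_id[markers$marker]) else hg
    labels_for_ic <- if (length(unique(cl$labels[cl$labels != -1])) >= 2)
      cl$labels else truth_cluster
    ic <- bootstrap_ic(as.matrix(norm[marker_genes, , drop = FALSE]),
                       labels_for_ic,
                       n_cells = config$bootstrap_cells,
                       reps = config$bootstrap_reps,
                       seed = stage_seed(config$seed, "bootstrap_ic"))
    dists <- pairwise_cell_distances(as.matrix(norm[hg, , drop = FALSE]),
                                     labels_for_ic)
    dm <- diffusion_map(as.matrix(norm[marker_genes, , drop = FALSE]),
                        k = min(10, ncol(norm) - 2))
    root <- if (preset == "trajectory")
      which.min(sim$truth$cell_pseudotime[kept_cells]) else 1L
    dpt <- diffusion_pseudotime(dm, root)
    cg <- correlated_genes(as.matrix(norm), dpt, labels_for_ic,
                           global_min = config$rho_global,
                           local_min = config$rho_local)
    ord <- order(dpt)
    corr_ids <- cg$gene_id[cg$correlated]
    dyn <- NULL
    if (length(corr_ids)) {
      trends <- t(apply(as.matrix(norm[corr_ids, , drop = FALSE]), 1,
                        function(v) moving_mean(v[ord], config$smooth_window)))
      rownames(trends) <- corr_ids
      dyn <- categorize_dynamics(trends)
    }
    manifest$stages$rna_trajectory <- list(
      n_marker_genes = length(marker_genes),
      n_correlated = length(corr_ids),
      dpt_truth_rho = if (preset == "trajectory")
        round(cor(dpt, sim$truth$cell_pseudotime[kept_cells],
                  method = "spearman"), 4) else NA)
    write.table(data.frame(cell_id = colnames(norm), cluster = cl$labels,
                           tsne_1 = emb[, 1], tsne_2 = emb[, 2], dpt = dpt),
                file.path(config$out_dir, "rna_cells.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(ic, file.path(config$out_dir, "rna_transition_index.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(markers))
      write.table(markers, file.path(config$out_dir, "rna_markers.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    results$rna <- list(qc = qc, clusters = cl, ic = ic, distances = dists,
                        dpt = dpt, markers = markers, dynamics = dyn,
                        truth = sim$truth)
  }

  if (run_atac) {
    cfg <- do.call(atac_sim_config,
                   c(config$sim_atac[setdiff(names(config$sim_atac), "seed")],
                     list(seed = stage_seed(config$seed, "sim_atac"))))
    sim <- generate_atac_counts(cfg)
    kept_peaks <- filter_peaks(sim$counts,
                               min_cells = config$peak_min_cells,
                               max_mean = config$peak_max_mean)
    counts_f <- sim$counts[kept_peaks, ]
    bin <- binarize(counts_f)
    ok_cells <- Matrix::colSums(bin) > 0
    bin <- bin[, ok_cells, drop = FALSE]
    truth_cluster <- sim$truth$cell_cluster[ok_cells]
    w <- tfidf(bin)
    k <- min(config$svd_k, min(dim(w)) - 1)
    sv <- svd_embed(w, k = k)
    emb <- embed_tsne(sv, perplexity = config$tsne_perplexity_atac,
                      iterations = config$tsne_iterations,
                      seed = stage_seed(config$seed, "tsne_atac"))
    cl <- cluster_hdbscan(emb, min_cluster_size = config$hdbscan_atac[1],
                          min_samples = config$hdbscan_atac[2])
    labels_for_peaks <- if (length(unique(cl$labels[cl$labels != -1])) >= 2)
      cl$labels else truth_cluster
    spec <- cluster_specific_peaks(bin, labels_for_peaks,
                                   alpha = config$specific_alpha)
    dev <- motif_deviation_zscores(
      counts_f$counts[, ok_cells, drop = FALSE],
      sim$motif_hits[, kept_peaks, drop = FALSE],
      seed = stage_seed(config$seed, "deviations"))
    anno <- annotate_peak_distance(
      sim$peaks[sim$peaks$peak_id %in% kept_peaks, ],
      data.frame(chrom = "chr1", start = seq(0, 1000000, by = 100000),
                 end = seq(0, 1000000, by = 100000) + 1),
      threshold_kb = config$tss_threshold_kb)
    manifest$stages$atac <- list(
      peaks_in = nrow(sim$counts$counts), peaks_kept = length(kept_peaks),
      n_clusters = length(unique(cl$labels[cl$labels != -1])),
      ari_vs_truth = round(adjusted_rand_index(
        cl$labels[cl$labels != -1], truth_cluster[cl$labels != -1]), 4),
      n_specific_peaks = nrow(spec),
      n_variable_motifs = length(variable_motifs(dev, config$deviation_z)))
    write.table(data.frame(cell_id = colnames(bin), cluster = cl$labels,
                           tsne_1 = emb[, 1], tsne_2 = emb[, 2]),
                file.path(config$out_dir, "atac_cells.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(spec, file.path(config$out_dir, "atac_specific_peaks.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(round(dev$z, 6),
                file.path(config$out_dir, "atac_motif_z.tsv"),
                sep = "\t", quote = FALSE, col.names = NA)
    results$atac <- list(clusters = cl, specific = spec, deviations = dev,
                         annotation = anno, truth = sim$truth)
  }

  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(c(results, list(manifest = manifest,
                            manifest_path = manifest_path)))
}
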