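test_that("generators are pure functions of their configs", {
  r1 <- generate_rna_counts(rna_sim_config(n_genes = 200, n_cells = 50, seed = 3))
  r2 <- generate_rna_counts(rna_sim_config(n_genes = 200, n_cells = 50, seed = 3))
  expect_identical(as.matrix(r1$counts$counts), as.matrix(r2$counts$counts))
  expect_identical(r1$truth, r2$truth)
  t1 <- generate_trajectory_counts(trajectory_sim_config(n_genes = 100,
                                                         n_cells = 50, seed = 4))
  t2 <- generate_trajectory_counts(trajectory_sim_config(n_genes = 100,
                                                         n_cells = 50, seed = 4))
  expect_identical(as.matrix(t1$counts$counts), as.matrix(t2$counts$counts))
  a1 <- generate_atac_counts(atac_sim_config(n_peaks = 300, n_cells = 40, seed = 5))
  a2 <- generate_atac_counts(atac_sim_config(n_peaks = 300, n_cells = 40, seed = 5))
  expect_identical(as.matrix(a1$counts$counts), as.matrix(a2$counts$counts))
  expect_identical(as.matrix(a1$motif_hits), as.matrix(a2$motif_hits))
  c1 <- generate_cellcycle_fixture(n_cells = 40, seed = 6)
  c2 <- generate_cellcycle_fixture(n_cells = 40, seed = 6)
  expect_identical(c1, c2)
  # the caller's RNG stream is left untouched
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(generate_rna_counts(rna_sim_config(n_genes = 50,
                                                            n_cells = 20)))
  expect_identical(runif(1), before)
})

test_that("invalid configurations name the offending field", {
  expect_error(rna_sim_config(nb_dispersion = -1), "nb_dispersion")
  expect_error(rna_sim_config(depth_range = c(5, 1)), "depth_range")
  expect_error(trajectory_sim_config(branch_point = 1.2), "branch_point")
  expect_error(trajectory_sim_config(noise_inflation = 0.5), "noise_inflation")
  expect_error(trajectory_sim_config(coordination_drop = 0), "coordination_drop")
  expect_error(atac_sim_config(specific_fraction = 1), "specific_fraction")
  expect_error(atac_sim_config(motif_peak_density = 0), "motif_peak_density")
  expect_error(generate_cellcycle_fixture(n_set_genes = 3), "n_set_genes")
})

test_that("counts are non-negative integers without NaN", {
  sim <- generate_rna_counts(rna_sim_config(n_genes = 200, n_cells = 60, seed = 7))
  x <- as.matrix(sim$counts$counts)
  expect_false(anyNA(x))
  expect_true(all(x >= 0 & x == round(x)))
  a <- generate_atac_counts(atac_sim_config(n_peaks = 400, n_cells = 50, seed = 7))
  xa <- as.matrix(a$counts$counts)
  expect_false(anyNA(xa))
  expect_true(all(xa >= 0 & xa == round(xa)))
})

test_that("dropout rate decreases with expression, by direct binning", {
  sim <- generate_rna_counts(rna_sim_config(n_genes = 500, n_cells = 300,
                                            seed = 8))
  x <- as.matrix(sim$counts$counts)
  gene_mean <- rowMeans(x)
  dropout <- rowMeans(x == 0)
  ok <- gene_mean > 0
  bins <- cut(log(gene_mean[ok]), breaks = 10)
  bin_drop <- tapply(dropout[ok], bins, mean)
  bin_drop <- bin_drop[!is.na(bin_drop)]
  expect_lt(cor(seq_along(bin_drop), bin_drop, method = "spearman"), 0)
  expect_true(all(diff(bin_drop[1:5]) <= 0.1))  # monotone trend, small slack
})

test_that("a zero log-fold effect yields null differential signal", {
  sim <- generate_rna_counts(rna_sim_config(n_genes = 300, n_cells = 150,
                                            n_clusters = 3, lfc_scale = 0,
                                            seed = 9))
  norm <- normalize_counts(sim$counts,
                           estimate_size_factors(sim$counts))
  x <- as.matrix(norm)
  cl <- factor(sim$truth$cell_cluster)
  pvals <- apply(x[rowSums(x) > 0, ], 1, function(v)
    kruskal.test(v, cl)$p.value)
  expect_lt(mean(pvals < 0.05), 0.1)
})

test_that("ATAC column sums always land in the configured depth range", {
  cfg <- atac_sim_config(n_peaks = 500, n_cells = 50, seed = 10)
  sim <- generate_atac_counts(cfg)
  cs <- Matrix::colSums(sim$counts$counts)
  expect_true(all(cs >= cfg$depth_range[1] & cs <= cfg$depth_range[2]))
})

test_that("ATAC defaults are sparse with home-cluster-specific peaks", {
  sim <- generate_atac_counts(atac_sim_config(seed = 11))
  m <- sim$counts$counts
  expect_gte(1 - Matrix::nnzero(m) / prod(dim(m)), 0.9)
  truth <- sim$truth
  bin <- binarize(sim$counts)
  freq_ok <- vapply(seq_along(truth$specific_peaks), function(k) {
    peaks <- truth$specific_peaks[[k]]
    incl <- truth$cell_cluster == k
    home <- Matrix::rowMeans(bin[peaks, incl, drop = FALSE])
    away <- Matrix::rowMeans(bin[peaks, !incl, drop = FALSE])
    mean(home > away)
  }, numeric(1))
  expect_true(all(freq_ok > 0.95))
  # peak coordinates are valid half-open intervals
  expect_true(all(sim$peaks$start < sim$peaks$end))
  expect_true(all(sim$peaks$start >= 0))
})

test_that("a null transition cluster is statistically unremarkable", {
  # residual per-cell variance in the transition cluster matches flanking
  # clusters when neither noise inflation nor coordination loss is planted
  # compare cells of the transition bin against flanking cells in a
  # matched narrow pseudotime band (so program level differences along
  # the trajectory do not masquerade as noise), detrending each gene
  # linearly on pseudotime and excluding arm-restricted program genes
  null_variance_p <- function(s, ni = 1, cd = 1) {
    sim <- generate_trajectory_counts(trajectory_sim_config(
      n_genes = 150, n_cells = 150, noise_inflation = ni,
      coordination_drop = cd, seed = 1000 + s))
    x <- log2(as.matrix(sim$counts$counts) + 1)
    x <- x[setdiff(rownames(x), unlist(sim$truth$arm_genes)), ]
    cl <- sim$truth$cell_cluster
    t <- sim$truth$cell_pseudotime
    resid_var <- function(cells) {
      sub <- x[, cells, drop = FALSE]
      fit <- t(apply(sub, 1, function(v)
        stats::lm.fit(cbind(1, t[cells]), v)$residuals))
      colMeans(fit^2)
    }
    tcells <- which(cl == sim$truth$transition_cluster)
    fcells <- which(cl != sim$truth$transition_cluster &
                      abs(t - 0.5) > 0.05 & abs(t - 0.5) <= 0.16)
    wilcox.test(resid_var(tcells), resid_var(fcells))$p.value
  }
  pvals <- vapply(1:50, null_variance_p, numeric(1))
  expect_gte(mean(pvals > 0.05), 0.9)
  # the same comparison must reject when the effects are planted
  p_alt <- vapply(1:5, null_variance_p, numeric(1), ni = 3, cd = 0.5)
  expect_true(all(p_alt < 0.05))
})

test_that("planted transition effects raise residual cell variance directly", {
  sim <- generate_trajectory_counts(trajectory_sim_config(seed = 13))
  norm <- normalize_counts(sim$counts, estimate_size_factors(sim$counts))
  dd <- pairwise_cell_distances(as.matrix(norm[sim$truth$dynamic_genes, ]),
                                sim$truth$cell_cluster)
  tc <- sim$truth$transition_cluster
  fl <- sim$truth$flanking_clusters
  expect_gt(dd$median[dd$cluster == tc], max(dd$median[dd$cluster %in% fl]))
})

test_that("planted monotone reporters track ground-truth pseudotime", {
  sim <- generate_trajectory_counts(trajectory_sim_config(seed = 14))
  norm <- as.matrix(normalize_counts(sim$counts,
                                     estimate_size_factors(sim$counts)))
  rhos <- abs(apply(norm[sim$truth$monotone_genes, ], 1, cor,
                    y = sim$truth$cell_pseudotime, method = "spearman"))
  expect_gt(max(rhos), 0.9)
  expect_gt(median(rhos), 0.75)
})

test_that("a null cell-cycle fixture shows no cycling signal", {
  set.seed(15)
  ks_ok <- vapply(1:10, function(s) {
    fx <- generate_cellcycle_fixture(n_cells = 120, cycling_fraction = 0,
                                     seed = 2000 + s)
    sc <- suppressWarnings(cellcycle_scores(fx$expr, fx$gene_sets))
    # split cells arbitrarily: refined scores must be exchangeable
    half <- seq_len(60)
    ks <- suppressWarnings(stats::ks.test(sc$refined[half, "S"],
                                          sc$refined[-half, "S"]))
    ks$p.value > 0.05
  }, logical(1))
  expect_gte(mean(ks_ok), 0.9)
})
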