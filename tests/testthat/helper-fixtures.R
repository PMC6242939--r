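# Shared fixture builders; everything is generated in code at test time.

# small dense count matrix with ids
tiny_counts <- function(mat, mito = integer(0), housekeeping = integer(0)) {
  fm <- data.frame(is_mitochondrial = seq_len(nrow(mat)) %in% mito,
                   is_housekeeping = seq_len(nrow(mat)) %in% housekeeping)
  count_matrix(mat,
               feature_ids = paste0("g", seq_len(nrow(mat))),
               cell_ids = paste0("c", seq_len(ncol(mat))),
               feature_meta = fm)
}

# NB counts with known per-cell depth multipliers and a common profile
nb_depth_fixture <- function(n_genes = 300, n_cells = 100, seed = 42) {
  set.seed(seed)
  profile <- rgamma(n_genes, 2, 0.5)
  depth <- runif(n_cells, 0.3, 3)
  mu <- outer(profile, depth)
  counts <- matrix(rnbinom(n_genes * n_cells, mu = mu, size = 10),
                   n_genes, n_cells,
                   dimnames = list(paste0("g", seq_len(n_genes)),
                                   paste0("c", seq_len(n_cells))))
  list(counts = counts, depth = depth)
}

# two well-separated 2-D blobs
two_blobs <- function(n_per = 50, gap = 100, seed = 1) {
  set.seed(seed)
  rbind(cbind(rnorm(n_per), rnorm(n_per)),
        cbind(rnorm(n_per) + gap, rnorm(n_per)))
}

# brute-force within-window heterogeneous-gene selection (independent oracle)
brute_select_hetero <- function(stats, window = 200, q = 0.99) {
  stats <- stats[!is.na(stats$cv_g), ]
  stats <- stats[order(stats$mean_g, stats$gene_id), ]
  n <- nrow(stats)
  n_windows <- max(1, n %/% window)
  sel <- character(0)
  for (w in seq_len(n_windows)) {
    lo <- (w - 1) * window + 1
    hi <- if (w == n_windows) n else w * window
    idx <- lo:hi
    zc <- (stats$cv_g[idx] - mean(stats$cv_g[idx])) /
      (if (sd(stats$cv_g[idx]) == 0) 1 else sd(stats$cv_g[idx]))
    zd <- (stats$drop_g[idx] - mean(stats$drop_g[idx])) /
      (if (sd(stats$drop_g[idx]) == 0) 1 else sd(stats$drop_g[idx]))
    hit <- zc > quantile(zc, q) | zd > quantile(zd, q)
    sel <- c(sel, stats$gene_id[idx][hit])
  }
  sort(sel)
}
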