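#' Configuration for the scATAC generator
#'
#' Defaults describe a sparse accessibility experiment: 5000 peaks, 400
#' cells in 5 clusters, 20% of peaks cluster-specific, 60% of each
#' cell's reads allocated to its cluster's signal profile, 200-800 total
#' counts per cell (over 90% of matrix entries zero), and 50 motifs with
#' a 5% baseline hit density; one motif per cluster is planted as
#' enriched in that cluster's specific peaks.
#'
#' @param n_peaks,n_cells,n_clusters dimensions.
#' @param specific_fraction fraction of peaks cluster-specific (0 gives
#'   clusterless data).
#' @param mean_frip fraction of a cell's reads following the cluster
#'   signal profile (the rest is uniform background).
#' @param depth_range per-cell total counts c(min, max); column sums
#'   always fall in this range.
#' @param n_motifs number of motifs.
#' @param motif_peak_density baseline motif-peak hit probability.
#' @param seed RNG seed.
#' @return A list of class `sct_atac_sim_config`.
#' @export
atac_sim_config <- function(n_peaks = 5000, n_cells = 400, n_clusters = 5,
                            specific_fraction = 0.2, mean_frip = 0.6,
                            depth_range = c(200, 800), n_motifs = 50,
                            motif_peak_density = 0.05, seed = 1) {
  check_count(n_peaks, "n_peaks", 100)
  check_count(n_cells, "n_cells", 10)
  check_count(n_clusters, "n_clusters", 1)
  if (specific_fraction < 0 || specific_fraction >= 1)
    stop("configuration error: `specific_fraction` must lie in [0,1)")
  check_fraction(mean_frip, "mean_frip")
  if (length(depth_range) != 2 || any(depth_range <= 0) ||
      depth_range[1] > depth_range[2])
    stop("configuration error: `depth_range` must be positive c(min, max)")
  check_count(n_motifs, "n_motifs", 1)
  check_fraction(motif_peak_density, "motif_peak_density")
  structure(list(n_peaks = n_peaks, n_cells = n_cells,
                 n_clusters = n_clusters,
                 specific_fraction = specific_fraction,
                 mean_frip = mean_frip, depth_range = depth_range,
                 n_motifs = n_motifs,
                 motif_peak_density = motif_peak_density, seed = seed),
            class = "sct_atac_sim_config")
}

#' Simulate sparse scATAC counts with peaks, motifs and ground truth
#'
#' Per cell, a total count is drawn uniformly from `depth_range` and
#' distributed multinomially over peaks: a `mean_frip` share follows the
#' cell's cluster signal profile (shared peaks plus a strong boost on
#' the cluster's specific peaks) and the remainder is uniform
#' background, producing near-binary sparse counts whose column sums are
#' inside `depth_range` by construction. Peaks get non-overlapping
#' synthetic coordinates (0-based half-open, 500 bp) on five synthetic
#' chromosomes. Motif hits are Bernoulli at the baseline density, with
#' one planted motif per cluster whose density is five-fold in that
#' cluster's specific peaks.
#'
#' @param config an [atac_sim_config()].
#' @return List with `counts` (an [count_matrix()], peaks x cells),
#'   `peaks` (data.frame `chrom`, `start`, `end`, `peak_id`),
#'   `motif_hits` (motifs x peaks 0/1 sparse matrix) and `truth`
#'   (`cell_cluster`, `specific_peaks` per cluster, `depths`,
#'   `motif_cluster_enrichment`).
#' @export
generate_atac_counts <- function(config = atac_sim_config()) {
  stopifnot(inherits(config, "sct_atac_sim_config"))
  with_seed(config$seed, {
    P <- config$n_peaks; N <- config$n_cells; K <- config$n_clusters
    peak_ids <- sprintf("peak_%05d", seq_len(P))
    n_spec <- floor(config$specific_fraction * P / max(K, 1)) * K
    spec_idx <- if (n_spec > 0) sample.int(P, n_spec) else integer(0)
    spec_cluster <- rep_len(seq_len(K), n_spec)  # peak -> home cluster
    base_w <- rgamma(P, shape = 2, rate = 2)
    cluster <- sort(rep_len(seq_len(K), N))
    # cluster signal profiles: shared baseline, boosted specific peaks
    signal <- matrix(base_w, P, K)
    if (n_spec > 0) {
      for (k in seq_len(K)) {
        own <- spec_idx[spec_cluster == k]
        other <- spec_idx[spec_cluster != k]
        signal[own, k] <- signal[own, k] * 8
        signal[other, k] <- signal[other, k] * 0.02
      }
    }
    signal <- sweep(signal, 2, colSums(signal), `/`)
    prob <- config$mean_frip * signal + (1 - config$mean_frip) / P
    depths <- round(runif(N, config$depth_range[1], config$depth_range[2]))
    counts <- matrix(0L, P, N)
    for (i in seq_len(N))
      counts[, i] <- rmultinom(1, depths[i], prob[, cluster[i]])
    peaks_per_chrom <- ceiling(P / 5)
    chrom <- paste0("chr", ((seq_len(P) - 1L) %/% peaks_per_chrom) + 1L)
    offset <- (seq_len(P) - 1L) %% peaks_per_chrom
    peaks <- data.frame(chrom = chrom, start = offset * 1500L,
                        end = offset * 1500L + 500L, peak_id = peak_ids,
                        stringsAsFactors = FALSE)
    motif_ids <- sprintf("motif_%03d", seq_len(config$n_motifs))
    hits <- matrix(rbinom(config$n_motifs * P, 1, config$motif_peak_density),
                   config$n_motifs, P, dimnames = list(motif_ids, peak_ids))
    enrich <- stats::setNames(integer(0), character(0))
    if (n_spec > 0) {
      planted <- seq_len(min(K, config$n_motifs))
      for (k in planted) {
        own <- spec_idx[spec_cluster == k]
        hits[k, own] <- rbinom(length(own), 1,
                               min(1, 5 * config$motif_peak_density))
      }
      enrich <- stats::setNames(planted, motif_ids[planted])
    }
    cm <- count_matrix(counts, feature_ids = peak_ids,
                       cell_ids = sprintf("cell_%04d", seq_len(N)),
                       cell_meta = data.frame(cluster = cluster))
    spec_sets <- if (n_spec > 0)
      lapply(seq_len(K), function(k) peak_ids[spec_idx[spec_cluster == k]])
    else rep(list(character(0)), K)
    list(counts = cm, peaks = peaks,
         motif_hits = Matrix::Matrix(hits, sparse = TRUE),
         truth = list(cell_cluster = cluster,
                      specific_peaks = stats::setNames(spec_sets,
                                                       paste0("cluster_", seq_len(K))),
                      depths = depths,
                      motif_cluster_enrichment = enrich))
  })
}
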