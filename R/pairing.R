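#' Pair RNA expression and ATAC motif-accessibility trends
#'
#' Compares pseudotime-ordered trends of transcription-factor expression
#' (RNA) and of the corresponding motif's accessibility deviation (ATAC).
#' RNA values are mean-centered and smoothed with a moving mean of
#' `rna_window` (15) cells, ATAC deviations with `atac_window` (13)
#' cells; trends of unequal length are linearly resampled to a common
#' grid. For every gene-motif pair the cross-correlation over lags up to
#' `max_lag_frac` of the trajectory is scanned; the pattern is
#' `"matched"` when the best lag is within `match_frac` of the length,
#' `"rna_precedes"` when expression leads accessibility, and
#' `"atac_precedes"` otherwise. The scan maximizes the signed
#' correlation, so anti-correlated pairs never reach a confident call:
#' pairs whose best correlation stays below `min_cor` are flagged
#' low-confidence.
#'
#' @param rna_trend genes-by-ordered-cells matrix (columns in pseudotime
#'   order).
#' @param atac_trend motifs-by-ordered-cells matrix (same ordering
#'   convention; may have a different number of columns).
#' @param pairs data.frame with columns `gene_id`, `motif_id`; pairs
#'   referencing a missing gene or motif are skipped with a warning.
#' @param rna_window,atac_window smoothing windows (15 / 13 cells).
#' @param max_lag_frac maximum scanned lag as a fraction of the common
#'   length (default 0.25).
#' @param match_frac lag tolerance for a "matched" call (default 0.05).
#' @param min_cor low-confidence threshold on max |cross-correlation|
#'   (default 0.3).
#' @return data.frame with `gene_id`, `motif_id`, `best_lag`,
#'   `best_cor`, `pattern`, `low_confidence`; smoothed resampled trends
#'   in attributes `"rna_smooth"` and `"atac_smooth"`.
#' @export
pair_rna_atac <- function(rna_trend, atac_trend, pairs,
                          rna_window = 15, atac_window = 13,
                          max_lag_frac = 0.25, match_frac = 0.05,
                          min_cor = 0.3) {
  rna <- as.matrix(rna_trend); atac <- as.matrix(atac_trend)
  L <- max(ncol(rna), ncol(atac))
  resample <- function(v, len) {
    if (length(v) == len) return(v)
    approx(seq_along(v), v, xout = seq(1, length(v), length.out = len))$y
  }
  smooth_rows <- function(mat, window, center) {
    t(apply(mat, 1, function(v) {
      if (center) v <- v - mean(v)
      resample(moving_mean(v, min(window, length(v) - (1 - length(v) %% 2))), L)
    }))
  }
  rna_s <- smooth_rows(rna, rna_window, center = TRUE)
  atac_s <- smooth_rows(atac, atac_window, center = FALSE)
  rownames(rna_s) <- rownames(rna); rownames(atac_s) <- rownames(atac)
  max_lag <- max(1L, floor(max_lag_frac * L))
  match_lag <- match_frac * L
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    g <- as.character(pairs$gene_id[i]); mo <- as.character(pairs$motif_id[i])
    if (!g %in% rownames(rna_s) || !mo %in% rownames(atac_s)) {
      warning("pair (", g, ", ", mo, ") references a missing trend; skipped")
      next
    }
    r <- rna_s[g, ]; a <- atac_s[mo, ]
    lags <- -max_lag:max_lag
    cc <- vapply(lags, function(l) {
      # positive lag: accessibility reproduces expression l cells later
      if (l >= 0) {
        xr <- r[seq_len(L - l)]; xa <- a[(1 + l):L]
      } else {
        xr <- r[(1 - l):L]; xa <- a[seq_len(L + l)]
      }
      if (sd(xr) == 0 || sd(xa) == 0) return(NA_real_)
      cor(xr, xa)
    }, numeric(1))
    best <- which.max(cc)   # signed: anti-correlated pairs stay low
    best_lag <- lags[best]; best_cor <- cc[best]
    pattern <- if (abs(best_lag) <= match_lag) "matched"
      else if (best_lag > 0) "rna_precedes" else "atac_precedes"
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = g, motif_id = mo, best_lag = best_lag,
      best_cor = best_cor, pattern = pattern,
      low_confidence = is.na(best_cor) || best_cor < min_cor,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "rna_smooth") <- rna_s
  attr(out, "atac_smooth") <- atac_s
  out
}

#' Select motifs with variable accessibility
#'
#' Returns motifs whose deviation Z-score exceeds `z_threshold` (1.5) in
#' magnitude in at least one cell, the selection used to pick
#' transcription factors for RNA:ATAC trend pairing.
#'
#' @param deviations an [motif_deviation_zscores()] result.
#' @param z_threshold magnitude cutoff (default 1.5).
#' @return Character vector of motif ids.
#' @export
variable_motifs <- function(deviations, z_threshold = 1.5) {
  stopifnot(inherits(deviations, "sct_deviations"))
  zmax <- apply(abs(deviations$z), 1, max, na.rm = TRUE)
  rownames(deviations$z)[zmax > z_threshold]
}
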