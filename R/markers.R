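#' Rank-based marker detection per cluster
#'
#' For each gene and each cluster, computes the cluster-versus-rest
#' AUROC from rank sums, a Welch 95% confidence interval on the log2
#' fold change (difference of means on log2-normalized values), and a
#' Wilcoxon rank-sum p-value (normal approximation with tie correction),
#' adjusted by Benjamini-Hochberg across genes within each cluster.
#' Genes are flagged `marker` when AUROC > `auroc_min` at
#' FDR < `fdr_max`, and `de` when the LFC interval clears `lfc_min` in
#' either direction at the same FDR.
#'
#' @param norm_matrix genes-by-cells matrix of log2-normalized expression.
#' @param labels integer cluster labels per cell; `-1` outliers are
#'   excluded. Clusters with fewer than 2 cells are skipped with a
#'   warning.
#' @param auroc_min AUROC threshold for the marker flag (default 0.8).
#' @param fdr_max FDR threshold (default 0.01).
#' @param lfc_min log2 fold-change bound threshold (default 2).
#' @return data.frame with columns `gene_id`, `cluster`, `auroc`, `lfc`,
#'   `lfc_lo`, `lfc_hi`, `p`, `fdr`, `marker`, `de`.
#' @export
find_markers_auroc <- function(norm_matrix, labels, auroc_min = 0.8,
                               fdr_max = 0.01, lfc_min = 2) {
  if (inherits(labels, "sct_clusters")) labels <- labels$labels
  m <- as.matrix(norm_matrix)
  if (is.null(rownames(m))) rownames(m) <- paste0("gene_", seq_len(nrow(m)))
  keep <- labels != -1
  m <- m[, keep, drop = FALSE]
  labels <- labels[keep]
  clusters <- sort(unique(labels))
  if (length(clusters) < 2) stop("need at least 2 non-outlier clusters")
  res <- list()
  for (cl in clusters) {
    in_cl <- labels == cl
    n1 <- sum(in_cl); n2 <- sum(!in_cl)
    if (n1 < 2) {
      warning("cluster ", cl, " has fewer than 2 cells; skipped")
      next
    }
    stats <- t(apply(m, 1, rank_sum_stats, in_cl = in_cl, n1 = n1, n2 = n2))
    x1 <- m[, in_cl, drop = FALSE]; x2 <- m[, !in_cl, drop = FALSE]
    mu1 <- rowMeans(x1); mu2 <- rowMeans(x2)
    v1 <- apply(x1, 1, var); v2 <- apply(x2, 1, var)
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    df[!is.finite(df) | df <= 0] <- n1 + n2 - 2
    tcrit <- qt(0.975, df)
    lfc <- mu1 - mu2
    fdr <- p.adjust(stats[, "p"], method = "BH")
    res[[length(res) + 1L]] <- data.frame(
      gene_id = rownames(m), cluster = cl,
      auroc = stats[, "auroc"], lfc = lfc,
      lfc_lo = lfc - tcrit * se, lfc_hi = lfc + tcrit * se,
      p = stats[, "p"], fdr = fdr,
      marker = stats[, "auroc"] > auroc_min & fdr < fdr_max,
      de = (lfc - tcrit * se > lfc_min | lfc + tcrit * se < -lfc_min) &
        fdr < fdr_max,
      stringsAsFactors = FALSE, row.names = NULL)
  }
  do.call(rbind, res)
}

# AUROC and Wilcoxon p (normal approximation, tie-corrected) from ranks.
rank_sum_stats <- function(x, in_cl, n1, n2) {
  r <- rank(x)
  R1 <- sum(r[in_cl])
  U <- R1 - n1 * (n1 + 1) / 2
  auroc <- U / (n1 * n2)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties)
  n <- n1 + n2
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (sigma2 <= 0) return(c(auroc = auroc, p = 1))
  z <- (U - n1 * n2 / 2) / sqrt(sigma2)
  c(auroc = auroc, p = 2 * pnorm(-abs(z)))
}
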