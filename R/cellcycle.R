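#' Cell-cycle stage scores with correlation refinement
#'
#' For each cell-cycle stage gene set (G1/S, S, G2, G2/M, M/G1) the raw
#' score of a cell is the average expression of the set's genes. The
#' score is refined by keeping only genes whose Spearman correlation with
#' the raw score exceeds `refine_cor` (default 0.4) and re-averaging;
#' refined scores are z-scored per stage.
#'
#' @param norm_expr genes-by-cells matrix of normalized expression.
#' @param gene_sets named list of character vectors (stage -> gene ids).
#'   Each set must retain at least 2 genes after intersection with the
#'   matrix; an empty intersection is an error naming the stage.
#' @param refine_cor rank-correlation threshold for refinement.
#' @return List of class `sct_cellcycle` with matrices `raw`, `refined`,
#'   `scaled` (cells x stages) and list `genes_used`.
#' @export
cellcycle_scores <- function(norm_expr, gene_sets, refine_cor = 0.4) {
  x <- as.matrix(norm_expr)
  stopifnot(is.list(gene_sets), length(gene_sets) > 0)
  stages <- names(gene_sets)
  raw <- refined <- matrix(NA_real_, ncol(x), length(stages),
                           dimnames = list(colnames(x), stages))
  genes_used <- list()
  for (st in stages) {
    genes <- intersect(gene_sets[[st]], rownames(x))
    if (length(genes) == 0)
      stop("gene set for stage '", st, "' has no genes in the matrix")
    if (length(genes) < 2)
      stop("gene set for stage '", st, "' needs >= 2 genes present")
    sub <- x[genes, , drop = FALSE]
    raw_st <- colMeans(sub)
    rho <- suppressWarnings(as.numeric(cor(t(sub), raw_st, method = "spearman")))
    keep <- !is.na(rho) & rho > refine_cor
    if (!any(keep)) {
      warning("no gene passed refinement for stage '", st, "'; using raw score")
      keep <- rep(TRUE, length(genes))
    }
    raw[, st] <- raw_st
    refined[, st] <- colMeans(sub[keep, , drop = FALSE])
    genes_used[[st]] <- genes[keep]
  }
  scaled <- scale(refined)
  scaled[, apply(refined, 2, sd) == 0] <- 0
  structure(list(raw = raw, refined = refined, scaled = scaled,
                 genes_used = genes_used),
            class = "sct_cellcycle")
}

#' Classify cells as cycling
#'
#' A cell is called cycling when its maximum scaled stage score exceeds
#' `threshold` (default 0: above-average commitment to at least one
#' stage).
#'
#' @param scores an [cellcycle_scores()] result.
#' @param threshold scaled-score cutoff.
#' @return Named logical vector per cell.
#' @export
classify_cycling <- function(scores, threshold = 0) {
  stopifnot(inherits(scores, "sct_cellcycle"))
  out <- apply(scores$scaled, 1, max) > threshold
  names(out) <- rownames(scores$scaled)
  out
}

#' Test equality of two proportions (Pearson chi-square)
#'
#' Pearson chi-square test on the 2x2 table `[[k1, n1-k1], [k2, n2-k2]]`
#' without continuity correction (df = 1), as used for comparing the
#' fraction of cycling cells or of smooth-muscle cells between
#' conditions.
#'
#' @param k1,n1 successes and trials in group 1.
#' @param k2,n2 successes and trials in group 2.
#' @return List of class `sct_proportion_test` with `table`, `chi2`,
#'   `p`, `proportions`.
#' @export
proportion_test <- function(k1, n1, k2, n2) {
  if (any(c(k1, n1, k2, n2) < 0) || k1 > n1 || k2 > n2)
    stop("need 0 <= k <= n in both groups")
  tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2, byrow = TRUE,
                dimnames = list(c("group1", "group2"), c("yes", "no")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate table: a margin is zero")
  ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
  structure(list(table = tab, chi2 = unname(ht$statistic),
                 p = ht$p.value,
                 proportions = c(p1 = k1 / n1, p2 = k2 / n2)),
            class = "sct_proportion_test")
}

#' @export
print.sct_proportion_test <- function(x, ...) {
  cat("2-sample test of equal proportions (Pearson chi-square, df = 1)\n")
  cat(sprintf("  p1 = %.4f, p2 = %.4f, X-squared = %.4g, p = %.4g\n",
              x$proportions[1], x$proportions[2], x$chi2, x$p))
  invisible(x)
}

#' Rule set for smooth-muscle-cell classification
#'
#' A cell is a smooth-muscle cell when the `null_gene` (Nkx2-5) is
#' essentially unexpressed (logTPM strictly below `null_max`) and at
#' least `min_panel_hits` of the panel genes are moderately-to-highly
#' expressed (logTPM strictly above `panel_min`).
#'
#' @param null_gene gene whose absence defines eligibility.
#' @param null_max upper bound for the null gene (default 1).
#' @param panel_genes smooth-muscle marker panel.
#' @param panel_min lower bound for a panel hit (default 2).
#' @param min_panel_hits hits required (default 5 of 7).
#' @return List of class `sct_smc_rule`.
#' @export
smc_rule <- function(null_gene = "Nkx2-5", null_max = 1,
                     panel_genes = c("Tagln", "Cnn1", "Acta2", "Cald1",
                                     "Mylk", "Hexim1", "Smtnl2"),
                     panel_min = 2, min_panel_hits = 5) {
  if (min_panel_hits > length(panel_genes))
    stop("min_panel_hits exceeds the panel size")
  structure(list(null_gene = null_gene, null_max = null_max,
                 panel_genes = panel_genes, panel_min = panel_min,
                 min_panel_hits = min_panel_hits),
            class = "sct_smc_rule")
}

#' Classify smooth-muscle cells by marker rule
#'
#' Applies an [smc_rule()] to a genes-by-cells logTPM matrix
#' (log2(TPM + 1) convention; thresholds are on the supplied scale).
#' Panel genes missing from the matrix count as non-hits with a warning;
#' a missing null gene is an error.
#'
#' @param logtpm_matrix genes-by-cells matrix on the log-TPM scale.
#' @param rule an [smc_rule()].
#' @return Named logical vector per cell.
#' @export
smc_classify <- function(logtpm_matrix, rule = smc_rule()) {
  x <- as.matrix(logtpm_matrix)
  if (!rule$null_gene %in% rownames(x))
    stop("null gene '", rule$null_gene, "' absent from the matrix")
  present <- rule$panel_genes[rule$panel_genes %in% rownames(x)]
  missing <- setdiff(rule$panel_genes, present)
  if (length(missing))
    warning("panel gene(s) absent, counted as non-hits: ",
            paste(missing, collapse = ", "))
  null_ok <- x[rule$null_gene, ] < rule$null_max
  hits <- if (length(present))
    colSums(x[present, , drop = FALSE] > rule$panel_min) else 0L
  out <- null_ok & (hits >= rule$min_panel_hits)
  names(out) <- colnames(x)
  out
}
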