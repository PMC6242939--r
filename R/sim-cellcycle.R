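#' Simulate a cell-cycle scoring fixture
#'
#' Builds a normalized expression matrix in which a fraction of cells is
#' cycling: each cycling cell is assigned one of the five cell-cycle
#' stages (G1/S, S, G2, G2/M, M/G1) and overexpresses that stage's gene
#' set by `effect` log2 units (with a half-strength spillover onto the
#' next stage, mimicking the cyclic progression). Non-cycling cells stay
#' at baseline. Background genes carry no stage signal.
#'
#' @param n_cells number of cells (default 300).
#' @param n_set_genes genes per stage set (default 20, minimum 5).
#' @param cycling_fraction fraction of cycling cells (default 0.5; 0
#'   gives a null fixture).
#' @param effect log2 overexpression of the active stage set (default 2).
#' @param n_background background genes without stage signal (default 200).
#' @param seed RNG seed.
#' @return List with `expr` (genes x cells normalized log2 matrix),
#'   `gene_sets` (named list per stage), `cycling` (logical per cell),
#'   `stage` (stage of each cycling cell, NA otherwise).
#' @export
generate_cellcycle_fixture <- function(n_cells = 300, n_set_genes = 20,
                                       cycling_fraction = 0.5, effect = 2,
                                       n_background = 200, seed = 1) {
  check_count(n_cells, "n_cells", 10)
  check_count(n_set_genes, "n_set_genes", 5)
  if (cycling_fraction < 0 || cycling_fraction > 1)
    stop("configuration error: `cycling_fraction` must lie in [0,1]")
  stages <- c("G1/S", "S", "G2", "G2/M", "M/G1")
  with_seed(seed, {
    gene_sets <- lapply(seq_along(stages), function(s)
      sprintf("cc%d_gene_%03d", s, seq_len(n_set_genes)))
    names(gene_sets) <- stages
    set_genes <- unlist(gene_sets, use.names = FALSE)
    bg_genes <- sprintf("bg_gene_%03d", seq_len(n_background))
    genes <- c(set_genes, bg_genes)
    G <- length(genes)
    n_cyc <- round(cycling_fraction * n_cells)
    cycling <- c(rep(TRUE, n_cyc), rep(FALSE, n_cells - n_cyc))
    stage <- rep(NA_integer_, n_cells)
    if (n_cyc > 0) stage[seq_len(n_cyc)] <- sample.int(5, n_cyc, replace = TRUE)
    base <- matrix(rnorm(G * n_cells, mean = 2, sd = 0.4), G, n_cells,
                   dimnames = list(genes, sprintf("cell_%04d", seq_len(n_cells))))
    for (i in which(cycling)) {
      s <- stage[i]
      base[gene_sets[[s]], i] <- base[gene_sets[[s]], i] + effect
      nxt <- if (s == 5) 1L else s + 1L
      base[gene_sets[[nxt]], i] <- base[gene_sets[[nxt]], i] + effect / 2
    }
    base[base < 0] <- 0
    list(expr = base, gene_sets = gene_sets, cycling = cycling,
         stage = ifelse(is.na(stage), NA_character_, stages[stage]))
  })
}
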