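test_that("per-cell QC metrics match hand arithmetic", {
  cm <- tiny_counts(matrix(c(0, 0, 10, 5), ncol = 1), mito = 3,
                    housekeeping = 4)
  qc <- compute_cell_qc(cm)
  expect_equal(qc$dropout_pct, 50)
  expect_equal(qc$n_features_ge10, 1)
  expect_equal(qc$mito_pct, 10 / 15 * 100)
  expect_equal(qc$genes_pct, 50)
  expect_equal(qc$housekeeping_expr, 5)
})

test_that("degenerate cells and duplicate columns are handled", {
  m <- cbind(c(0, 0, 0, 0), c(1, 2, 3, 4), c(1, 2, 3, 4))
  cm <- tiny_counts(m, mito = 1, housekeeping = 2)
  qc <- compute_cell_qc(cm)
  expect_equal(qc$dropout_pct[1], 100)
  expect_true(is.na(qc$mito_pct[1]))  # zero-total cell: metric undefined
  expect_equal(qc[2, -1], qc[3, -1], ignore_attr = TRUE)
})

test_that("missing mitochondrial flags produce NA metrics with a warning", {
  cm <- tiny_counts(matrix(1:8, 4), mito = integer(0), housekeeping = 1)
  expect_warning(qc <- compute_cell_qc(cm), "mitochondrial")
  expect_true(all(is.na(qc$mito_pct)))
})

test_that("cells are kept unless they fail more than max_failures criteria", {
  set.seed(11)
  n <- 50
  report <- data.frame(
    cell_id = paste0("c", seq_len(n)),
    mito_pct = rnorm(n, 5, 0.5),
    n_features_ge10 = rnorm(n, 1000, 30),
    dropout_pct = rnorm(n, 40, 2),
    housekeeping_expr = rnorm(n, 100, 5),
    genes_pct = rnorm(n, 60, 2))
  # plant one single-criterion outlier and one multi-criterion outlier
  report$mito_pct[1] <- 30
  report$mito_pct[2] <- 30; report$dropout_pct[2] <- 80
  out <- flag_low_quality_cells(report)
  expect_true(out$keep[1])    # failing exactly one criterion is tolerated
  expect_false(out$keep[2])
  expect_identical(out$keep, out$n_failed <= 1)
})

test_that("QC verdicts equal a brute-force reimplementation of each rule", {
  set.seed(7)
  n <- 50
  report <- data.frame(
    cell_id = paste0("c", seq_len(n)),
    mito_pct = c(rnorm(n - 3, 5, 1), 25, 22, 4),
    n_features_ge10 = c(rnorm(n - 3, 800, 50), 100, 820, 1500),
    dropout_pct = c(rnorm(n - 3, 50, 3), 90, 49, 48),
    housekeeping_expr = c(rnorm(n - 3, 200, 20), 10, 190, 210),
    genes_pct = c(rnorm(n - 3, 50, 3), 20, 51, 49))
  out <- flag_low_quality_cells(report, qc_criteria())
  # independent oracle: apply each published rule directly
  madu <- function(x) stats::mad(x)
  fails <- with(report,
    (mito_pct > median(mito_pct) + 1.5 * madu(mito_pct)) +
    (abs(n_features_ge10 - median(n_features_ge10)) > 2 * madu(n_features_ge10)) +
    (dropout_pct > median(dropout_pct) + 2 * madu(dropout_pct)) +
    (housekeeping_expr < median(housekeeping_expr) - 2 * madu(housekeeping_expr)) +
    (abs(genes_pct - median(genes_pct)) > 1.5 * madu(genes_pct)))
  expect_identical(out$n_failed, as.integer(fails))
  expect_identical(out$keep, fails <= 1)
})

test_that("zero-spread metrics flag nothing and verdicts are permutation invariant", {
  report <- data.frame(cell_id = paste0("c", 1:6), mito_pct = 5,
                       n_features_ge10 = 100, dropout_pct = 40,
                       housekeeping_expr = 10, genes_pct = 60)
  out <- flag_low_quality_cells(report)
  expect_true(all(out$keep))
  set.seed(3)
  rep2 <- data.frame(cell_id = paste0("c", 1:20),
                     mito_pct = rnorm(20, 5), n_features_ge10 = rnorm(20, 100),
                     dropout_pct = rnorm(20, 40), housekeeping_expr = rnorm(20, 10),
                     genes_pct = rnorm(20, 60))
  perm <- sample(20)
  o1 <- flag_low_quality_cells(rep2)
  o2 <- flag_low_quality_cells(rep2[perm, ])
  expect_identical(o2$keep, o1$keep[perm])
  expect_error(flag_low_quality_cells(rep2[1:3, ]), "at least 5")
})

test_that("gene filtering applies both lineage criteria with an OR across lineages", {
  # gene 1: passes both in lineage A; gene 2: 9 cells > 10 counts (fails
  # support) everywhere; gene 3: passes only in lineage B
  m <- matrix(0, 3, 24)
  lineage <- rep(c("A", "B"), each = 12)
  m[1, 1:12] <- c(rep(230, 10), 40, 30)          # A: total 2770, 12 cells > 10
  m[2, 1:9] <- 11; m[2, 13:21] <- 300            # A: 9 cells; B: 9 cells
  m[3, 13:24] <- 250                             # B only
  cm <- count_matrix(m, feature_ids = c("g1", "g2", "g3"),
                     cell_ids = paste0("c", 1:24))
  kept <- filter_genes(cm, lineage = lineage)
  expect_setequal(kept, c("g1", "g3"))
  # single lineage degenerates gracefully and output is idempotent subset
  kept_a <- filter_genes(cm[, 1:12], lineage = rep("A", 12))
  expect_identical(kept_a, "g1")
  expect_true(all(kept %in% c("g1", "g2", "g3")))
  expect_error(filter_genes(cm, lineage = "A"), "lineage")
})

test_that("excluded genotypes do not contribute to gene filtering", {
  m <- matrix(0, 1, 24)
  m[1, ] <- 250   # passes everywhere...
  cm <- count_matrix(m, feature_ids = "g1", cell_ids = paste0("c", 1:24),
                     cell_meta = data.frame(genotype = c(rep("ko", 15),
                                                         rep("wt", 9))))
  # ...but only 9 wild-type cells support it once KO cells are excluded
  kept <- filter_genes(cm, lineage = rep("A", 24), exclude_genotypes = "ko")
  expect_length(kept, 0)
})
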