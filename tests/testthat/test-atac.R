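test_that("ATAC cell QC gates three metrics with the failure budget", {
  n <- 50
  set.seed(1)
  metrics <- data.frame(mito_content = rnorm(n, 5, 0.5),
                        n_accessible_peaks = rnorm(n, 2000, 100),
                        log_total_counts = rnorm(n, 8, 0.3))
  metrics$mito_content[1] <- 20                        # one failure: kept
  metrics$mito_content[2] <- 20
  metrics$log_total_counts[2] <- 3                     # two failures: dropped
  out <- atac_cell_qc(metrics)
  expect_true(out$keep[1])
  expect_false(out$keep[2])
  # brute-force rule application
  madu <- function(x) stats::mad(x)
  fails <- with(metrics,
    (mito_content > median(mito_content) + 2 * madu(mito_content)) +
    (abs(n_accessible_peaks - median(n_accessible_peaks)) >
       2 * madu(n_accessible_peaks)) +
    (abs(log_total_counts - median(log_total_counts)) >
       2 * madu(log_total_counts)))
  expect_identical(out$n_failed, as.integer(fails))
  expect_identical(out$keep, fails <= 1)
  # identical cells: zero spread, everything kept
  same <- data.frame(mito_content = rep(3, 10),
                     n_accessible_peaks = rep(500, 10),
                     log_total_counts = rep(7, 10))
  expect_true(all(atac_cell_qc(same)$keep))
  expect_error(atac_cell_qc(same[, 1:2]), "log_total_counts")
})

test_that("peak filtering applies strict support and coverage bounds", {
  n_cells <- 100
  m <- matrix(0, 4, n_cells)
  m[1, 1:35] <- 1                 # support exactly 35: removed (strict >)
  m[2, 1:36] <- 1                 # support 36, mean << 15: kept
  m[3, ] <- 14.9                  # wait: mean 14.9 < 15, support 100: kept
  m[4, ] <- 15                    # mean 15: removed
  m <- round(m)
  m[3, ] <- c(rep(14, 90), rep(23, 10))  # integer counts, mean 14.9
  rownames(m) <- paste0("p", 1:4)
  kept <- filter_peaks(m)
  expect_setequal(kept, c("p2", "p3"))
  # all-zero peak removed; brute-force row scan agrees on a random fixture
  set.seed(2)
  r <- matrix(rpois(500 * 60, 0.5), 500, 60,
              dimnames = list(paste0("p", 1:500), NULL))
  brute <- rownames(r)[rowSums(r > 0) > 35 & rowMeans(r) < 15]
  expect_identical(filter_peaks(r), brute)
})

test_that("binarization is an idempotent indicator transform", {
  m <- matrix(c(0, 1, 17, 0, 3, 0), 2)
  b <- binarize(m)
  expect_equal(as.matrix(b), matrix(c(0, 1, 1, 0, 1, 0), 2),
               ignore_attr = TRUE)
  expect_equal(Matrix::nnzero(b), sum(m > 0))
  expect_equal(as.matrix(binarize(b)), as.matrix(b))
  expect_error(binarize(matrix(c(-1, 2), 1)), "negative")
})

test_that("TF-IDF weights follow the smoothed closed form", {
  # peak 1 open in all 9 cells; cell 1 has a single open peak
  m <- matrix(0, 3, 9)
  m[1, ] <- 1
  m[2, 2:5] <- 1
  b <- binarize(m)
  w <- tfidf(b)
  idf <- attr(w, "idf")
  expect_equal(idf[1], log(1 + 9 / 10))
  expect_equal(idf[2], log(1 + 9 / 5))
  expect_equal(w[1, 1], 1 * log(1.9))        # tf = 1 for a one-peak cell
  expect_equal(w[1, 2], 0.5 * log(1.9))
  # count magnitudes are irrelevant after binarization
  expect_equal(as.matrix(tfidf(binarize(m * 7))), as.matrix(w),
               ignore_attr = TRUE)
  m0 <- m; m0[, 9] <- 0
  expect_error(tfidf(binarize(m0)), "9")
})

test_that("SVD embedding reflects rank and drops the first component", {
  set.seed(3)
  u <- matrix(rnorm(40), 40, 1); v <- matrix(rnorm(30), 30, 1)
  low_rank <- u %*% t(v) + 2 * outer(rnorm(40), rnorm(30))
  emb <- svd_embed(low_rank, k = 6, drop_first = TRUE)
  d <- attr(emb, "d")
  expect_lt(d[3] / d[1], 1e-6)
  expect_equal(ncol(emb), 5)
  expect_equal(ncol(attr(emb, "all_components")), 6)
  expect_error(svd_embed(low_rank, k = 30), "smaller")
})

test_that("cluster-specific peaks match the hypergeometric closed form", {
  n1 <- 30; n2 <- 300
  labels <- rep(c(0, 1), c(n1, n2))
  m <- matrix(0, 3, n1 + n2, dimnames = list(paste0("p", 1:3), NULL))
  m[1, 1:n1] <- 1                          # perfectly specific to cluster 0
  m[2, ] <- rep(c(1, 0), length.out = n1 + n2)  # indifferent
  m[3, sample(seq_len(n1 + n2), 100)] <- 1
  set.seed(4)
  res <- cluster_specific_peaks(m, labels, alpha = 1e-5)
  expect_true("p1" %in% res$peak_id)
  expect_equal(res$cluster[res$peak_id == "p1"], 0)
  expect_false("p2" %in% res$peak_id)
  p_expected <- phyper(n1 - 1, n1, n2, n1, lower.tail = FALSE)
  expect_equal(res$p[res$peak_id == "p1"], p_expected)
  expect_error(cluster_specific_peaks(m, rep(0, n1 + n2)), "clusters")
})

test_that("motif deviations are reproducible and flag variable motifs", {
  sim <- generate_atac_counts(atac_sim_config(n_peaks = 1000, n_cells = 100,
                                              seed = 5))
  kept <- filter_peaks(sim$counts, min_cells = 5)
  counts <- sim$counts[kept, ]$counts
  hits <- as.matrix(sim$motif_hits[1:8, kept])
  hits <- rbind(hits, dup = hits[8, ])
  d1 <- motif_deviation_zscores(counts, hits, B = 20, seed = 9)
  d2 <- motif_deviation_zscores(counts, hits, B = 20, seed = 9)
  expect_identical(d1$z, d2$z)
  # duplicate motif rows give identical Z rows under the same seed
  expect_equal(unname(d1$z["dup", ]), unname(d1$z[8, ]))
  vm <- variable_motifs(d1, z_threshold = 1.5)
  expect_true(all(vm %in% rownames(d1$z)))
  skinny <- hits; skinny[1, ] <- 0; skinny[1, 1:2] <- 1
  expect_warning(motif_deviation_zscores(counts, skinny, B = 5, seed = 1),
                 "skipped")
})

test_that("peak resizing fixes widths around midpoints", {
  peaks <- data.frame(chrom = "chr1", start = c(1000, 120), end = c(2000, 180))
  out <- resize_peaks(peaks, width = 500)
  expect_equal(out$end - out$start, c(500, 500))
  expect_equal(out$start[1], 1250)
  expect_true(all(out$start >= 0))
})

test_that("ATAC pseudotime recovers a monotone accessibility gradient", {
  set.seed(6)
  n <- 60
  grad <- seq_len(n)
  m <- matrix(0, 80, n)
  for (p in 1:80) m[p, ] <- rbinom(n, 1, plogis((grad - p) / 6))
  rownames(m) <- paste0("p", 1:80); colnames(m) <- paste0("c", 1:n)
  keep <- rowSums(m) > 0 & rowSums(m) < n
  w <- tfidf(m[keep, colSums(m[keep, ]) > 0])
  dpt <- atac_pseudotime(w, root_cell = 1)
  expect_gt(abs(cor(dpt, grad[colSums(m[keep, ]) > 0],
                    method = "spearman")), 0.8)
  expect_equal(unname(dpt[1]), 0)
  expect_error(atac_pseudotime(w[, 1:5]), "12 cells")
})

test_that("RNA:ATAC trend pairing detects lags and confidence", {
  set.seed(7)
  n <- 120
  base <- sin(seq(0, 3, length.out = n)) + rnorm(n, sd = 0.02)
  shift <- round(0.2 * n)
  rna <- rbind(tf1 = base, tf2 = base, tf3 = base)
  atac <- rbind(m1 = base,                              # identical: matched
                m2 = c(rep(base[1], shift), base[1:(n - shift)]),  # later
                m3 = -base)                             # anti-correlated
  pairs <- data.frame(gene_id = c("tf1", "tf2", "tf3", "tf4"),
                      motif_id = c("m1", "m2", "m3", "m4"))
  expect_warning(res <- pair_rna_atac(rna, atac, pairs), "missing")
  expect_equal(nrow(res), 3)
  expect_equal(res$pattern[res$motif_id == "m1"], "matched")
  expect_equal(res$best_lag[res$motif_id == "m1"], 0)
  expect_equal(res$pattern[res$motif_id == "m2"], "rna_precedes")
  m3row <- res[res$motif_id == "m3", ]
  expect_lt(m3row$best_cor, 0.3)
  expect_true(m3row$low_confidence)
  expect_false(any(res$low_confidence[res$motif_id %in% c("m1", "m2")]))
  # trends of different lengths are resampled onto a common grid
  res2 <- pair_rna_atac(rna, atac[, seq(1, n, by = 2)],
                        pairs[1, , drop = FALSE])
  expect_equal(res2$pattern, "matched")
})
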