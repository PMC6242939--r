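test_that("t-SNE embeddings are reproducible and preconditions enforced", {
  set.seed(1)
  x <- matrix(rnorm(100 * 5), 100, 5)
  e1 <- embed_tsne(x, perplexity = 10, iterations = 300, seed = 4)
  e2 <- embed_tsne(x, perplexity = 10, iterations = 300, seed = 4)
  expect_identical(e1, e2)
  expect_error(embed_tsne(x[1:20, ], perplexity = 10), "3 \\* perplexity")
})

test_that("well-separated clusters survive the t-SNE projection", {
  set.seed(2)
  centers <- rbind(c(0, 0, 0), c(30, 0, 0), c(0, 30, 0))
  x <- do.call(rbind, lapply(1:3, function(k)
    sweep(matrix(rnorm(40 * 3), 40, 3), 2, centers[k, ], `+`)))
  truth <- rep(1:3, each = 40)
  emb <- embed_tsne(x, perplexity = 12, iterations = 500, seed = 1)
  cl <- cluster_hdbscan(emb, 7, 9)
  keep <- cl$labels != -1
  expect_gte(scTransit:::adjusted_rand_index(cl$labels[keep], truth[keep]), 0.9)
})

test_that("HDBSCAN finds two tight blobs with no outliers", {
  coords <- two_blobs()
  cl <- cluster_hdbscan(coords, min_cluster_size = 7, min_samples = 9)
  expect_setequal(unique(cl$labels), c(0, 1))
  expect_equal(sum(cl$labels == -1), 0)
  expect_length(unique(cl$labels[1:50]), 1)
  expect_length(unique(cl$labels[51:100]), 1)
})

test_that("HDBSCAN labels uniform noise as outliers and is permutation stable", {
  set.seed(9)
  noise <- cbind(runif(20), runif(20))
  cl <- cluster_hdbscan(noise, 7, 9)
  expect_gt(mean(cl$labels == -1), 0.5)
  coords <- two_blobs(seed = 3)
  perm <- sample(nrow(coords))
  l1 <- cluster_hdbscan(coords, 7, 9)$labels
  l2 <- cluster_hdbscan(coords[perm, ], 7, 9)$labels
  expect_equal(scTransit:::adjusted_rand_index(l1[perm], l2), 1)
  expect_warning(tiny <- cluster_hdbscan(coords[1:3, ], 7, 9), "outliers")
  expect_true(all(tiny$labels == -1))
})

test_that("a gene expressed only in one cluster gets AUROC 1 and a marker flag", {
  set.seed(5)
  n1 <- 20; n2 <- 40
  m <- rbind(sig = c(rnorm(n1, 8, 0.2), rep(0, n2)),
             flat = rnorm(n1 + n2, 3, 0.3))
  labels <- rep(c(0, 1), c(n1, n2))
  tab <- find_markers_auroc(m, labels)
  sig0 <- tab[tab$gene_id == "sig" & tab$cluster == 0, ]
  expect_equal(sig0$auroc, 1)
  expect_true(sig0$marker)
  flat0 <- tab[tab$gene_id == "flat" & tab$cluster == 0, ]
  expect_lt(abs(flat0$auroc - 0.5), 0.2)
  expect_false(flat0$marker)
})

test_that("marker statistics match a brute-force wilcox/AUROC loop", {
  set.seed(6)
  n_genes <- 200
  labels <- rep(c(0, 1, 2), c(25, 30, 35))
  m <- matrix(rnorm(n_genes * 90, 4), n_genes, 90,
              dimnames = list(sprintf("g%03d", 1:n_genes), NULL))
  m[1:20, labels == 0] <- m[1:20, labels == 0] + 3
  tab <- find_markers_auroc(m, labels)
  for (cl in 0:2) {
    in_cl <- labels == cl
    sub <- tab[tab$cluster == cl, ]
    sub <- sub[match(rownames(m), sub$gene_id), ]
    oracle <- t(vapply(seq_len(n_genes), function(g) {
      w <- wilcox.test(m[g, in_cl], m[g, !in_cl], exact = FALSE,
                       correct = FALSE)
      auroc <- unname(w$statistic) / (sum(in_cl) * sum(!in_cl))
      c(auroc, w$p.value)
    }, numeric(2)))
    expect_equal(sub$auroc, oracle[, 1], tolerance = 1e-12)
    expect_equal(sub$p, oracle[, 2], tolerance = 1e-9)
    expect_equal(sub$fdr, p.adjust(oracle[, 2], "BH"), tolerance = 1e-9)
    expect_identical(sub$marker, sub$auroc > 0.8 & sub$fdr < 0.01)
    expect_identical(sub$de,
                     (sub$lfc_lo > 2 | sub$lfc_hi < -2) & sub$fdr < 0.01)
  }
})

test_that("singleton clusters are skipped and outliers excluded", {
  set.seed(7)
  m <- matrix(rnorm(50 * 30), 50, 30,
              dimnames = list(paste0("g", 1:50), NULL))
  labels <- c(rep(0, 14), rep(1, 15), 2)
  expect_warning(tab <- find_markers_auroc(m, labels), "skipped")
  expect_setequal(unique(tab$cluster), c(0, 1))
  expect_error(find_markers_auroc(m, rep(0, 30)), "2 non-outlier")
})
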