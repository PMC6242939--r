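test_that("diffusion components recover a 1-D gradient and its ordering", {
  set.seed(1)
  pos <- seq(0, 10, length.out = 60)
  x <- rbind(outer(rnorm(15), pos) + rnorm(15 * 60, sd = 0.01))
  colnames(x) <- paste0("c", 1:60)
  dm <- diffusion_map(x, k = 5)
  expect_gt(abs(cor(dm$evec[, 1], pos, method = "spearman")), 0.99)
  expect_true(all(diff(dm$eval) <= 1e-9))
  expect_true(all(dm$eval <= 1 + 1e-9))
  dpt <- diffusion_pseudotime(dm, "c1")
  expect_equal(unname(dpt["c1"]), 0)
  expect_equal(range(dpt), c(0, 1))
  expect_gt(cor(dpt, pos, method = "spearman"), 0.99)
  # reversing the root reverses the ordering
  dpt_rev <- diffusion_pseudotime(dm, "c60")
  expect_lt(cor(dpt, dpt_rev, method = "spearman"), -0.99)
  expect_error(diffusion_pseudotime(dm, "nope"), "not found")
  expect_error(diffusion_map(x[, 1:5], k = 5), "k \\+ 2")
})

test_that("projection inherits the nearest reference cell's pseudotime exactly", {
  set.seed(2)
  ref <- matrix(rnorm(20 * 30), 20, 30,
                dimnames = list(paste0("g", 1:20), paste0("r", 1:30)))
  dpt <- runif(30)
  q <- ref[, c(4, 17), drop = FALSE]
  colnames(q) <- c("q1", "q2")
  proj <- project_cells(ref, dpt, q, k_neighbors = 5)
  expect_equal(proj$dpt, dpt[c(4, 17)])
  # permuting reference cells leaves projections unchanged
  perm <- sample(30)
  proj2 <- project_cells(ref[, perm], dpt[perm], q, k_neighbors = 5)
  expect_equal(proj2$dpt, proj$dpt)
  expect_error(project_cells(ref, dpt, matrix(1, 2, 2,
    dimnames = list(c("x1", "x2"), NULL))), "shared")
})

test_that("query cells from one cluster land inside its pseudotime range", {
  set.seed(3)
  centers <- seq(0, 8, by = 2)
  ref <- do.call(cbind, lapply(centers, function(cc)
    matrix(rnorm(15 * 20, mean = cc, sd = 0.3), 15, 20)))
  rownames(ref) <- paste0("g", 1:15)
  colnames(ref) <- paste0("r", seq_len(ncol(ref)))
  dpt <- rep(seq(0, 1, length.out = 5), each = 20)
  query <- matrix(rnorm(15 * 30, mean = centers[3], sd = 0.3), 15, 30,
                  dimnames = list(paste0("g", 1:15), paste0("q", 1:30)))
  proj <- project_cells(ref, dpt, query, k_neighbors = 10)
  iqr <- quantile(dpt[41:60], c(0.25, 0.75))
  inside <- mean(proj$dpt >= 0.5 - 0.25 & proj$dpt <= 0.75)
  expect_gte(mean(proj$dpt >= iqr[1] - 0.13 & proj$dpt <= iqr[2] + 0.13), 0.9)
})

test_that("pseudotime-correlated genes follow the global-or-local rule", {
  set.seed(4)
  n <- 60
  dpt <- seq(0, 1, length.out = n)
  labels <- rep(c(1, 2, 3), each = 20)
  x <- rbind(
    exact = dpt,
    local = c(seq(0, 1, length.out = 20) * 0.2,
              seq(0, 1, length.out = 20) + rnorm(20, sd = 0.1),
              rnorm(20, 0.5, 0.5)),
    flat = rnorm(n),
    const = rep(1, n))
  tab <- correlated_genes(x, dpt, labels)
  expect_equal(tab$rho_global[1], 1)
  expect_true(tab$correlated[1])
  loc <- tab[tab$gene_id == "local", ]
  expect_gt(abs(loc$rho_local_max), 0.5)
  expect_true(loc$correlated)
  expect_false(tab$correlated[tab$gene_id == "flat"])
  expect_true(is.na(tab$rho_global[tab$gene_id == "const"]))
  expect_false(tab$correlated[tab$gene_id == "const"])
})

test_that("smoothing matches a brute-force truncated-window loop", {
  set.seed(5)
  v <- rnorm(20)
  sm <- smooth_along_pseudotime(v, window = 11)
  oracle <- vapply(1:20, function(i) mean(v[max(1, i - 5):min(20, i + 5)]),
                   numeric(1))
  expect_equal(sm, oracle)
  expect_equal(smooth_along_pseudotime(v, window = 1), v)
  expect_equal(smooth_along_pseudotime(rep(3, 15), window = 7), rep(3, 15))
  # mean preserved within boundary tolerance
  expect_lt(abs(mean(sm) - mean(v)), max(abs(v)) * 11 / 20)
  # an explicit ordering smooths along that ordering
  ord <- sample(20)
  sm2 <- smooth_along_pseudotime(v, order = ord, window = 11)
  expect_equal(sm2[ord], scTransit:::moving_mean(v[ord], 11))
  expect_error(smooth_along_pseudotime(v, window = 0), "window")
  expect_error(smooth_along_pseudotime(v, window = 4), "odd")
  expect_error(smooth_along_pseudotime(v, window = 31), "exceeds")
})

test_that("trend categories follow the early/late-third rule", {
  trends <- rbind(down = seq(5, 1, length.out = 30),
                  up = seq(1, 5, length.out = 30),
                  flat = rep(2, 30))
  cats <- categorize_dynamics(trends)
  expect_identical(cats$category,
                   c("priming", "de_novo", "unclassified"))
})

test_that("duplicating every cell preserves diffusion structure", {
  set.seed(6)
  pos <- seq(0, 5, length.out = 40)
  x <- outer(rnorm(10), pos) + matrix(rnorm(400, sd = 0.05), 10, 40)
  colnames(x) <- paste0("c", 1:40)
  x2 <- cbind(x, x)
  colnames(x2) <- paste0("c", 1:80)
  dm2 <- diffusion_map(x2, k = 3)
  # duplicated copies of the same cell get equal component values
  expect_equal(unname(dm2$evec[1:40, 1]), unname(dm2$evec[41:80, 1]),
               tolerance = 1e-6)
})
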