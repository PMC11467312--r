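test_that("Mann-Whitney U uses the min-U convention with midranks", {
  expect_equal(mann_whitney_u(1:3, 4:6)$U, 0)
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$U, 4.5)
  # complete separation, n = 6: exact two-sided p = 2/20
  expect_equal(mann_whitney_u(1:3, 4:6)$p_value, 0.1)
})

test_that("exact Mann-Whitney p agrees with wilcox.test on tie-free data", {
  set.seed(30)
  for (i in 1:20) {
    nx <- sample(2:5, 1); ny <- sample(2:5, 1)
    x <- rnorm(nx); y <- rnorm(ny)
    ours <- mann_whitney_u(x, y)
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(ours$U, min(ref$statistic, nx * ny - ref$statistic),
                 ignore_attr = TRUE)
  }
})

test_that("large-sample Mann-Whitney approximation matches wilcox.test", {
  set.seed(31)
  x <- rnorm(13); y <- rnorm(14) + 0.8
  ours <- mann_whitney_u(x, y)
  ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("pooled t test reports the classical df", {
  set.seed(32)
  x <- rnorm(13); y <- rnorm(14)
  tt <- student_t(x, y)
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(tt$t, unname(ref$statistic))
  expect_equal(tt$df, 25)
  expect_equal(tt$p_value, ref$p.value)
  expect_equal(student_t(c(1, 2, 3), c(1, 2, 3))$t, 0)
  expect_error(student_t(c(1, 1), c(1, 1)), "zero pooled variance")
})

test_that("Pearson chi-square has no continuity correction", {
  tab <- matrix(c(12, 1, 6, 8), 2, byrow = TRUE)
  ours <- pearson_chi2(tab)
  ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
  expect_equal(ours$chi2, unname(ref$statistic))
  expect_equal(ours$df, 1L)
  # closed form N (ad - bc)^2 / row/col products on every 2x2 table
  set.seed(33)
  for (i in 1:20) {
    t2 <- matrix(sample(1:30, 4, replace = TRUE), 2)
    a <- t2[1, 1]; b <- t2[1, 2]; c2 <- t2[2, 1]; d <- t2[2, 2]
    closed <- sum(t2) * (a * d - b * c2)^2 /
      ((a + b) * (c2 + d) * (a + c2) * (b + d))
    expect_equal(pearson_chi2(t2)$chi2, closed, tolerance = 1e-12)
  }
  expect_equal(pearson_chi2(matrix(c(10, 0, 0, 10), 2))$chi2, 20)
  expect_equal(pearson_chi2(matrix(c(6, 3, 12, 6), 2))$chi2, 0)
  expect_error(pearson_chi2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "marginal")
})

test_that("scaled-MAD screening removes the documented outlier", {
  d <- c(1.0, 1.1, 1.2, 9.9)
  x <- c(10, 20, 30, 40)
  res <- spearman_mad(x, d)
  expect_equal(res$outliers, c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(res$n_used, 3)
  expect_equal(res$rho, 1)
  expect_error(spearman_mad(1:3, 1:3), "at least 4")
})

test_that("spearman_mad finds perfect monotone association", {
  x <- 1:10
  y <- x^2
  expect_equal(spearman_mad(x, y)$rho, 1)
  set.seed(34)
  # independent data: |rho| < 0.3 in at least 19 of 20 draws at n = 100
  small <- vapply(1:20, function(i) {
    abs(spearman_mad(rnorm(100), rnorm(100))$rho)
  }, 0)
  expect_gte(sum(small < 0.3), 19)
})

test_that("edge adjacency joins edges sharing a channel", {
  adj <- edge_adjacency(c("a", "b", "c", "d"))
  expect_length(adj$features, 6)
  i12 <- which(adj$features == "a--b")
  i23 <- which(adj$features == "b--c")
  i34 <- which(adj$features == "c--d")
  expect_true(i23 %in% adj$neighbours[[i12]])
  expect_false(i34 %in% adj$neighbours[[i12]])
  expect_error(edge_adjacency(c("a", "a", "b")), "duplicate")
  expect_length(edge_adjacency(letters[1:7])$features, 21)
})

test_that("sensor adjacency comes from a valid triangulation", {
  m <- standard_montage_32()
  adj <- sensor_adjacency(m)
  deg <- lengths(adj$neighbours)
  expect_true(all(deg >= 3 & deg <= 8))
  # symmetric neighbour relation, no self-neighbours
  for (i in seq_along(adj$neighbours)) {
    expect_false(i %in% adj$neighbours[[i]])
    for (j in adj$neighbours[[i]]) {
      expect_true(i %in% adj$neighbours[[j]])
    }
  }
  sq <- data.frame(label = c("a", "b", "c", "d"),
                   x = c(0.5, -0.5, 0.5, -0.5), y = c(0.5, 0.5, -0.5, -0.5),
                   z = sqrt(0.5))
  adj_sq <- sensor_adjacency(sq)
  expect_true(all(lengths(adj_sq$neighbours) >= 2))
})

test_that("identical groups yield no clusters", {
  set.seed(35)
  adj <- edge_adjacency(paste0("ch", 1:6))
  A <- matrix(rnorm(4 * 15), 4)
  res <- cluster_permutation_test(A, A, adj, n_perm = 100, seed = 1)
  expect_length(res$clusters, 0)
  expect_length(res$p_value, 0)
})

test_that("a strongly shifted edge is detected in a significant cluster", {
  set.seed(36)
  labs <- paste0("ch", 1:8)
  adj <- edge_adjacency(labs)
  A <- matrix(rnorm(13 * 28), 13)
  B <- matrix(rnorm(14 * 28), 14)
  shifted <- which(adj$features == "ch2--ch5")
  B[, shifted] <- B[, shifted] + 5
  res <- cluster_permutation_test(A, B, adj, n_perm = 500, seed = 2)
  sig <- which(res$p_value < 0.05)
  expect_gte(length(sig), 1)
  expect_true("ch2--ch5" %in% unlist(res$cluster_features[sig]))
})

test_that("cluster membership is independent of feature order", {
  set.seed(37)
  labs <- paste0("s", 1:10)
  pos <- montage_subset(standard_montage_32(),
                        standard_montage_32()$label[1:10])
  pos$label <- labs
  adj <- sensor_adjacency(pos)
  A <- matrix(rnorm(6 * 10), 6)
  B <- matrix(rnorm(6 * 10), 6)
  B[, 3] <- B[, 3] + 4
  res1 <- cluster_permutation_test(A, B, adj, n_perm = 200, seed = 3)
  # permute features consistently everywhere
  perm <- sample(10)
  adj_p <- adj
  adj_p$features <- adj$features[perm]
  inv <- order(perm)
  adj_p$neighbours <- lapply(adj$neighbours[perm], function(v) inv[v])
  res2 <- cluster_permutation_test(A[, perm], B[, perm], adj_p,
                                   n_perm = 200, seed = 3)
  feats1 <- lapply(res1$cluster_features, sort)
  feats2 <- lapply(res2$cluster_features, sort)
  expect_setequal(vapply(feats1, paste, "", collapse = "|"),
                  vapply(feats2, paste, "", collapse = "|"))
})

test_that("small designs are enumerated exactly", {
  set.seed(38)
  adj <- edge_adjacency(paste0("c", 1:5))
  A <- matrix(rnorm(3 * 10), 3)
  B <- matrix(rnorm(3 * 10), 3) + 3
  res <- cluster_permutation_test(A, B, adj, n_perm = 1024, seed = 1)
  expect_true(res$enumerated)
  expect_equal(res$n_perm, choose(6, 3))
  expect_gte(min(res$p_value), 1 / (choose(6, 3) + 1))
})

test_that("permutation p-values are calibrated under the null", {
  set.seed(39)
  adj <- edge_adjacency(paste0("c", 1:8))
  hits <- 0
  n_rep <- 120
  for (k in seq_len(n_rep)) {
    A <- matrix(rnorm(8 * 28), 8)
    B <- matrix(rnorm(8 * 28), 8)
    r <- cluster_permutation_test(A, B, adj, n_perm = 150, seed = k)
    if (length(r$p_value) && min(r$p_value) < 0.05) hits <- hits + 1
  }
  # FWER at alpha 0.05: allow generous Monte-Carlo slack at 120 reps
  expect_lte(hits / n_rep, 0.05 + 2.5 * sqrt(0.05 * 0.95 / n_rep))
})
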