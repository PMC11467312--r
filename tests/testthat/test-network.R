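test_that("global efficiency matches closed-form small cases", {
  K4 <- matrix(1, 4, 4); diag(K4) <- 0
  expect_equal(global_efficiency(K4), 1)
  expect_equal(global_efficiency(matrix(0, 3, 3)), 0)
  P3 <- matrix(0, 3, 3)
  P3[1, 2] <- P3[2, 1] <- P3[2, 3] <- P3[3, 2] <- 1
  expect_equal(global_efficiency(P3), 5 / 6)
})

test_that("global efficiency equals the brute-force oracle on random graphs", {
  set.seed(20)
  for (i in 1:60) {
    W <- rand_graph(sample(3:6, 1))
    expect_equal(global_efficiency(W), bf_global_eff(W), tolerance = 1e-12)
  }
})

test_that("nodal efficiency is the induced-subgraph efficiency", {
  # node 1 linked to 2,3,4; among neighbours only edge (2,3) = 1
  W <- matrix(0, 4, 4)
  W[1, 2:4] <- W[2:4, 1] <- 1
  W[2, 3] <- W[3, 2] <- 1
  expect_equal(nodal_efficiency(W, 1), 1 / 3)
  # complete neighbourhood scores 1, single neighbour scores 0
  K4 <- matrix(1, 4, 4); diag(K4) <- 0
  expect_equal(unname(nodal_efficiency(K4)[1]), 1)
  star <- matrix(0, 4, 4); star[1, 2:4] <- star[2:4, 1] <- 1
  expect_equal(nodal_efficiency(star, 2), 0)
  expect_error(nodal_efficiency(W, "nope"), "unknown node")
})

test_that("Onnela clustering matches hand computations", {
  tri <- matrix(0, 3, 3)
  tri[upper.tri(tri)] <- 1; tri <- tri + t(tri)
  expect_equal(unname(clustering_coefficient(tri)), rep(1, 3))
  star <- matrix(0, 4, 4); star[1, 2:4] <- star[2:4, 1] <- 1
  expect_equal(clustering_coefficient(star, 1), 0)
  wt <- tri; wt[2, 3] <- wt[3, 2] <- 0.125
  expect_equal(unname(clustering_coefficient(wt)), rep(0.5, 3))
})

test_that("Louvain finds the exhaustive-search optimum on small graphs", {
  W <- two_triangles()
  lp <- louvain_partition(W, seed = 5)
  expect_equal(lp$Q, 0.5, tolerance = 1e-12)
  expect_equal(lp$Q, bf_best_q(W), tolerance = 1e-9)
  expect_equal(lp$membership[1:3], rep(lp$membership[1], 3))
  expect_equal(lp$membership[4:6], rep(lp$membership[4], 3))

  # two cliques of 4 joined by one weak edge
  W8 <- matrix(0, 8, 8)
  W8[1:4, 1:4] <- 1; W8[5:8, 5:8] <- 1; diag(W8) <- 0
  W8[4, 5] <- W8[5, 4] <- 0.1
  lp8 <- louvain_partition(W8, seed = 6)
  expect_gte(lp8$Q, bf_best_q(W8) - 1e-9)
})

test_that("complete graphs collapse to one community with Q = 0", {
  K5 <- matrix(1, 5, 5); diag(K5) <- 0
  lp <- louvain_partition(K5, seed = 2)
  expect_equal(max(lp$membership), 1)
  expect_equal(lp$Q, 0, tolerance = 1e-12)
})

test_that("Louvain is deterministic given the seed", {
  set.seed(77)
  W <- rand_graph(12, density = 0.4)
  a <- louvain_partition(W, seed = 9)
  b <- louvain_partition(W, seed = 9)
  expect_identical(a, b)
  expect_error(louvain_partition(matrix(0, 3, 3)), "zero total weight")
})

test_that("nodal modularity decomposes Q exactly", {
  W <- two_triangles()
  lp <- louvain_partition(W, seed = 5)
  nm <- nodal_modularity(W, lp$membership)
  expect_equal(unname(nm), rep(0.5 / 6, 6), tolerance = 1e-12)
  set.seed(21)
  for (i in 1:50) {
    W <- rand_graph(sample(4:9, 1))
    if (sum(W) == 0) next
    mem <- sample(1:3, nrow(W), replace = TRUE)
    expect_equal(sum(nodal_modularity(W, mem)), bf_modularity(W, mem),
                 tolerance = 1e-9)
    expect_lt(abs(sum(nodal_modularity(W, mem)) - modularity_q(W, mem)), 1e-9)
  }
  # isolated zero-degree singleton contributes 0
  W0 <- rbind(cbind(two_triangles(), 0), 0)
  expect_equal(unname(nodal_modularity(W0, c(1, 1, 1, 2, 2, 2, 3))[7]), 0)
})

test_that("nodal metrics are equivariant under node relabelling", {
  set.seed(22)
  W <- rand_graph(7)
  perm <- sample(7)
  Wp <- W[perm, perm]
  expect_equal(unname(nodal_efficiency(Wp)), unname(nodal_efficiency(W)[perm]),
               tolerance = 1e-12)
  expect_equal(unname(clustering_coefficient(Wp)),
               unname(clustering_coefficient(W)[perm]), tolerance = 1e-12)
})

test_that("adding an edge never decreases global efficiency", {
  set.seed(23)
  for (i in 1:20) {
    W <- rand_graph(6, density = 0.5)
    zero <- which(W == 0 & upper.tri(W), arr.ind = TRUE)
    if (!nrow(zero)) next
    pick <- zero[sample(nrow(zero), 1), ]
    W2 <- W
    W2[pick[1], pick[2]] <- W2[pick[2], pick[1]] <- runif(1, 0.1, 1)
    expect_gte(global_efficiency(W2), global_efficiency(W) - 1e-12)
  }
})

test_that("metric_set bundles consistent nodal and global values", {
  set.seed(24)
  W <- rand_graph(8, density = 0.8)
  rownames(W) <- colnames(W) <- paste0("ch", 1:8)
  ms <- metric_set(W, seed = 4)
  expect_equal(ms$global_clustering, mean(ms$nodal_clustering))
  expect_lt(abs(sum(ms$nodal_modularity) - ms$modularity_Q), 1e-9)
  expect_identical(ms, metric_set(W, seed = 4))

  # exchangeable all-equal-weight graph: nodal efficiencies all equal
  E <- matrix(0.5, 6, 6); diag(E) <- 0
  mse <- metric_set(E, seed = 1)
  expect_equal(max(ms$nodal_efficiency) >= 0, TRUE)
  expect_equal(unname(diff(range(mse$nodal_efficiency))), 0, tolerance = 1e-12)

  # scaling weights by a common factor <= 1/max: clustering unchanged,
  # efficiency scales monotonically
  W2 <- W * 0.5
  expect_equal(clustering_coefficient(W2), clustering_coefficient(W),
               tolerance = 1e-12)
  expect_equal(global_efficiency(W2), 0.5 * global_efficiency(W),
               tolerance = 1e-12)
})
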