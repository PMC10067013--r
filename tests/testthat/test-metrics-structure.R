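test_that("centroids and PCD match hand and loop oracles", {
  # one cluster: centroid is the mean
  X <- matrix(c(0, 0, 2, 2), 2, 2, byrow = TRUE)
  expect_equal(unname(cluster_centroids(X, c(1, 1))), matrix(c(1, 1), 1))
  # every cell its own cluster: centroids equal the data
  X2 <- matrix(rnorm(12), 4, 3)
  expect_equal(unname(cluster_centroids(X2, 1:4)), X2)
  # random matrix against brute-force group means
  set.seed(5)
  X3 <- matrix(rnorm(500), 100, 5)
  lab <- sample(letters[1:3], 100, replace = TRUE)
  cent <- cluster_centroids(X3, lab)
  for (cl in c("a", "b", "c"))
    expect_equal(cent[cl, ], colMeans(X3[lab == cl, ]), tolerance = 1e-12)

  # 3-4-5 triangle distances
  X4 <- matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE)
  pcd <- compute_pcd(X4, centroids = X4)
  expect_equal(unname(pcd$dists), matrix(c(0, 5, 5, 0), 2), tolerance = 1e-12)
  # shape is N x C
  pcd2 <- compute_pcd(X3, lab)
  expect_identical(dim(pcd2$dists), c(100L, 3L))
  # a cell sitting at a centroid has distance zero to it
  expect_equal(pcd$dists[1, 1], 0)
})

test_that("global Spearman matches the worked value and rank properties", {
  expect_equal(global_spearman(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  set.seed(6)
  p <- compute_pcd(matrix(rnorm(60), 20, 3), rep(1:2, 10))
  expect_equal(global_spearman(p, p), 1.0)
  flipped <- max(p$dists) - p$dists
  expect_equal(global_spearman(p, flipped), -1.0)
  # invariant under strictly monotone transforms
  expect_equal(global_spearman(p$dists, exp(p$dists / 2)), 1.0)
  # constant vector is undefined
  expect_true(is.na(global_spearman(matrix(1, 3, 2), matrix(rnorm(6), 3, 2))))
  # agreement with the rank/Pearson oracle on random vectors
  for (s in 1:5) {
    set.seed(s)
    x <- rnorm(200); y <- x + rnorm(200)
    expect_equal(global_spearman(x, y), oracle_spearman(x, y),
                 tolerance = 1e-9)
  }
})

test_that("global EMD matches the CDF-integral oracle and its axioms", {
  expect_equal(global_emd(c(0, 1), c(0, 1)), 0)
  expect_equal(wasserstein1d(c(0, 1), c(0, 0.5, 1)), 1 / 6, tolerance = 1e-12)
  # both constant vectors normalize to zeros
  expect_equal(global_emd(rep(3, 5), rep(9, 7)), 0)
  for (s in 1:5) {
    set.seed(s)
    x <- rnorm(150); y <- rnorm(120, 1)
    expect_equal(wasserstein1d(x, y), oracle_emd1d(x, y), tolerance = 1e-9)
    expect_equal(global_emd(x, y),
                 oracle_emd1d(oracle_minmax(x), oracle_minmax(y)),
                 tolerance = 1e-9)
    # symmetry and triangle inequality on normalized vectors
    z <- runif(90)
    expect_equal(global_emd(x, y), global_emd(y, x), tolerance = 1e-12)
    expect_lte(global_emd(x, y),
               global_emd(x, z) + global_emd(z, y) + 1e-12)
  }
})

test_that("neighbor sets match the quadratic oracle in exact mode", {
  # 2 cells: each is the other's neighbor
  X <- matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE)
  nb <- build_neighbors(X, k = 1)
  expect_equal(as.vector(nb$idx), c(2L, 1L))
  # saturation: k >= N-1 gives all other cells
  X2 <- matrix(rnorm(20), 10, 2)
  nb2 <- build_neighbors(X2, k = 50)
  expect_equal(nb2$k, 9L)
  for (i in 1:10) expect_setequal(nb2$idx[i, ], setdiff(1:10, i))
  # brute-force agreement on 200 random cells
  set.seed(8)
  X3 <- matrix(rnorm(600), 200, 3)
  nb3 <- build_neighbors(X3, k = 10, mode = "exact")
  orc <- oracle_knn_sets(X3, 10)
  for (i in 1:200) expect_identical(as.integer(nb3$idx[i, ]), orc[[i]])
})

test_that("approximate neighbors reach 0.95 recall on a mixture fixture", {
  set.seed(9)
  fix <- make_blobs(rbind(c(0, 0, 0), c(5, 0, 0), c(0, 5, 0), c(3, 3, 3)),
                    n_per = 1250, sd = 1, seed = 9)
  exact <- build_neighbors(fix$X, k = 30, mode = "exact")
  approx <- build_neighbors(fix$X, k = 30, mode = "approximate")
  expect_gte(neighbor_recall(approx, exact), 0.95)
})

test_that("knn score matches hand enumeration and invariances", {
  # 1-D: every nearest neighbor changes between the two arrangements
  Xo <- matrix(c(0, 1, 10, 11), ncol = 1)
  Xe <- matrix(c(0, 10, 1, 11), ncol = 1)
  expect_equal(knn_score(build_neighbors(Xo, 1), build_neighbors(Xe, 1)), 0)
  # identical sets give 1; saturation gives 1
  nb <- build_neighbors(Xo, 2)
  expect_equal(knn_score(nb, nb), 1)
  expect_equal(knn_score(build_neighbors(Xo, 3), build_neighbors(Xe, 3)), 1)
  # rigid transform + uniform scaling invariance (exact mode)
  set.seed(10)
  X <- matrix(rnorm(300), 100, 3)
  theta <- 0.7
  R <- diag(3); R[1:2, 1:2] <- matrix(c(cos(theta), sin(theta),
                                        -sin(theta), cos(theta)), 2)
  Xt <- 3.7 * X %*% R + matrix(c(5, -2, 1), 100, 3, byrow = TRUE)
  expect_equal(knn_score(build_neighbors(X, 10), build_neighbors(Xt, 10)), 1)
  # random data against the full loop oracle
  E <- matrix(rnorm(200), 100, 2)
  expect_equal(knn_score(build_neighbors(X, 7), build_neighbors(E, 7)),
               oracle_knn_score(X, E, 7), tolerance = 1e-12)
})

test_that("NPE is zero on identity, NA when degenerate, oracle-exact otherwise", {
  set.seed(11)
  fix <- make_blobs(rbind(c(0, 0), c(2, 0), c(0, 2)), n_per = 40, sd = 1)
  nb <- build_neighbors(fix$X, k = 15)
  expect_equal(npe(nb, nb, fix$labels), 0)
  # far-separated blobs: all proportions 1 in both spaces -> all skipped
  far <- make_blobs(rbind(c(0, 0), c(100, 100)), n_per = 20, sd = 0.1)
  nf <- build_neighbors(far$X, k = 5)
  expect_true(is.na(npe(nf, nf, far$labels)))
  # shuffled embedding against the independently coded five-step oracle
  set.seed(12)
  E <- fix$X[sample(nrow(fix$X)), ]
  nbe <- build_neighbors(E, k = 15)
  got <- npe(nb, nbe, fix$labels)
  expect_gt(got, 0)
  expect_equal(got, oracle_npe(fix$X, E, fix$labels, 15), tolerance = 1e-9)
  # invariant to cluster relabeling
  relab <- c("z", "a", "q")[fix$labels]
  expect_equal(npe(nb, nbe, relab), got, tolerance = 1e-12)
})
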