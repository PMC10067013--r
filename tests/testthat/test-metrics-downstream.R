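test_that("embedding clustering recovers separable structure", {
  fix <- make_blobs(rbind(c(0, 0), c(50, 50)), n_per = 40, sd = 0.5, seed = 1)
  got <- cluster_embedding(fix$X, 2, algorithm = "kmeans", seed = 2)
  expect_equal(ari(got, fix$labels), 1)
  # hint = N: every cell its own cluster
  small <- fix$X[1:12, ]
  expect_setequal(cluster_embedding(small, 12, algorithm = "kmeans", seed = 3),
                  1:12)
  expect_error(cluster_embedding(small, 13, algorithm = "kmeans"), "exceeds")
  # SOM + meta-clustering on a 3-blob fixture
  fix3 <- make_blobs(rbind(c(0, 0), c(10, 0), c(0, 10)), n_per = 120,
                     sd = 1, seed = 4)
  som <- cluster_embedding(fix3$X, 3, algorithm = "som_meta", seed = 5)
  expect_gte(ari(som, fix3$labels), 0.9)
})

test_that("silhouette matches limit, hand and loop oracles", {
  far <- make_blobs(rbind(c(0, 0), c(100, 100)), n_per = 25, sd = 1, seed = 6)
  expect_gte(silhouette_score(far$X, far$labels), 0.95)
  # 4 points on a line, hand-checkable
  E <- matrix(c(0, 1, 10, 11), ncol = 1)
  lab <- c(1, 1, 2, 2)
  expect_equal(silhouette_score(E, lab), oracle_silhouette(E, lab),
               tolerance = 1e-12)
  expect_gt(silhouette_score(E, lab), 0.85)
  # random labels on one blob: near zero
  set.seed(7)
  blob <- matrix(rnorm(200), 100, 2)
  rl <- sample(1:2, 100, replace = TRUE)
  expect_lt(abs(silhouette_score(blob, rl)), 0.15)
  expect_error(silhouette_score(blob, rep(1, 100)), "2 clusters")
  # loop-oracle agreement on an irregular instance
  fix <- make_blobs(rbind(c(0, 0), c(3, 1), c(1, 3)), n_per = 15, sd = 1.2,
                    seed = 8)
  expect_equal(silhouette_score(fix$X, fix$labels),
               oracle_silhouette(fix$X, fix$labels), tolerance = 1e-9)
})

test_that("Davies-Bouldin matches the loop oracle and is monotone in spread", {
  # point-mass clusters at distinct locations score 0
  E <- matrix(c(0, 0, 0, 0, 5, 5, 5, 5), 4, 2, byrow = TRUE)
  expect_equal(davies_bouldin(E, c(1, 1, 2, 2)), 0)
  # 6-point hand instance
  E6 <- matrix(c(0, 0, 1, 0, 0, 1, 8, 8, 9, 8, 8, 9), 6, 2, byrow = TRUE)
  l6 <- c(1, 1, 1, 2, 2, 2)
  expect_equal(davies_bouldin(E6, l6), oracle_dbi(E6, l6), tolerance = 1e-12)
  # shrinking within-cluster spread with fixed centroids lowers the index
  vals <- sapply(c(1, 0.5, 0.25), function(s) {
    fix <- make_blobs(rbind(c(0, 0), c(6, 0), c(0, 6)), n_per = 30,
                      sd = s, seed = 9)
    davies_bouldin(scale(fix$X, scale = FALSE), fix$labels)
  })
  expect_true(all(diff(vals) < 0))
  # loop oracle on a random instance
  fix <- make_blobs(rbind(c(0, 0), c(2, 2), c(4, 0)), n_per = 12, sd = 1,
                    seed = 10)
  expect_equal(davies_bouldin(fix$X, fix$labels),
               oracle_dbi(fix$X, fix$labels), tolerance = 1e-9)
})

test_that("Calinski-Harabasz matches the loop oracle and its conventions", {
  E <- matrix(c(0, 0, 0, 0, 5, 5, 5, 5), 4, 2, byrow = TRUE)
  expect_true(is.na(calinski_harabasz(E, c(1, 1, 2, 2))))  # zero within-var
  E6 <- matrix(c(0, 0, 1, 0, 0, 1, 8, 8, 9, 8, 8, 9), 6, 2, byrow = TRUE)
  l6 <- c(1, 1, 1, 2, 2, 2)
  expect_equal(calinski_harabasz(E6, l6), oracle_chi(E6, l6),
               tolerance = 1e-12)
  # translation invariance
  shift <- E6 + matrix(c(100, -50), 6, 2, byrow = TRUE)
  expect_equal(calinski_harabasz(shift, l6), calinski_harabasz(E6, l6),
               tolerance = 1e-9)
  fix <- make_blobs(rbind(c(0, 0), c(2, 2), c(4, 0)), n_per = 12, sd = 1,
                    seed = 11)
  expect_equal(calinski_harabasz(fix$X, fix$labels),
               oracle_chi(fix$X, fix$labels), tolerance = 1e-9)
})

test_that("random-forest prediction separates blobs and nulls out on noise", {
  far <- make_blobs(rbind(c(0, 0), c(100, 100)), n_per = 60, sd = 1, seed = 12)
  expect_gte(rf_cluster_prediction(far$X, far$labels, seed = 1), 0.99)
  # permuted labels on balanced classes: chance level
  set.seed(13)
  acc <- rf_cluster_prediction(matrix(rnorm(400), 200, 2),
                               rep(1:2, each = 100), seed = 2)
  expect_lt(abs(acc - 0.5), 0.11)
  # reproducible under a fixed seed
  expect_identical(rf_cluster_prediction(far$X, far$labels, seed = 3),
                   rf_cluster_prediction(far$X, far$labels, seed = 3))
  expect_error(rf_cluster_prediction(far$X, c(3, far$labels[-1])), "2 members")
})

test_that("ARI matches pair-counting brute force", {
  expect_equal(ari(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(ari(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  expect_equal(ari(c(1, 1, 2, 2), c("b", "b", "a", "a")), 1)  # relabeling
  for (s in 1:5) {
    set.seed(s)
    a <- sample(1:3, 30, replace = TRUE)
    b <- sample(1:4, 30, replace = TRUE)
    expect_equal(ari(a, b), oracle_ari(a, b), tolerance = 1e-9)
    expect_equal(ari(a, b), ari(b, a), tolerance = 1e-12)
  }
})

test_that("NMI matches the entropy formula and conventions", {
  expect_equal(nmi(c(1, 1, 2, 2), c(2, 2, 7, 7)), 1)
  expect_equal(nmi(c(1, 1, 1, 1), c(1, 2, 1, 2)), 0)  # constant labeling
  # 12-cell hand instance against the plug-in entropy oracle
  a <- c(1, 1, 1, 1, 2, 2, 2, 2, 3, 3, 3, 3)
  b <- c(1, 1, 2, 2, 2, 2, 3, 3, 3, 1, 1, 1)
  expect_equal(nmi(a, b), oracle_nmi(a, b), tolerance = 1e-9)
  for (s in 1:5) {
    set.seed(s)
    x <- sample(1:3, 40, replace = TRUE); y <- sample(1:3, 40, replace = TRUE)
    expect_equal(nmi(x, y), oracle_nmi(x, y), tolerance = 1e-9)
    expect_equal(nmi(x, y), nmi(y, x), tolerance = 1e-12)
  }
})

test_that("NMI agrees with the igraph implementation", {
  skip_if_not_installed("igraph")
  for (s in 1:5) {
    set.seed(s)
    x <- sample(1:4, 60, replace = TRUE); y <- sample(1:3, 60, replace = TRUE)
    expect_equal(nmi(x, y), igraph::compare(x, y, method = "nmi"),
                 tolerance = 1e-9)
  }
})

test_that("cell-type concordance reuses the agreement measures", {
  ct <- rep(c("B", "T", "NK"), each = 10)
  cl <- rep(1:3, each = 10)
  out <- celltype_clustering_concordance(ct, cl)
  expect_equal(out$ari, 1)
  expect_equal(out$nmi, 1)
  set.seed(14)
  out2 <- celltype_clustering_concordance(ct, sample(cl))
  expect_lt(abs(out2$ari), 0.35)
})
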