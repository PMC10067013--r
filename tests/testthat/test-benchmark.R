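test_that("a single-method benchmark completes with no failures", {
  m <- blob_model(P = 3, M = 6)
  s <- simulate_cytof(m, 600, seed = 1)
  b <- run_benchmark(s$expression, "pca", labels = s$cell_types, k = 30,
                     seed = 2, clustering = "kmeans")
  expect_s3_class(b, "dr_benchmark")
  vals <- b$scores$values
  expect_identical(rownames(vals), "pca")
  expect_true(all(is.finite(vals[, setdiff(colnames(vals), "npe")])))
  expect_gt(vals[, "cor"], 0.5)
})

test_that("a failing method is all-NA and ranked last overall", {
  register_dr_method("always_fails", function(X, params, seed) stop("nope"),
                     overwrite = TRUE)
  # overlapping blobs keep every metric (NPE included) estimable for pca,
  # so the failed method sits strictly at the bottom everywhere
  fix <- make_blobs(rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0)),
                    n_per = 130, sd = 1, seed = 3)
  s <- list(expression = fix$X, cell_types = fix$labels)
  b <- run_benchmark(s$expression, c("pca", "always_fails"),
                     labels = s$cell_types, k = 20, seed = 4,
                     clustering = "kmeans")
  expect_true(all(is.na(b$scores$values["always_fails", ])))
  expect_equal(b$results$always_fails$status, "error")
  expect_lt(b$ranks$overall["always_fails"], b$ranks$overall["pca"])
  expect_equal(unname(b$ranks$overall["always_fails"]), 1)
  # every method failing is a hard error
  expect_error(run_benchmark(s$expression, "always_fails",
                             labels = s$cell_types, seed = 5),
               "no method")
})

test_that("benchmarks are deterministic under identical config and seed", {
  m <- blob_model(P = 3, M = 6)
  s <- simulate_cytof(m, 400, seed = 6)
  b1 <- run_benchmark(s$expression, c("pca", "random_proj"),
                      labels = s$cell_types, k = 20, seed = 7,
                      clustering = "kmeans")
  b2 <- run_benchmark(s$expression, c("pca", "random_proj"),
                      labels = s$cell_types, k = 20, seed = 7,
                      clustering = "kmeans")
  expect_identical(b1$scores$values, b2$scores$values)
  # inserting a method does not perturb the other methods' seeds
  b3 <- run_benchmark(s$expression, c("pca", "random_proj", "nmf"),
                      labels = s$cell_types, k = 20, seed = 7,
                      clustering = "kmeans")
  expect_identical(b3$scores$values["random_proj", ],
                   b1$scores$values["random_proj", ])
})

test_that("benchmark artifacts are written to the output directory", {
  m <- blob_model(P = 2, M = 5)
  s <- simulate_cytof(m, 200, seed = 8)
  out <- file.path(tempdir(), "benchrun")
  b <- run_benchmark(s$expression, "pca", labels = s$cell_types, k = 10,
                     seed = 9, clustering = "kmeans", out_dir = out)
  expect_true(file.exists(file.path(out, "scores.tsv")))
  expect_true(file.exists(file.path(out, "ranks.tsv")))
  expect_true(file.exists(file.path(out, "embedding_pca.csv")))
  log <- readLines(file.path(out, "run.log"))
  expect_true(any(grepl("stage=dr method=pca status=ok", log)))
  back <- read_scores(file.path(out, "scores.tsv"))
  expect_equal(back["pca", "cor"], unname(b$scores$values["pca", "cor"]))
})

test_that("fixture factory writes documented ground truth", {
  d <- file.path(tempdir(), "fix")
  p <- make_fixture("blobs", dir = d, n_cells = 300, n_types = 3,
                    n_markers = 6, seed = 1)
  X <- read_expression(p[["expression"]])
  lab <- read_labels(p[["cell_types"]])
  expect_identical(dim(X), c(300L, 6L))
  expect_equal(length(unique(lab)), 3L)

  p2 <- make_fixture("trajectory", dir = d, n_cells = 200, n_types = 4,
                     n_markers = 5, seed = 2)
  pt <- as.matrix(utils::read.csv(p2[["pseudotime"]]))
  expect_true(all(pt >= 0 & pt <= 1))

  # jitter 0: the second modality is an exact copy, so the concordance
  # metrics sit at their identity values
  p3 <- make_fixture("two_modality", dir = d, n_cells = 300, n_types = 3,
                     n_markers = 6, jitter = 0, seed = 3)
  X3 <- read_expression(p3[["expression"]])
  R3 <- read_expression(p3[["modality2"]])
  t3 <- read_labels(p3[["cell_types"]])
  common <- sort(unique(t3))
  expect_equal(cluster_distance(rank_distance_centroids(X3, t3, common),
                                rank_distance_centroids(R3, t3, common)), 0)
  expect_equal(concordance_emd(X3, t3, R3, t3, common), 0)
  expect_equal(gating_concordance(t3, t3)$ari, 1)
})

test_that("matched-modality benchmarks include the concordance category", {
  m <- blob_model(P = 3, M = 6)
  s <- simulate_cytof(m, 500, seed = 10)
  ct <- paste0("type", s$cell_types)
  b <- run_benchmark(s$expression, "pca", labels = s$cell_types,
                     cell_types = ct, rna = s$expression, rna_types = ct,
                     k = 20, seed = 11, clustering = "kmeans")
  expect_true(all(c("cluster_distance", "concordance_emd", "gating_ari",
                    "gating_nmi") %in% colnames(b$scores$values)))
  expect_true(all(c("major:scrna", "major:global") %in%
                  colnames(b$ranks$category_scores)))
})
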