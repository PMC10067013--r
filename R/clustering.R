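# Embedding-space clustering. The default mirrors the cytometry standard:
# a self-organizing map over the cells followed by hierarchical
# meta-clustering of the codebook vectors down to the requested number of
# clusters. A deterministic kmeans fallback is provided so metric tests are
# not hostage to SOM stochasticity.

# batch self-organizing map on a grid_dim x grid_dim grid
som_fit <- function(X, grid_dim = 10L, n_epochs = 10L) {
  n <- nrow(X); ncode <- grid_dim^2L
  gx <- rep(seq_len(grid_dim), each = grid_dim)
  gy <- rep(seq_len(grid_dim), times = grid_dim)
  grid_d2 <- outer(gx, gx, "-")^2 + outer(gy, gy, "-")^2
  codes <- X[sample.int(n, ncode, replace = n < ncode), , drop = FALSE]
  radius <- seq(grid_dim / 2, 0.5, length.out = n_epochs)
  for (ep in seq_len(n_epochs)) {
    d <- outer(rowSums(X^2), rep(1, ncode)) - 2 * tcrossprod(X, codes) +
      outer(rep(1, n), rowSums(codes^2))
    bmu <- max.col(-d, ties.method = "first")
    h <- exp(-grid_d2 / (2 * radius[ep]^2))       # neighborhood kernel
    w <- h[, bmu, drop = FALSE]                   # ncode x n
    denom <- rowSums(w)
    denom[denom == 0] <- 1
    codes <- (w %*% X) / denom
  }
  d <- outer(rowSums(X^2), rep(1, ncode)) - 2 * tcrossprod(X, codes) +
    outer(rep(1, n), rowSums(codes^2))
  list(codes = codes, bmu = max.col(-d, ties.method = "first"))
}

#' Cluster an embedding
#'
#' @param E numeric matrix (cells x dims), typically a 2-D embedding.
#' @param n_clusters_hint target number of clusters.
#' @param algorithm `"som_meta"` (self-organizing map + hierarchical
#'   meta-clustering of codebook vectors, Ward linkage) or `"kmeans"`
#'   (deterministic fallback, `stats::kmeans` with multiple starts).
#' @param seed integer seed or `NULL`.
#' @param grid_dim SOM grid side length; default 10 (100 codebook vectors).
#' @param over_clusters extra SOM-level granularity retained before
#'   meta-clustering consolidates down to the hint; default 15 keeps rare
#'   populations as separate codes (the consolidation makes the end result
#'   robust to this choice).
#' @return integer vector of cluster labels of length `nrow(E)`.
#' @export
cluster_embedding <- function(E, n_clusters_hint,
                              algorithm = c("som_meta", "kmeans"),
                              seed = NULL, grid_dim = 10L,
                              over_clusters = 15L) {
  algorithm <- match.arg(algorithm)
  check_matrix(E, "E")
  n <- nrow(E)
  if (n_clusters_hint < 1L) stop("n_clusters_hint must be >= 1", call. = FALSE)
  if (n_clusters_hint > n)
    stop("n_clusters_hint exceeds the number of cells", call. = FALSE)
  with_seed(seed, {
    if (algorithm == "kmeans") {
      if (n_clusters_hint == n) return(seq_len(n))
      km <- stats::kmeans(E, centers = n_clusters_hint, nstart = 10L,
                          iter.max = 50L)
      as.integer(km$cluster)
    } else {
      fit <- som_fit(E, grid_dim = grid_dim)
      used <- sort(unique(fit$bmu))
      codes <- fit$codes[used, , drop = FALSE]
      target <- min(n_clusters_hint, nrow(codes))
      hc <- stats::hclust(stats::dist(codes), method = "ward.D2")
      meta <- stats::cutree(hc, k = target)
      meta[match(fit$bmu, used)]
    }
  })
}
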