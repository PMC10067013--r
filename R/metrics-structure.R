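# Global and local structure-preservation metrics. Global metrics compare
# Point-Cluster Distances (PCD): the N x C matrix of Euclidean distances
# from every cell to every original-space cluster centroid, a memory-linear
# surrogate for the full pairwise distance matrix. Local metrics compare
# k-nearest-neighbor sets between the original and embedding spaces.

#' Cluster centroids
#'
#' Arithmetic mean of the rows in each cluster. Cluster order is the sorted
#' order of the distinct labels.
#'
#' @param X numeric matrix (cells x dims).
#' @param labels cluster labels, length `nrow(X)`.
#' @return clusters x dims matrix with cluster ids as row names.
#' @export
cluster_centroids <- function(X, labels) {
  check_matrix(X, "X")
  check_labels(labels, nrow(X))
  labels <- as.character(labels)
  ids <- sort(unique(labels))
  cent <- t(vapply(ids, function(cl)
    colMeans(X[labels == cl, , drop = FALSE]), numeric(ncol(X))))
  if (ncol(X) == 1L) cent <- matrix(cent, ncol = 1L, dimnames = list(ids, NULL))
  rownames(cent) <- ids
  cent
}

#' Point-Cluster Distance matrix
#'
#' Euclidean distance from each cell to each cluster centroid. Centroids are
#' computed from `labels` unless supplied directly.
#'
#' @param X numeric matrix (cells x dims).
#' @param labels cluster labels (used to compute centroids), or `NULL` if
#'   `centroids` is given.
#' @param centroids optional clusters x dims matrix.
#' @return object of class `pcd`: list with `dists` (N x C matrix) and
#'   `cluster_ids`.
#' @export
compute_pcd <- function(X, labels = NULL, centroids = NULL) {
  check_matrix(X, "X")
  if (is.null(centroids)) {
    if (is.null(labels)) stop("supply labels or centroids", call. = FALSE)
    centroids <- cluster_centroids(X, labels)
  }
  centroids <- as.matrix(centroids)
  if (ncol(centroids) != ncol(X))
    stop("centroid dimension does not match data", call. = FALSE)
  d2 <- outer(rowSums(X^2), rep(1, nrow(centroids))) -
    2 * tcrossprod(X, centroids) +
    outer(rep(1, nrow(X)), rowSums(centroids^2))
  d2[d2 < 0] <- 0
  structure(list(dists = sqrt(d2),
                 cluster_ids = rownames(centroids) %||%
                   as.character(seq_len(nrow(centroids)))),
            class = "pcd")
}

pcd_vector <- function(pcd) {
  if (inherits(pcd, "pcd")) as.vector(pcd$dists) else as.vector(pcd)
}

#' Global structure preservation: Spearman correlation of PCDs
#'
#' The original-space and embedding-space PCD matrices are flattened and
#' their Spearman rank correlation is returned. Higher is better; 1 means
#' the ranking of all cell-to-centroid distances is perfectly preserved.
#'
#' @param pcd_orig,pcd_emb `pcd` objects (or matrices) of identical shape.
#' @return scalar in `[-1, 1]`, or `NA` if either vector is constant.
#' @export
global_spearman <- function(pcd_orig, pcd_emb) {
  x <- pcd_vector(pcd_orig); y <- pcd_vector(pcd_emb)
  if (length(x) != length(y))
    stop("PCD shapes differ", call. = FALSE)
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

#' Global structure preservation: Earth Mover's Distance of PCDs
#'
#' Both flattened PCD vectors are min-max normalized (to remove the scale
#' difference between original and embedding space) and compared as
#' empirical one-dimensional distributions with the Wasserstein distance.
#' Lower is better; 0 iff the normalized distributions coincide. A constant
#' vector normalizes to all zeros, so two constant vectors score 0.
#'
#' @param pcd_orig,pcd_emb `pcd` objects (or numeric vectors/matrices).
#' @return non-negative scalar.
#' @export
global_emd <- function(pcd_orig, pcd_emb) {
  wasserstein1d(minmax(pcd_vector(pcd_orig)), minmax(pcd_vector(pcd_emb)))
}

#' Local structure preservation: k-nearest-neighbor overlap
#'
#' For each cell, the fraction of its k original-space neighbors retained in
#' the embedding space, averaged over cells. Higher is better; 1 means every
#' neighborhood is perfectly preserved.
#'
#' @param nb_orig,nb_emb `neighbor_sets` over the same cells with equal `k`.
#' @return scalar in `[0, 1]`.
#' @export
knn_score <- function(nb_orig, nb_emb) {
  stopifnot(inherits(nb_orig, "neighbor_sets"),
            inherits(nb_emb, "neighbor_sets"))
  if (nrow(nb_orig$idx) != nrow(nb_emb$idx) || nb_orig$k != nb_emb$k)
    stop("neighbor sets must share N and k", call. = FALSE)
  n <- nrow(nb_orig$idx)
  hits <- vapply(seq_len(n), function(i)
    length(intersect(nb_orig$idx[i, ], nb_emb$idx[i, ])), integer(1L))
  mean(hits) / nb_orig$k
}

# Scott-type bandwidth; falls back to the SD-only rule when the IQR is 0 so
# that a positive-variance vector always gets a positive bandwidth.
kde_bandwidth <- function(x) {
  s <- stats::sd(x)
  iqr <- stats::IQR(x)
  bw <- 1.06 * min(s, iqr / 1.34) * length(x)^(-1 / 5)
  if (bw <= 0) bw <- 1.06 * s * length(x)^(-1 / 5)
  bw
}

# Gaussian KDE evaluated exactly on a grid (no binning), so results are
# reproducible to full floating-point precision.
kde_on_grid <- function(x, grid, bw) {
  colMeans(stats::dnorm(outer(x, grid, "-") / bw)) / bw
}

#' Local structure preservation: Neighborhood Proportion Error
#'
#' For each cell, the proportion of its k neighbors sharing the cell's
#' original-space cluster is computed in both spaces. Per cluster, Gaussian
#' kernel density estimates of the two proportion distributions are compared
#' by the supremum of their absolute difference over a uniform grid on
#' `[0, 1]`; the per-cluster values are averaged. Clusters whose proportion
#' vector is constant in either space carry an inestimable point-mass
#' density and are skipped. Lower is better; 0 when neighborhoods keep the
#' same class composition.
#'
#' @param nb_orig,nb_emb `neighbor_sets` over the same cells with equal `k`.
#' @param labels original-space cluster labels.
#' @param grid_size number of grid points on `[0, 1]`; default 1024.
#' @return non-negative scalar, or `NA` if every cluster was skipped.
#' @export
npe <- function(nb_orig, nb_emb, labels, grid_size = 1024) {
  stopifnot(inherits(nb_orig, "neighbor_sets"),
            inherits(nb_emb, "neighbor_sets"))
  n <- nrow(nb_orig$idx)
  if (nrow(nb_emb$idx) != n || nb_orig$k != nb_emb$k)
    stop("neighbor sets must share N and k", call. = FALSE)
  check_labels(labels, n)
  labels <- as.character(labels)
  k <- nb_orig$k
  same_prop <- function(nb) {
    lab_mat <- matrix(labels[nb$idx], n, k)
    rowSums(lab_mat == labels) / k
  }
  p_orig <- same_prop(nb_orig)
  p_emb <- same_prop(nb_emb)
  grid <- seq(0, 1, length.out = grid_size)
  tvs <- c()
  for (cl in sort(unique(labels))) {
    xo <- p_orig[labels == cl]
    xe <- p_emb[labels == cl]
    if (length(xo) < 2L || stats::var(xo) == 0 || stats::var(xe) == 0)
      next  # inestimable point mass
    Pc <- kde_on_grid(xo, grid, kde_bandwidth(xo))
    Qc <- kde_on_grid(xe, grid, kde_bandwidth(xe))
    tvs <- c(tvs, max(abs(Pc - Qc)))
  }
  if (!length(tvs)) return(NA_real_)
  mean(tvs)
}
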