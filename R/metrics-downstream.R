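# Downstream analysis metrics: how well original-space clustering survives
# in the embedding (cluster reconstruction), and partition agreement between
# labelings (cluster concordance, cell-type concordance).

#' Mean silhouette width
#'
#' Cohesion-vs-separation of a clustering in the embedding, by Euclidean
#' distance; the per-cell silhouette `(b - a) / max(a, b)` averaged over
#' cells. Higher is better.
#'
#' @param E numeric matrix (cells x dims).
#' @param labels cluster labels with at least 2 distinct values.
#' @return scalar in `[-1, 1]`.
#' @export
silhouette_score <- function(E, labels) {
  check_matrix(E, "E")
  check_labels(labels, nrow(E))
  labels <- as.integer(factor(labels))
  if (length(unique(labels)) < 2L)
    stop("silhouette requires at least 2 clusters", call. = FALSE)
  sil <- cluster::silhouette(labels, stats::dist(E))
  mean(sil[, "sil_width"])
}

#' Davies-Bouldin index
#'
#' Average over clusters of the maximal ratio of summed within-cluster
#' scatter to centroid separation. Lower is better; 0 for point-mass
#' clusters at distinct locations.
#'
#' @inheritParams silhouette_score
#' @return non-negative scalar.
#' @export
davies_bouldin <- function(E, labels) {
  check_matrix(E, "E")
  check_labels(labels, nrow(E))
  labels <- as.character(labels)
  ids <- sort(unique(labels))
  k <- length(ids)
  if (k < 2L) stop("Davies-Bouldin requires at least 2 clusters", call. = FALSE)
  cent <- cluster_centroids(E, labels)
  scatter <- vapply(ids, function(cl) {
    rows <- E[labels == cl, , drop = FALSE]
    mean(sqrt(rowSums((rows - matrix(cent[cl, ], nrow(rows), ncol(E),
                                     byrow = TRUE))^2)))
  }, numeric(1L))
  M <- as.matrix(stats::dist(cent))
  r <- numeric(k)
  for (i in seq_len(k)) {
    ratios <- (scatter[i] + scatter[-i]) / M[i, -i]
    r[i] <- max(ratios)
  }
  mean(r)
}

#' Calinski-Harabasz index
#'
#' Ratio of between-cluster to within-cluster variance, scaled by degrees
#' of freedom. Higher is better. When every cluster is a point mass the
#' within-variance is 0 and `NA` is returned to keep rank tables finite.
#'
#' @inheritParams silhouette_score
#' @return non-negative scalar or `NA`.
#' @export
calinski_harabasz <- function(E, labels) {
  check_matrix(E, "E")
  check_labels(labels, nrow(E))
  labels <- as.character(labels)
  ids <- sort(unique(labels))
  k <- length(ids); n <- nrow(E)
  if (k < 2L) stop("Calinski-Harabasz requires at least 2 clusters",
                   call. = FALSE)
  if (n <= k) stop("need more cells than clusters", call. = FALSE)
  cent <- cluster_centroids(E, labels)
  gmean <- colMeans(E)
  sizes <- table(labels)[ids]
  B <- sum(as.numeric(sizes) *
             rowSums((cent - matrix(gmean, k, ncol(E), byrow = TRUE))^2))
  W <- sum(vapply(ids, function(cl) {
    rows <- E[labels == cl, , drop = FALSE]
    sum((rows - matrix(cent[cl, ], nrow(rows), ncol(E), byrow = TRUE))^2)
  }, numeric(1L)))
  if (W == 0) return(NA_real_)
  (B / (k - 1)) / (W / (n - k))
}

#' Random-forest cluster prediction accuracy
#'
#' Trains a random forest on a stratified 67/33 split of the embedding and
#' reports held-out accuracy at predicting the original-space cluster
#' labels. Higher is better: separable clusters in the embedding are easy
#' to predict.
#'
#' @param E numeric matrix (cells x dims).
#' @param labels cluster labels; every class needs at least 2 members.
#' @param train_fraction training fraction of each class; default 0.67.
#' @param seed integer seed or `NULL`.
#' @param ntree number of trees; default 100.
#' @return scalar accuracy in `[0, 1]`.
#' @export
rf_cluster_prediction <- function(E, labels, train_fraction = 0.67,
                                  seed = NULL, ntree = 100L) {
  check_matrix(E, "E")
  check_labels(labels, nrow(E))
  y <- factor(labels)
  if (any(table(y) < 2L))
    stop("every class needs at least 2 members for a stratified split",
         call. = FALSE)
  with_seed(seed, {
    train <- unlist(lapply(levels(y), function(cl) {
      idx <- which(y == cl)
      n_tr <- max(1L, min(length(idx) - 1L, round(train_fraction * length(idx))))
      sample(idx, n_tr)
    }))
    test <- setdiff(seq_len(nrow(E)), train)
    fit <- randomForest::randomForest(x = E[train, , drop = FALSE],
                                      y = droplevels(y[train]),
                                      ntree = ntree)
    pred <- stats::predict(fit, E[test, , drop = FALSE])
    mean(as.character(pred) == as.character(y[test]))
  })
}

#' Adjusted Rand Index
#'
#' Pair-counting agreement between two partitions, adjusted for chance.
#' 1 iff the partitions are identical up to relabeling; independent
#' partitions score near 0.
#'
#' @param a,b label vectors of equal length.
#' @return scalar `<= 1`.
#' @export
ari <- function(a, b) {
  if (length(a) != length(b)) stop("label lengths differ", call. = FALSE)
  mclust::adjustedRandIndex(as.character(a), as.character(b))
}

#' Normalized Mutual Information
#'
#' Mutual information between two partitions normalized by the arithmetic
#' mean of their marginal entropies. 1 for identical non-constant
#' partitions; 0 when either partition is constant (convention) or the
#' partitions are independent.
#'
#' @param a,b label vectors of equal length.
#' @return scalar in `[0, 1]`.
#' @export
nmi <- function(a, b) {
  if (length(a) != length(b)) stop("label lengths differ", call. = FALSE)
  n <- length(a)
  tab <- table(as.character(a), as.character(b))
  pij <- tab / n
  pi_ <- rowSums(pij); pj <- colSums(pij)
  hx <- -sum(ifelse(pi_ > 0, pi_ * log(pi_), 0))
  hy <- -sum(ifelse(pj > 0, pj * log(pj), 0))
  if (hx == 0 || hy == 0) return(0)
  eij <- outer(pi_, pj)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / eij[nz]))
  mi / ((hx + hy) / 2)
}

#' Cell-type/clustering concordance
#'
#' ARI and NMI between assigned cell types and an embedding-space
#' clustering; the same agreement measures as cluster concordance, applied
#' to different inputs.
#'
#' @param cell_types cell-type labels.
#' @param emb_clusters embedding-space cluster labels.
#' @return named list with `ari` and `nmi`.
#' @export
celltype_clustering_concordance <- function(cell_types, emb_clusters) {
  list(ari = ari(cell_types, emb_clusters),
       nmi = nmi(cell_types, emb_clusters))
}
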