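# Cross-modality concordance: compares cell-type geometry between a CyTOF
# embedding and a matched scRNA-seq reference. Distances are converted to
# ranks within each modality, so only relative cell-type arrangement is
# compared, never raw coordinates.

#' Normalized centroid-distance rank vector
#'
#' For each ordered pair (a, b) of common cell types, the rank of
#' `d(centroid_a, centroid_b)` among the distances from `a` to all other
#' centroids (ascending, 1 = nearest, ties broken by centroid index),
#' divided by the number of common types T. The vector is generally
#' asymmetric in (a, b): ranks depend on each type's own neighborhood.
#'
#' @param data numeric matrix (cells x dims), one modality.
#' @param cell_types cell-type labels for `data`'s rows.
#' @param common_types character vector of cell types shared by both
#'   modalities (exact, case-sensitive match); at least 2.
#' @return object of class `rank_distance`: list with `values` (length
#'   `T*(T-1)`, entries in `(0, 1]`) and `pair_index` (2-column character
#'   matrix of ordered pairs).
#' @export
rank_distance_centroids <- function(data, cell_types, common_types) {
  check_matrix(data, "data")
  check_labels(cell_types, nrow(data))
  common_types <- as.character(common_types)
  if (length(common_types) < 2L)
    stop("need at least 2 common cell types", call. = FALSE)
  if (!all(common_types %in% as.character(cell_types)))
    stop("common_types absent from cell_types", call. = FALSE)
  keep <- as.character(cell_types) %in% common_types
  cent <- cluster_centroids(data[keep, , drop = FALSE],
                            as.character(cell_types)[keep])
  cent <- cent[common_types, , drop = FALSE]
  T_ <- length(common_types)
  D <- as.matrix(stats::dist(cent))
  vals <- numeric(0); pairs <- NULL
  for (a in seq_len(T_)) {
    others <- setdiff(seq_len(T_), a)
    d <- D[a, others]
    rk <- rank_with_index_ties(d)
    for (j in seq_along(others)) {
      vals <- c(vals, rk[j] / T_)
      pairs <- rbind(pairs, c(common_types[a], common_types[others[j]]))
    }
  }
  structure(list(values = vals, pair_index = pairs), class = "rank_distance")
}

# ascending 1-based ranks with ties broken by position (lowest index first)
rank_with_index_ties <- function(d) {
  o <- order(d, seq_along(d))
  rk <- integer(length(d))
  rk[o] <- seq_along(d)
  rk
}

#' Cluster Distance between two modalities
#'
#' L1 distance between the normalized centroid-distance rank vectors of the
#' two modalities over the same ordered cell-type pairs. Lower is better; 0
#' when the rank structure of cell types agrees exactly.
#'
#' @param cytof,rna `rank_distance` objects with identical `pair_index`.
#' @return non-negative scalar.
#' @export
cluster_distance <- function(cytof, rna) {
  stopifnot(inherits(cytof, "rank_distance"), inherits(rna, "rank_distance"))
  if (!identical(cytof$pair_index, rna$pair_index))
    stop("pair_index mismatch between modalities", call. = FALSE)
  sum(abs(cytof$values - rna$values))
}

# pooled normalized cell-level rank vector for one modality: for each
# ordered pair (a, b), Euclidean distances from centroid(a) to every cell
# are ranked (ties by cell index); the ranks of b's cells, divided by the
# total cell count, are pooled across pairs.
pooled_cell_ranks <- function(data, cell_types, common_types) {
  cell_types <- as.character(cell_types)
  keep <- cell_types %in% common_types
  X <- data[keep, , drop = FALSE]
  types <- cell_types[keep]
  n <- nrow(X)
  cent <- cluster_centroids(X, types)[common_types, , drop = FALSE]
  out <- numeric(0)
  for (a in common_types) {
    d <- sqrt(rowSums((X - matrix(cent[a, ], n, ncol(X), byrow = TRUE))^2))
    rk <- rank_with_index_ties(d)
    for (b in setdiff(common_types, a)) {
      out <- c(out, rk[types == b] / n)
    }
  }
  out
}

#' Cross-modality EMD over pooled cell-level distance ranks
#'
#' The cell-level refinement of Cluster Distance: per ordered cell-type pair
#' (a, b), the cells of b are ranked by distance from a's centroid among all
#' cells of that modality, normalized by the modality's cell count; the
#' normalized ranks pooled over pairs form one empirical distribution per
#' modality, compared by the Wasserstein distance. Lower is better; 0 when
#' the second modality copies the first.
#'
#' @param cytof_data,rna_data numeric matrices (cells x dims), one per
#'   modality (the CyTOF side is typically the 2-D embedding).
#' @param cytof_types,rna_types cell-type labels per modality.
#' @param common_types cell types shared by both modalities; at least 2.
#' @return non-negative scalar.
#' @export
concordance_emd <- function(cytof_data, cytof_types, rna_data, rna_types,
                            common_types) {
  common_types <- as.character(common_types)
  if (length(common_types) < 2L)
    stop("need at least 2 common cell types", call. = FALSE)
  if (!all(common_types %in% as.character(cytof_types)) ||
      !all(common_types %in% as.character(rna_types)))
    stop("common_types absent from one modality", call. = FALSE)
  x <- pooled_cell_ranks(cytof_data, cytof_types, common_types)
  y <- pooled_cell_ranks(rna_data, rna_types, common_types)
  wasserstein1d(x, y)
}

#' Gating concordance
#'
#' ARI and NMI between original-space and embedding-space cell-type
#' assignments: a validation that typing from the embedding reproduces the
#' reference typing.
#'
#' @param orig_space_types,emb_space_types cell-type label vectors of equal
#'   length.
#' @return named list with `ari` and `nmi`.
#' @export
gating_concordance <- function(orig_space_types, emb_space_types) {
  list(ari = ari(orig_space_types, emb_space_types),
       nmi = nmi(orig_space_types, emb_space_types))
}
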