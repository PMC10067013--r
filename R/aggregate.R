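# Hierarchical equal-weight rank aggregation. Methods are ranked per metric
# (higher rank = better, maximum rank for ties, failures ranked last), then
# ranks are averaged up an equal-weight hierarchy: metrics within a
# sub-category, sub-categories within a major category, major categories
# into the overall accuracy score.

#' Default metric hierarchy
#'
#' The four-category tree: Global {COR, EMD}; Local {KNN, NPE}; Downstream
#' {ClusterReconstruction {Silhouette, DBI, CHI, RF}, ClusterConcordance
#' {ARI, NMI}, CellTypeConcordance {ARI, NMI}}; scRNA {ClusterDistance,
#' EMD, Gating {ARI, NMI}}. A metric without a named sub-category forms its
#' own singleton sub-category, which makes the equal-weight rule uniform.
#'
#' @return data frame with columns `metric`, `major`, `sub`, `direction`.
#' @export
default_metric_tree <- function() {
  tree <- rbind(
    c("cor",                 "global",     NA,                       "higher_better"),
    c("emd",                 "global",     NA,                       "lower_better"),
    c("knn",                 "local",      NA,                       "higher_better"),
    c("npe",                 "local",      NA,                       "lower_better"),
    c("silhouette",          "downstream", "cluster_reconstruction", "higher_better"),
    c("dbi",                 "downstream", "cluster_reconstruction", "lower_better"),
    c("chi",                 "downstream", "cluster_reconstruction", "higher_better"),
    c("rf",                  "downstream", "cluster_reconstruction", "higher_better"),
    c("cc_ari",              "downstream", "cluster_concordance",    "higher_better"),
    c("cc_nmi",              "downstream", "cluster_concordance",    "higher_better"),
    c("ct_ari",              "downstream", "celltype_concordance",   "higher_better"),
    c("ct_nmi",              "downstream", "celltype_concordance",   "higher_better"),
    c("cluster_distance",    "scrna",      NA,                       "lower_better"),
    c("concordance_emd",     "scrna",      NA,                       "lower_better"),
    c("gating_ari",          "scrna",      "gating",                 "higher_better"),
    c("gating_nmi",          "scrna",      "gating",                 "higher_better"))
  data.frame(metric = tree[, 1L], major = tree[, 2L], sub = tree[, 3L],
             direction = tree[, 4L], stringsAsFactors = FALSE)
}

#' Construct a score table
#'
#' @param values methods x metrics numeric matrix with method row names and
#'   metric column names; `NA` marks a failed evaluation.
#' @param tree metric hierarchy as in [default_metric_tree()]; only rows for
#'   metrics present in `values` are kept.
#' @return object of class `score_table` with fields `values` and `tree`.
#' @export
score_table <- function(values, tree = default_metric_tree()) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values needs method row names and metric column names",
         call. = FALSE)
  missing <- setdiff(colnames(values), tree$metric)
  if (length(missing))
    stop("metrics absent from tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  tree <- tree[match(colnames(values), tree$metric), , drop = FALSE]
  structure(list(values = values, tree = tree), class = "score_table")
}

#' @export
print.score_table <- function(x, ...) {
  cat("Score table:", nrow(x$values), "methods x", ncol(x$values),
      "metrics (", sum(is.na(x$values)), "failures )\n")
  print(round(x$values, 4))
  invisible(x)
}

#' Rank methods on one metric
#'
#' Values are oriented so that better is larger, then ranked ascending with
#' the best method receiving rank K. Tied values all receive the maximum
#' rank of their tied block. Failures (`NA`) tie below every finite value,
#' so under the maximum-rank convention each failure receives rank equal to
#' the number of failures.
#'
#' @param values length-K numeric vector, `NA` for failures.
#' @param direction `"higher_better"` or `"lower_better"`.
#' @return length-K numeric rank vector (higher = better).
#' @export
rank_metric <- function(values, direction = c("higher_better", "lower_better")) {
  direction <- match.arg(direction)
  v <- as.numeric(values)
  if (direction == "lower_better") v <- -v
  v[is.na(v)] <- -Inf
  rank(v, ties.method = "max")
}

#' Aggregate a score table into hierarchical rank scores
#'
#' @param scores a `score_table`.
#' @return object of class `rank_table`: `ranks` (methods x metrics),
#'   `category_scores` (methods x sub- and major categories, sub columns
#'   prefixed `sub:`, major prefixed `major:`), `overall` (methods vector),
#'   `tree`.
#' @export
aggregate_scores <- function(scores) {
  stopifnot(inherits(scores, "score_table"))
  vals <- scores$values; tree <- scores$tree
  K <- nrow(vals)
  ranks <- vals
  for (j in seq_len(ncol(vals)))
    ranks[, j] <- rank_metric(vals[, j], tree$direction[j])
  # singleton sub-category for metrics without one
  sub <- ifelse(is.na(tree$sub), tree$metric, tree$sub)
  sub_key <- paste(tree$major, sub, sep = "/")
  sub_scores <- sapply(unique(sub_key), function(s)
    rowMeans(ranks[, sub_key == s, drop = FALSE]))
  if (K == 1L) sub_scores <- matrix(sub_scores, nrow = 1L,
                                    dimnames = list(rownames(vals),
                                                    unique(sub_key)))
  sub_major <- tree$major[match(colnames(sub_scores), sub_key)]
  major_scores <- sapply(unique(sub_major), function(mj)
    rowMeans(sub_scores[, sub_major == mj, drop = FALSE]))
  if (K == 1L) major_scores <- matrix(major_scores, nrow = 1L,
                                      dimnames = list(rownames(vals),
                                                      unique(sub_major)))
  overall <- rowMeans(major_scores)
  cs <- cbind(sub_scores, major_scores)
  colnames(cs) <- c(paste0("sub:", colnames(sub_scores)),
                    paste0("major:", colnames(major_scores)))
  structure(list(ranks = ranks, category_scores = cs, overall = overall,
                 tree = tree), class = "rank_table")
}

#' @export
print.rank_table <- function(x, ...) {
  cat("Rank table (higher = better):\n")
  ord <- order(-x$overall)
  out <- data.frame(overall = round(x$overall[ord], 3))
  mj <- x$category_scores[, grepl("^major:", colnames(x$category_scores)),
                          drop = FALSE]
  out <- cbind(out, round(mj[ord, , drop = FALSE], 3))
  print(out)
  invisible(x)
}

#' Complementarity of top-performing methods across datasets
#'
#' Given the top-ranked method of each dataset, greedily orders candidate
#' methods so that each added method maximizes the fraction of datasets
#' whose top performer is already covered; ties are broken lexicographically
#' by method name. The first element is the method most often on top; the
#' cumulative coverage is non-decreasing.
#'
#' @param top_method_per_dataset character vector: the top performer of
#'   each dataset.
#' @param candidate_methods candidate pool; defaults to the methods seen.
#' @return data frame with columns `method` and `coverage` (cumulative
#'   fraction of datasets covered).
#' @export
complementarity <- function(top_method_per_dataset,
                            candidate_methods = NULL) {
  tops <- as.character(top_method_per_dataset)
  stopifnot(length(tops) >= 1L)
  cands <- sort(unique(candidate_methods %||% tops))
  chosen <- character(0); coverage <- numeric(0)
  covered <- rep(FALSE, length(tops))
  while (length(setdiff(cands, chosen))) {
    remaining <- sort(setdiff(cands, chosen))
    gain <- vapply(remaining, function(m)
      mean(covered | tops == m), numeric(1L))
    best <- remaining[which.max(gain)]   # which.max takes first = lexicographic
    chosen <- c(chosen, best)
    covered <- covered | tops == best
    coverage <- c(coverage, mean(covered))
    if (all(covered)) break
  }
  data.frame(method = chosen, coverage = coverage, row.names = NULL)
}
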