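# End-to-end driver: embed a sample with every requested DR method, score
# each embedding with all applicable metric categories, and aggregate the
# ranks. One failing method never aborts the run: its row becomes NA and it
# is ranked last.

#' Run a dimension-reduction benchmark
#'
#' @param X numeric matrix (cells x markers), the original-space data
#'   (typically already arcsinh-transformed).
#' @param methods character vector of registered DR method names, or a
#'   named list of parameter lists (names = methods).
#' @param labels original-space cluster labels; if `NULL`, the original
#'   space is clustered with [cluster_embedding()] using `n_clusters_hint`.
#' @param cell_types cell-type labels; defaults to `labels`.
#' @param rna optional matched second-modality matrix (cells x features,
#'   its own cell count); enables the scRNA-seq concordance category.
#' @param rna_types cell-type labels for `rna` rows (required with `rna`).
#' @param k neighborhood size for the local metrics; default 100.
#' @param n_clusters_hint target cluster count for embedding-space
#'   clustering; defaults to the number of distinct `labels`.
#' @param clustering embedding-space clustering algorithm
#'   (see [cluster_embedding()]).
#' @param neighbor_mode passed to [build_neighbors()].
#' @param seed master seed; all stage and method seeds derive from it via
#'   [child_seed()], so adding a method never perturbs the others.
#' @param out_dir optional directory; when given, scores, ranks, embeddings
#'   and a key=value run log are written there.
#' @return object of class `dr_benchmark`: `scores` (a `score_table`),
#'   `ranks` (a `rank_table`), `results` (per-method `dr_result`),
#'   `embedding_clusters`, and the inputs' summary.
#' @export
run_benchmark <- function(X, methods, labels = NULL, cell_types = NULL,
                          rna = NULL, rna_types = NULL, k = 100,
                          n_clusters_hint = NULL,
                          clustering = c("som_meta", "kmeans"),
                          neighbor_mode = "auto", seed = 0L,
                          out_dir = NULL) {
  clustering <- match.arg(clustering)
  check_matrix(X, "X")
  if (is.character(methods))
    methods <- stats::setNames(rep(list(list()), length(methods)), methods)
  if (!length(methods)) stop("at least one method required", call. = FALSE)
  if (!is.null(rna) && is.null(rna_types))
    stop("rna_types required with rna", call. = FALSE)
  log_lines <- character(0)
  log_add <- function(...) {
    line <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " ",
                   paste(..., sep = " "))
    log_lines <<- c(log_lines, line)
  }
  log_add("stage=start", paste0("n_cells=", nrow(X)),
          paste0("n_markers=", ncol(X)), paste0("seed=", seed))

  if (is.null(labels)) {
    hint <- n_clusters_hint %||% 8L
    labels <- cluster_embedding(X, hint, algorithm = clustering,
                                seed = child_seed(seed, "cluster:orig"))
    log_add("stage=orig_clustering", paste0("hint=", hint))
  }
  check_labels(labels, nrow(X))
  cell_types <- cell_types %||% labels
  hint <- n_clusters_hint %||% length(unique(labels))

  pcd_orig <- compute_pcd(X, labels)
  nb_orig <- build_neighbors(X, k = k, mode = neighbor_mode,
                             seed = child_seed(seed, "nb:orig"))
  log_add("stage=orig_structures", paste0("k=", nb_orig$k))

  has_rna <- !is.null(rna)
  common_types <- if (has_rna)
    sort(intersect(unique(as.character(cell_types)),
                   unique(as.character(rna_types)))) else character(0)
  use_rna <- has_rna && length(common_types) >= 2L

  metric_names <- c("cor", "emd", "knn", "npe", "silhouette", "dbi", "chi",
                    "rf", "cc_ari", "cc_nmi", "ct_ari", "ct_nmi")
  if (use_rna)
    metric_names <- c(metric_names, "cluster_distance", "concordance_emd",
                      "gating_ari", "gating_nmi")
  vals <- matrix(NA_real_, length(methods), length(metric_names),
                 dimnames = list(names(methods), metric_names))
  results <- vector("list", length(methods))
  names(results) <- names(methods)
  emb_clusters <- vector("list", length(methods))
  names(emb_clusters) <- names(methods)

  for (mn in names(methods)) {
    res <- run_dr(mn, X, params = methods[[mn]],
                  seed = child_seed(seed, paste0("dr:", mn)))
    results[[mn]] <- res
    if (res$status != "ok") {
      log_add("stage=dr", paste0("method=", mn), "status=error",
              paste0("message=", gsub("\\s+", "_", res$message)))
      next
    }
    log_add("stage=dr", paste0("method=", mn), "status=ok")
    E <- res$embedding
    row <- safe_metrics(E, X, labels, cell_types, pcd_orig, nb_orig, k,
                        hint, clustering, neighbor_mode,
                        rna, rna_types, common_types, use_rna,
                        seed = child_seed(seed, paste0("metrics:", mn)))
    emb_clusters[[mn]] <- attr(row, "clusters")
    vals[mn, names(row)] <- row
    log_add("stage=metrics", paste0("method=", mn))
  }
  if (all(vapply(results, function(r) r$status != "ok", logical(1L))))
    stop("no method produced an embedding", call. = FALSE)

  st <- score_table(vals)
  rt <- aggregate_scores(st)
  bench <- structure(list(scores = st, ranks = rt, results = results,
                          embedding_clusters = emb_clusters,
                          labels = labels, cell_types = cell_types,
                          k = nb_orig$k, seed = seed,
                          n_cells = nrow(X), n_markers = ncol(X)),
                     class = "dr_benchmark")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_scores(st, file.path(out_dir, "scores.tsv"))
    write_scores(rt, file.path(out_dir, "ranks.tsv"))
    for (mn in names(results)) {
      if (results[[mn]]$status == "ok")
        write_expression(results[[mn]]$embedding,
                         file.path(out_dir, paste0("embedding_", mn, ".csv")))
    }
    log_add("stage=done")
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }
  bench
}

# score one embedding; individual metric failures become NA, never errors
safe_metrics <- function(E, X, labels, cell_types, pcd_orig, nb_orig, k,
                         hint, clustering, neighbor_mode, rna, rna_types,
                         common_types, use_rna, seed) {
  try_na <- function(expr) tryCatch(expr, error = function(e) NA_real_)
  out <- c(cor = NA_real_)
  pcd_emb <- try(compute_pcd(E, labels), silent = TRUE)
  if (!inherits(pcd_emb, "try-error")) {
    out["cor"] <- try_na(global_spearman(pcd_orig, pcd_emb))
    out["emd"] <- try_na(global_emd(pcd_orig, pcd_emb))
  }
  nb_emb <- try(build_neighbors(E, k = k, mode = neighbor_mode,
                                seed = child_seed(seed, "nb")), silent = TRUE)
  if (!inherits(nb_emb, "try-error")) {
    out["knn"] <- try_na(knn_score(nb_orig, nb_emb))
    out["npe"] <- try_na(npe(nb_orig, nb_emb, labels))
  }
  out["silhouette"] <- try_na(silhouette_score(E, labels))
  out["dbi"] <- try_na(davies_bouldin(E, labels))
  out["chi"] <- try_na(calinski_harabasz(E, labels))
  out["rf"] <- try_na(rf_cluster_prediction(E, labels,
                                            seed = child_seed(seed, "rf")))
  clusters <- tryCatch(
    cluster_embedding(E, hint, algorithm = clustering,
                      seed = child_seed(seed, "cluster")),
    error = function(e) NULL)
  if (!is.null(clusters)) {
    out["cc_ari"] <- try_na(ari(labels, clusters))
    out["cc_nmi"] <- try_na(nmi(labels, clusters))
    out["ct_ari"] <- try_na(ari(cell_types, clusters))
    out["ct_nmi"] <- try_na(nmi(cell_types, clusters))
  }
  if (use_rna) {
    # embedding-space cell types: majority cell type per embedding cluster
    emb_types <- if (!is.null(clusters)) {
      tab <- table(clusters, as.character(cell_types))
      maj <- colnames(tab)[max.col(tab, ties.method = "first")]
      maj[match(clusters, rownames(tab))]
    } else NULL
    if (!is.null(emb_types)) {
      # a weak embedding may lose rare types; score on the types it retains
      present <- sort(intersect(common_types, unique(emb_types)))
      if (length(present) >= 2L) {
        out["cluster_distance"] <- try_na(cluster_distance(
          rank_distance_centroids(E, emb_types, present),
          rank_distance_centroids(rna, rna_types, present)))
        out["concordance_emd"] <- try_na(
          concordance_emd(E, emb_types, rna, rna_types, present))
      }
      out["gating_ari"] <- try_na(ari(cell_types, emb_types))
      out["gating_nmi"] <- try_na(nmi(cell_types, emb_types))
    }
  }
  attr(out, "clusters") <- clusters
  out
}

#' @export
print.dr_benchmark <- function(x, ...) {
  cat("DR benchmark:", x$n_cells, "cells x", x$n_markers, "markers;",
      length(x$results), "methods; k =", x$k, "\n")
  ok <- vapply(x$results, function(r) r$status == "ok", logical(1L))
  if (any(!ok)) cat("  failed:", paste(names(ok)[!ok], collapse = ", "), "\n")
  print(x$ranks)
  invisible(x)
}

#' @export
summary.dr_benchmark <- function(object, ...) {
  cat("Raw metric values:\n")
  print(object$scores)
  cat("\n")
  print(object$ranks)
  invisible(object)
}

#' Plot benchmark embeddings colored by original-space cluster
#'
#' @param x a `dr_benchmark`.
#' @param methods which methods to draw; default all successful ones.
#' @param ... passed to [graphics::plot()].
#' @export
plot.dr_benchmark <- function(x, methods = NULL, ...) {
  ok <- names(Filter(function(r) r$status == "ok", x$results))
  methods <- methods %||% ok
  methods <- intersect(methods, ok)
  if (!length(methods)) stop("no successful embeddings to plot", call. = FALSE)
  old <- graphics::par(mfrow = c(1, length(methods)), mar = c(3, 3, 2, 1))
  on.exit(graphics::par(old))
  cols <- as.integer(factor(x$labels))
  for (mn in methods) {
    E <- x$results[[mn]]$embedding
    graphics::plot(E, col = cols, pch = 16, cex = 0.4, main = mn,
                   xlab = "", ylab = "", ...)
  }
  invisible(x)
}

#' Generate benchmark fixture files on disk
#'
#' Wraps the simulator to produce small, documented test inputs:
#' `"blobs"` (childless Gaussian mixture), `"trajectory"` (types joined by
#' differentiation paths; pseudotime file included), and `"two_modality"`
#' (a jittered copy with shared cell types, exercising the concordance
#' metrics; jitter 0 makes the second modality an exact copy).
#'
#' @param kind `"blobs"`, `"trajectory"`, or `"two_modality"`.
#' @param dir output directory (created if needed).
#' @param n_cells number of cells; default 3000.
#' @param n_types number of cell types; default 3.
#' @param n_markers number of markers; default 10.
#' @param jitter SD of the Gaussian jitter for the second modality.
#' @param seed integer seed.
#' @return named character vector of written file paths, invisibly.
#' @export
make_fixture <- function(kind = c("blobs", "trajectory", "two_modality"),
                         dir = tempdir(), n_cells = 3000L, n_types = 3L,
                         n_markers = 10L, jitter = 0.1, seed = 0L) {
  kind <- match.arg(kind)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n_trees <- if (kind == "blobs") n_types else max(1L, n_types %/% 2L)
  model <- default_model(n_types, n_markers, n_trees = n_trees,
                         seed = child_seed(seed, "fixture:model"))
  samp <- simulate_cytof(model, n_cells,
                         seed = child_seed(seed, "fixture:sample"))
  prefix <- file.path(dir, kind)
  paths <- write_sample(samp, prefix)
  names(paths) <- c("expression", "cell_types", "pseudotime")
  if (kind == "two_modality") {
    rna <- samp$expression + if (jitter > 0)
      with_seed(child_seed(seed, "fixture:jitter"),
                matrix(stats::rnorm(length(samp$expression), 0, jitter),
                       nrow(samp$expression))) else 0
    p2 <- paste0(prefix, "_modality2.csv")
    write_expression(rna, p2)
    paths <- c(paths, modality2 = p2)
  }
  invisible(paths)
}
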