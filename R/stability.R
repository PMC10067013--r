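# Bootstrap stability of a DR method: how much the distribution of
# point-cluster distances in the embedding moves when the method is re-run
# on bootstrap resamples of the same sample.

#' Bootstrap stability of a dimension-reduction method
#'
#' A reference embedding is computed on the full sample. For each of `b`
#' bootstrap resamples (size N, with replacement) the method is re-run with
#' the same tuning parameters, the point-cluster distances of the bootstrap
#' embedding are computed (each resampled cell keeps the original-space
#' cluster label of its source cell), and the Earth Mover's Distance between
#' the min-max-normalized flattened PCD vectors of the reference and the
#' bootstrap embedding is recorded. The per-iteration distances are
#' averaged; smaller means more stable. A failure on a bootstrap iteration
#' is recorded and excluded from the mean; a failure on the reference is an
#' error.
#'
#' @param X numeric matrix (cells x markers).
#' @param labels original-space cluster labels.
#' @param method registered DR method name.
#' @param b number of bootstrap iterations; default 100.
#' @param params named list of back-end parameters (held fixed).
#' @param seed integer master seed; one child seed per iteration.
#' @return object of class `stability_result`: `per_bootstrap_emd`
#'   (length = completed iterations), `mean_emd`, `b` (completed
#'   iterations), `failures` (failed iteration count), `method`.
#' @export
bootstrap_stability <- function(X, labels, method, b = 100L,
                                params = list(), seed = NULL) {
  check_matrix(X, "X")
  check_labels(labels, nrow(X))
  seed <- seed %||% 0L
  ref <- run_dr(method, X, params, seed = child_seed(seed, "stability:ref"))
  if (ref$status != "ok")
    stop("reference embedding failed for ", method, ": ", ref$message,
         call. = FALSE)
  p_ref <- minmax(as.vector(compute_pcd(ref$embedding, labels)$dists))
  n <- nrow(X)
  emds <- numeric(0)
  failures <- 0L
  for (i in seq_len(b)) {
    it_seed <- child_seed(seed, paste0("stability:boot:", i))
    idx <- with_seed(it_seed, sample.int(n, n, replace = TRUE))
    res <- run_dr(method, X[idx, , drop = FALSE], params,
                  seed = child_seed(it_seed, "dr"))
    if (res$status != "ok") { failures <- failures + 1L; next }
    q <- minmax(as.vector(compute_pcd(res$embedding, labels[idx])$dists))
    emds <- c(emds, wasserstein1d(p_ref, q))
  }
  structure(list(per_bootstrap_emd = emds,
                 mean_emd = if (length(emds)) mean(emds) else NA_real_,
                 b = length(emds), failures = failures, method = method),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat("Bootstrap stability [", x$method, "]: mean EMD ",
      signif(x$mean_emd, 4), " over ", x$b, " iterations",
      if (x$failures) paste0(" (", x$failures, " failed)") else "", "\n",
      sep = "")
  invisible(x)
}
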