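# Registry of dimension-reduction adapters. Every adapter reduces a
# cells x markers matrix to a cells x 2 embedding behind a uniform
# interface; back-end exceptions are captured as failed results so a
# benchmark run never aborts because one method aborts. Adapters that
# support out-of-sample mapping can be run under the subsample-fit-then-map
# policy for large samples.

.dr_registry <- new.env(parent = emptyenv())

#' Register a dimension-reduction adapter
#'
#' @param name method name (registry key).
#' @param fit function `(X, params, seed)` returning either a cells x 2
#'   matrix, or a list with elements `embedding` (cells x 2 matrix) and
#'   optionally `map` (function mapping a new matrix to 2-D coordinates).
#' @param supports_mapping whether `fit` returns a usable `map` function.
#' @param overwrite replace an existing registration.
#' @return `name`, invisibly.
#' @export
register_dr_method <- function(name, fit, supports_mapping = FALSE,
                               overwrite = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fit))
  if (!overwrite && !is.null(.dr_registry[[name]]))
    stop("method already registered: ", name, call. = FALSE)
  assign(name, list(fit = fit, supports_mapping = supports_mapping),
         envir = .dr_registry)
  invisible(name)
}

#' List registered dimension-reduction methods
#'
#' @return data frame with columns `method` and `supports_mapping`.
#' @export
list_dr_methods <- function() {
  nms <- sort(ls(.dr_registry))
  data.frame(method = nms,
             supports_mapping = vapply(nms, function(n)
               .dr_registry[[n]]$supports_mapping, logical(1L)),
             row.names = NULL)
}

get_dr_method <- function(name) {
  m <- .dr_registry[[name]]
  if (is.null(m)) stop("unregistered DR method: ", name, call. = FALSE)
  m
}

dr_result <- function(method_name, embedding = NULL, message = "") {
  structure(list(method_name = method_name,
                 status = if (is.null(embedding)) "error" else "ok",
                 embedding = embedding, message = message),
            class = "dr_result")
}

#' @export
print.dr_result <- function(x, ...) {
  if (x$status == "ok") {
    cat("DR result [", x$method_name, "]: ", nrow(x$embedding),
        " x ", ncol(x$embedding), " embedding\n", sep = "")
  } else {
    cat("DR result [", x$method_name, "]: FAILED (", x$message, ")\n",
        sep = "")
  }
  invisible(x)
}

#' Run a registered dimension-reduction method
#'
#' Any exception raised by the back-end is captured and returned as a
#' failed result rather than propagated, so callers can rank failures last.
#'
#' @param method_name registered method name.
#' @param X numeric matrix (cells x markers).
#' @param params named list of back-end parameters.
#' @param seed integer seed or `NULL`.
#' @return object of class `dr_result` with fields `method_name`, `status`
#'   (`"ok"`/`"error"`), `embedding` (cells x 2 matrix or `NULL`), and
#'   `message`.
#' @export
run_dr <- function(method_name, X, params = list(), seed = NULL) {
  m <- get_dr_method(method_name)
  check_matrix(X, "X")
  res <- tryCatch({
    fit <- with_seed(seed, m$fit(X, params, seed))
    emb <- if (is.list(fit)) fit$embedding else fit
    emb <- as.matrix(emb)
    if (nrow(emb) != nrow(X) || ncol(emb) != 2L || !all(is.finite(emb)))
      stop("back-end returned an invalid embedding")
    colnames(emb) <- c("dim1", "dim2")
    dr_result(method_name, embedding = emb)
  }, error = function(e) dr_result(method_name, message = conditionMessage(e)))
  res
}

#' Subsample, fit, then map the remaining cells
#'
#' Fits the method on `floor(fraction * N)` cells sampled without
#' replacement, then maps all remaining cells onto the fitted embedding via
#' the adapter's mapping function. The returned embedding covers all N
#' cells in the original row order. With `fraction = 1` this is equivalent
#' to [run_dr()] on the full data.
#'
#' @param method_name registered method name; must support mapping.
#' @param X numeric matrix (cells x markers).
#' @param fraction training fraction in `(0, 1]`; default 0.1.
#' @param params named list of back-end parameters.
#' @param seed integer seed or `NULL`.
#' @return object of class `dr_result`.
#' @export
subsample_fit_map <- function(method_name, X, fraction = 0.1,
                              params = list(), seed = NULL) {
  m <- get_dr_method(method_name)
  check_matrix(X, "X")
  if (fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]", call. = FALSE)
  if (fraction == 1) return(run_dr(method_name, X, params, seed))
  if (!m$supports_mapping)
    stop("method has no mapping capability: ", method_name, call. = FALSE)
  n <- nrow(X)
  n_train <- max(2L, floor(fraction * n))
  tryCatch({
    with_seed(seed, {
      train <- sample.int(n, n_train, replace = FALSE)
      fit <- m$fit(X[train, , drop = FALSE], params, seed)
      if (!is.list(fit) || is.null(fit$map))
        stop("adapter did not return a mapping function")
      emb <- matrix(NA_real_, n, 2L)
      emb[train, ] <- as.matrix(fit$embedding)
      rest <- setdiff(seq_len(n), train)
      if (length(rest))
        emb[rest, ] <- as.matrix(fit$map(X[rest, , drop = FALSE]))
      if (!all(is.finite(emb))) stop("mapping produced non-finite values")
      colnames(emb) <- c("dim1", "dim2")
      dr_result(method_name, embedding = emb)
    })
  }, error = function(e) dr_result(method_name, message = conditionMessage(e)))
}

# ---- bundled adapters ------------------------------------------------------

# symmetric FastICA with logcosh contrast; whitening via SVD
fastica_2d <- function(X, maxit = 200L, tol = 1e-6) {
  Xc <- scale(X, center = TRUE, scale = FALSE)
  sv <- svd(Xc, nu = 0, nv = min(ncol(X), 10L))
  keep <- sv$d > 1e-10
  K <- sv$v[, keep, drop = FALSE] %*% diag(1 / sv$d[keep] * sqrt(nrow(X)),
                                           sum(keep))
  Z <- Xc %*% K                       # whitened, n x r
  r <- ncol(Z)
  if (r < 2L) stop("rank < 2: cannot extract 2 independent components")
  W <- matrix(stats::rnorm(2L * r), 2L, r)
  sym_decor <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- sym_decor(W)
  for (it in seq_len(maxit)) {
    WX <- Z %*% t(W)                  # n x 2
    G <- tanh(WX)
    Gp <- 1 - G^2
    W1 <- t(G) %*% Z / nrow(Z) - diag(colMeans(Gp), 2L) %*% W
    W1 <- sym_decor(W1)
    if (max(abs(abs(rowSums(W1 * W)) - 1)) < tol) { W <- W1; break }
    W <- W1
  }
  Z %*% t(W)
}

# rank-2 NMF by multiplicative updates on the column-min-shifted matrix;
# the 2-D embedding is the cell coefficient matrix W
nmf_2d <- function(X, maxit = 200L) {
  V <- sweep(X, 2L, apply(X, 2L, min))   # shift to non-negative
  n <- nrow(V); m <- ncol(V)
  W <- matrix(stats::runif(n * 2L, 0.1, 1), n, 2L)
  H <- matrix(stats::runif(2L * m, 0.1, 1), 2L, m)
  eps <- 1e-9
  for (it in seq_len(maxit)) {
    H <- H * (t(W) %*% V) / (t(W) %*% W %*% H + eps)
    W <- W * (V %*% t(H)) / (W %*% H %*% t(H) + eps)
  }
  W
}

# spectral embedding from a symmetrized kNN graph (normalized Laplacian)
spectral_2d <- function(X, k = 15L) {
  n <- nrow(X)
  k <- min(k, n - 1L)
  nn <- FNN::get.knn(X, k = k)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) A[i, nn$nn.index[i, ]] <- 1
  A <- pmax(A, t(A))
  d <- rowSums(A)
  d[d == 0] <- 1
  Dn <- 1 / sqrt(d)
  L <- diag(n) - (Dn * A) * rep(Dn, each = n)
  ev <- eigen(L, symmetric = TRUE)
  ev$vectors[, c(n - 1L, n - 2L), drop = FALSE]
}

register_builtin_methods <- function() {
  register_dr_method("pca", function(X, params, seed) {
    p <- stats::prcomp(X, rank. = 2L, center = TRUE, scale. = FALSE)
    list(embedding = p$x[, 1:2, drop = FALSE],
         map = function(newX) stats::predict(p, newX)[, 1:2, drop = FALSE])
  }, supports_mapping = TRUE, overwrite = TRUE)

  register_dr_method("ica", function(X, params, seed) {
    fastica_2d(X, maxit = params$maxit %||% 200L)
  }, overwrite = TRUE)

  register_dr_method("fa", function(X, params, seed) {
    f <- stats::factanal(X, factors = 2L, scores = "regression")
    unclass(f$scores)
  }, overwrite = TRUE)

  register_dr_method("nmf", function(X, params, seed) {
    nmf_2d(X, maxit = params$maxit %||% 200L)
  }, overwrite = TRUE)

  register_dr_method("tsne", function(X, params, seed) {
    perp <- params$perplexity %||% min(30, max(2, floor((nrow(X) - 1) / 3)))
    Rtsne::Rtsne(X, dims = 2L, perplexity = perp, check_duplicates = FALSE,
                 pca = TRUE, verbose = FALSE)$Y
  }, overwrite = TRUE)

  register_dr_method("umap", function(X, params, seed) {
    nn <- params$n_neighbors %||% min(15L, nrow(X) - 1L)
    fit <- uwot::umap(X, n_components = 2L, n_neighbors = nn,
                      ret_model = TRUE, n_threads = 1L)
    list(embedding = fit$embedding,
         map = function(newX) uwot::umap_transform(newX, fit,
                                                   n_threads = 1L))
  }, supports_mapping = TRUE, overwrite = TRUE)

  register_dr_method("kpca", function(X, params, seed) {
    sig <- params$sigma %||% 0.1
    kp <- kernlab::kpca(X, kernel = "rbfdot", kpar = list(sigma = sig),
                        features = 2L)
    kernlab::rotated(kp)
  }, overwrite = TRUE)

  register_dr_method("isomap", function(X, params, seed) {
    k <- params$k %||% 10L
    D <- stats::dist(X)
    # grow k until the neighborhood graph is connected
    for (kk in unique(pmin(c(k, 2L * k, 4L * k, nrow(X) - 1L), nrow(X) - 1L))) {
      fit <- tryCatch(vegan::isomap(D, ndim = 2L, k = kk),
                      error = function(e) NULL)
      if (!is.null(fit)) return(fit$points[, 1:2, drop = FALSE])
    }
    stop("isomap graph disconnected at all tried k")
  }, overwrite = TRUE)

  register_dr_method("spectral", function(X, params, seed) {
    spectral_2d(X, k = params$k %||% 15L)
  }, overwrite = TRUE)

  # baselines: random Gaussian projection, and the same with rows shuffled
  # (destroys cell correspondence; a floor for every metric)
  register_dr_method("random_proj", function(X, params, seed) {
    R <- matrix(stats::rnorm(ncol(X) * 2L), ncol(X), 2L)
    X %*% R
  }, overwrite = TRUE)

  register_dr_method("random_shuffle", function(X, params, seed) {
    R <- matrix(stats::rnorm(ncol(X) * 2L), ncol(X), 2L)
    (X %*% R)[sample.int(nrow(X)), , drop = FALSE]
  }, overwrite = TRUE)

  invisible(NULL)
}

.onLoad <- function(libname, pkgname) {
  register_builtin_methods()
}
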