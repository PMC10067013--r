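# Probabilistic CyTOF simulator. Cells are drawn from a categorical mixture
# of P cell types on the arcsinh scale; each type p has marker means mu[p,]
# and SDs sigma[p,], a null-marker set on which mu = sigma = 0, and
# optionally children in a differentiation forest. A differentiating cell
# moves toward a uniformly chosen child along a path g with g(0) = 0 and
# g(1) = mu_child - mu_parent, evaluated at a Beta(0.4, 1) pseudotime drawn
# per marker. Measurement noise is additive Gaussian.

#' Construct a CyTOF simulation model
#'
#' @param pi length-P probability vector of cell-type frequencies.
#' @param mu P x M matrix of arcsinh-scale marker means per type.
#' @param sigma P x M non-negative matrix of marker SDs per type.
#' @param null_sets list of length P; integer marker indices not expressed by
#'   each type. `mu` and `sigma` are forced to 0 on these markers.
#' @param children list of length P; integer indices of each type's children
#'   in the differentiation forest (empty vector for terminal types). The
#'   relation must be a forest: at most one parent per type, no cycles.
#' @param noise_sd non-negative SD of the additive measurement noise.
#' @param path_kind differentiation path realization: `"linear"` (straight
#'   interpolation) or `"bridge"` (linear plus a Brownian-bridge perturbation
#'   pinned to 0 at both ends).
#' @param bridge_sd scale of the bridge perturbation (ignored for linear).
#' @param shared_pseudotime if `TRUE`, one pseudotime per cell is shared by
#'   all markers; default `FALSE` draws pseudotime per marker per cell.
#' @param beta_shape1,beta_shape2 shape parameters of the pseudotime Beta
#'   distribution; defaults 0.4 and 1.
#' @return an object of class `cytomulate_model`.
#' @export
cytomulate_model <- function(pi, mu, sigma, null_sets = NULL, children = NULL,
                             noise_sd = 0.2, path_kind = c("linear", "bridge"),
                             bridge_sd = 0.1, shared_pseudotime = FALSE,
                             beta_shape1 = 0.4, beta_shape2 = 1) {
  path_kind <- match.arg(path_kind)
  mu <- as.matrix(mu); sigma <- as.matrix(sigma)
  P <- length(pi); M <- ncol(mu)
  if (is.null(null_sets)) null_sets <- rep(list(integer(0)), P)
  if (is.null(children)) children <- rep(list(integer(0)), P)
  for (p in seq_len(P)) {
    mu[p, null_sets[[p]]] <- 0
    sigma[p, null_sets[[p]]] <- 0
  }
  model <- structure(list(pi = as.numeric(pi), mu = mu, sigma = sigma,
                          null_sets = lapply(null_sets, as.integer),
                          children = lapply(children, as.integer),
                          noise_sd = noise_sd, path_kind = path_kind,
                          bridge_sd = bridge_sd,
                          shared_pseudotime = isTRUE(shared_pseudotime),
                          beta_shape1 = beta_shape1,
                          beta_shape2 = beta_shape2),
                     class = "cytomulate_model")
  validate_model(model)
  model
}

#' Validate a simulation model's invariants
#'
#' Checks that `pi` is a probability vector, dimensions agree, null-set
#' markers have zero mean and SD, and the child relation is a forest.
#'
#' @param model a `cytomulate_model`.
#' @return the model, invisibly; errors on violation.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "cytomulate_model"))
  pi <- model$pi; P <- length(pi); M <- ncol(model$mu)
  if (any(pi < 0) || abs(sum(pi) - 1) > 1e-12)
    stop("pi must be non-negative and sum to 1", call. = FALSE)
  if (!all(dim(model$mu) == c(P, M)) || !all(dim(model$sigma) == c(P, M)))
    stop("mu and sigma must be P x M", call. = FALSE)
  if (any(model$sigma < 0)) stop("sigma must be non-negative", call. = FALSE)
  if (model$noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  if (length(model$null_sets) != P || length(model$children) != P)
    stop("null_sets and children must have length P", call. = FALSE)
  for (p in seq_len(P)) {
    A <- model$null_sets[[p]]
    if (length(A) && (any(A < 1) || any(A > M)))
      stop("null_sets indices out of range", call. = FALSE)
    if (length(A) && (any(model$mu[p, A] != 0) || any(model$sigma[p, A] != 0)))
      stop("null-set markers must have mu = sigma = 0", call. = FALSE)
  }
  parent <- rep(NA_integer_, P)
  for (p in seq_len(P)) for (ch in model$children[[p]]) {
    if (ch < 1 || ch > P) stop("child index out of range", call. = FALSE)
    if (!is.na(parent[ch]))
      stop("type ", ch, " has more than one parent", call. = FALSE)
    parent[ch] <- p
  }
  for (p in seq_len(P)) {  # no type reachable from itself
    seen <- integer(0); q <- p
    while (!is.na(parent[q])) {
      q <- parent[q]
      if (q == p || q %in% seen)
        stop("children relation contains a cycle", call. = FALSE)
      seen <- c(seen, q)
    }
  }
  invisible(model)
}

#' @export
print.cytomulate_model <- function(x, ...) {
  P <- length(x$pi); M <- ncol(x$mu)
  roots <- sum(vapply(seq_len(P), function(p)
    !any(vapply(x$children, function(ch) p %in% ch, logical(1L))),
    logical(1L)))
  cat("CyTOF simulation model:", P, "cell types,", M, "markers,",
      roots, "differentiation tree(s)\n")
  cat("  type frequencies:", paste(signif(x$pi, 3), collapse = " "), "\n")
  cat("  noise sd:", x$noise_sd, " path:", x$path_kind,
      " pseudotime: Beta(", x$beta_shape1, ",", x$beta_shape2, ")\n")
  invisible(x)
}

#' Draw cell types from the model's categorical prior
#'
#' @param model a `cytomulate_model`.
#' @param n_cells number of cells.
#' @param seed integer seed or `NULL`.
#' @return integer vector of type indices in `1..P`.
#' @export
sample_cell_types <- function(model, n_cells, seed = NULL) {
  validate_model(model)
  stopifnot(n_cells >= 1)
  with_seed(seed,
            sample.int(length(model$pi), n_cells, replace = TRUE,
                       prob = model$pi))
}

#' Draw pseudotime values
#'
#' The differentiation progress coordinate of a cell along a parent-to-child
#' path, distributed Beta(0.4, 1) by default: most cells sit near the parent
#' state with a long tail toward the child.
#'
#' @param n number of draws.
#' @param shape1,shape2 Beta shape parameters.
#' @param seed integer seed or `NULL`.
#' @return numeric vector in `[0, 1]`.
#' @export
sample_pseudotime <- function(n, shape1 = 0.4, shape2 = 1, seed = NULL) {
  with_seed(seed, stats::rbeta(n, shape1, shape2))
}

#' Realize a differentiation path
#'
#' Returns a continuous function `g` on `[0, 1]` with `g(0) = 0` and
#' `g(1) = delta_mu`. The linear kind is the straight interpolation
#' `g(t) = t * delta_mu`; the bridge kind adds a Brownian-bridge perturbation
#' (scale `bridge_sd`), realized on a 101-point grid and linearly
#' interpolated, so both endpoints remain exact.
#'
#' @param delta_mu target end value (child mean minus parent mean).
#' @param path_kind `"linear"` or `"bridge"`.
#' @param bridge_sd bridge scale; 0 degenerates to the linear path.
#' @param seed integer seed or `NULL` (bridge only).
#' @return function mapping `[0,1]` vectors to numeric vectors.
#' @export
differentiation_path <- function(delta_mu, path_kind = c("linear", "bridge"),
                                 bridge_sd = 0.1, seed = NULL) {
  path_kind <- match.arg(path_kind)
  if (path_kind == "linear")
    return(function(t) t * delta_mu)
  grid <- seq(0, 1, length.out = 101L)
  inc <- with_seed(seed, stats::rnorm(100L, 0, bridge_sd * sqrt(diff(grid))))
  w <- c(0, cumsum(inc))
  bridge <- w - grid * w[101L]              # pinned to 0 at both ends
  vals <- grid * delta_mu + bridge
  f <- stats::approxfun(grid, vals, rule = 2)
  function(t) f(t)
}

#' Simulate a CyTOF sample
#'
#' Draws `n_cells` cells: a type from the categorical prior, a uniformly
#' chosen child target for types with children, per-marker Gaussian base
#' expression, per-marker Beta pseudotime, the differentiation-path
#' contribution toward the child, and additive Gaussian noise.
#'
#' @param model a `cytomulate_model`.
#' @param n_cells number of cells.
#' @param seed integer seed or `NULL`; identical seeds give identical samples.
#' @return list of class `cytomulate_sample`: `expression` (cells x markers
#'   matrix), `cell_types` (integer vector), `child_targets` (integer vector,
#'   `NA` for terminal cells), `pseudotimes` (cells x markers matrix).
#' @export
simulate_cytof <- function(model, n_cells, seed = NULL) {
  validate_model(model)
  stopifnot(n_cells >= 1)
  with_seed(seed, {
    P <- length(model$pi); M <- ncol(model$mu)
    types <- sample.int(P, n_cells, replace = TRUE, prob = model$pi)
    child <- rep(NA_integer_, n_cells)
    for (p in seq_len(P)) {
      ch <- model$children[[p]]
      idx <- which(types == p)
      if (length(ch) && length(idx))
        child[idx] <- ch[sample.int(length(ch), length(idx), replace = TRUE)]
    }
    tmat <- if (model$shared_pseudotime) {
      matrix(stats::rbeta(n_cells, model$beta_shape1, model$beta_shape2),
             n_cells, M)
    } else {
      matrix(stats::rbeta(n_cells * M, model$beta_shape1, model$beta_shape2),
             n_cells, M)
    }
    Y <- model$mu[types, , drop = FALSE] +
      matrix(stats::rnorm(n_cells * M), n_cells, M) *
        model$sigma[types, , drop = FALSE]
    # one path realization per (parent, child, marker) edge, shared by cells
    edges <- unique(stats::na.omit(cbind(types, child)))
    if (nrow(edges)) {
      for (e in seq_len(nrow(edges))) {
        p <- edges[e, 1L]; pc <- edges[e, 2L]
        idx <- which(types == p & child == pc)
        for (m in seq_len(M)) {
          g <- differentiation_path(model$mu[pc, m] - model$mu[p, m],
                                    model$path_kind, model$bridge_sd)
          Y[idx, m] <- Y[idx, m] + g(tmat[idx, m])
        }
      }
    }
    if (model$noise_sd > 0)
      Y <- Y + matrix(stats::rnorm(n_cells * M, 0, model$noise_sd),
                      n_cells, M)
    colnames(Y) <- colnames(model$mu) %||% paste0("marker", seq_len(M))
    structure(list(expression = Y, cell_types = types,
                   child_targets = child, pseudotimes = tmat),
              class = "cytomulate_sample")
  })
}

#' @rdname simulate_cytof
#' @param object a `cytomulate_model` (for the [stats::simulate()] generic).
#' @param nsim number of cells to simulate.
#' @param ... unused.
#' @export
simulate.cytomulate_model <- function(object, nsim = 1000, seed = NULL, ...) {
  simulate_cytof(object, n_cells = nsim, seed = seed)
}

#' @export
print.cytomulate_sample <- function(x, ...) {
  cat("Simulated CyTOF sample:", nrow(x$expression), "cells x",
      ncol(x$expression), "markers;",
      length(unique(x$cell_types)), "cell types observed\n")
  invisible(x)
}

#' Build a randomized default simulation model
#'
#' Fixture factory for simulation sweeps: `n_types` cell types arranged into
#' `n_trees` differentiation trees, cell-type frequencies drawn from a flat
#' Dirichlet, marker means from Normal(3, 1) truncated at 0, SDs from
#' Uniform(0.1, 0.5), and a random null-marker set per type.
#'
#' @param n_types number of cell types (P).
#' @param n_markers number of protein markers (M).
#' @param n_trees number of differentiation trees (forest roots),
#'   `1 <= n_trees <= n_types`.
#' @param seed integer seed or `NULL`.
#' @param null_fraction fraction of markers in each type's null set.
#' @param noise_sd measurement noise SD.
#' @return a valid `cytomulate_model`.
#' @export
default_model <- function(n_types, n_markers, n_trees = 1, seed = NULL,
                          null_fraction = 0.3, noise_sd = 0.2) {
  stopifnot(n_trees >= 1, n_trees <= n_types, n_markers >= 1)
  with_seed(seed, {
    P <- n_types; M <- n_markers
    pi <- stats::rgamma(P, 1); pi <- pi / sum(pi)
    mu <- matrix(0, P, M)
    for (p in seq_len(P)) for (m in seq_len(M)) {
      repeat { v <- stats::rnorm(1, 3, 1); if (v >= 0) break }
      mu[p, m] <- v
    }
    sigma <- matrix(stats::runif(P * M, 0.1, 0.5), P, M)
    colnames(mu) <- colnames(sigma) <- paste0("marker", seq_len(M))
    n_null <- floor(null_fraction * M)
    null_sets <- lapply(seq_len(P), function(p)
      if (n_null) sort(sample.int(M, n_null)) else integer(0))
    children <- rep(list(integer(0)), P)
    if (P > n_trees) {
      for (p in seq.int(n_trees + 1L, P)) {
        parent <- sample.int(p - 1L, 1L)
        children[[parent]] <- c(children[[parent]], p)
      }
    }
    cytomulate_model(pi = pi, mu = mu, sigma = sigma, null_sets = null_sets,
                     children = children, noise_sd = noise_sd)
  })
}

#' Write a simulated sample to CSV files
#'
#' Writes `<prefix>_expression.csv`, `<prefix>_cell_types.csv` and
#' `<prefix>_pseudotime.csv`.
#'
#' @param sample a `cytomulate_sample`.
#' @param prefix output path prefix.
#' @return character vector of written paths, invisibly.
#' @export
write_sample <- function(sample, prefix) {
  stopifnot(inherits(sample, "cytomulate_sample"))
  paths <- paste0(prefix, c("_expression.csv", "_cell_types.csv",
                            "_pseudotime.csv"))
  write_expression(sample$expression, paths[1L])
  utils::write.table(data.frame(cell_type = sample$cell_types), paths[2L],
                     sep = ",", quote = FALSE, row.names = FALSE)
  utils::write.table(sample$pseudotimes, paths[3L], sep = ",", quote = FALSE,
                     row.names = FALSE,
                     col.names = colnames(sample$expression))
  invisible(paths)
}
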