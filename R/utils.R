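#' @keywords internal
"_PACKAGE"

#' Evaluate code with a temporary RNG seed
#'
#' Sets the R random number generator to `seed`, evaluates `code`, and
#' restores the previous RNG state so callers never observe a side effect.
#' A `NULL` seed evaluates `code` with the current RNG stream untouched.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Derive a child seed from a master seed and a stage label
#'
#' Deterministic, platform-independent derivation so that adding a method to
#' a benchmark does not perturb the seeds of other methods or stages.
#' Uses a polynomial rolling hash of the label folded with the master seed,
#' reduced modulo 2^31 - 1.
#'
#' @param seed master integer seed.
#' @param label character stage label, e.g. `"dr:pca"`.
#' @return a single integer in `[0, 2^31 - 2]`.
#' @export
child_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  m <- 2147483647
  h <- 0
  for (ch in utf8ToInt(paste(label, collapse = ":"))) {
    h <- (h * 31 + ch) %% m
  }
  as.integer((abs(seed) %% m + h * 48271) %% m)
}

#' Min-max normalize a numeric vector
#'
#' Rescales to `[0, 1]`. A constant (or length-1) vector maps to all zeros,
#' so two constant vectors compare as identical distributions.
#'
#' @param x numeric vector, all finite.
#' @return numeric vector in `[0, 1]`.
#' @export
minmax <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 1L, all(is.finite(x)))
  r <- range(x)
  if (r[1] == r[2]) return(rep(0, length(x)))
  (x - r[1]) / (r[2] - r[1])
}

#' One-dimensional Wasserstein (Earth Mover's) distance
#'
#' Distance between the empirical distributions of two samples, computed as
#' the integral of the absolute difference between their empirical CDFs.
#' Sample sizes may differ; observations are equally weighted within each
#' sample.
#'
#' @param x,y numeric vectors of observations (finite, non-empty).
#' @return non-negative scalar; 0 iff the empirical distributions coincide.
#' @export
wasserstein1d <- function(x, y) {
  stopifnot(length(x) >= 1L, length(y) >= 1L,
            all(is.finite(x)), all(is.finite(y)))
  g <- sort(unique(c(x, y)))
  if (length(g) == 1L) return(0)
  Fx <- stats::ecdf(x)(g)
  Fy <- stats::ecdf(y)(g)
  k <- length(g)
  sum(abs(Fx[-k] - Fy[-k]) * diff(g))
}

# internal: validate a cells x markers / cells x 2 numeric matrix
check_matrix <- function(X, what = "matrix") {
  if (!is.matrix(X) || !is.numeric(X))
    stop(what, " must be a numeric matrix", call. = FALSE)
  if (!all(is.finite(X)))
    stop(what, " contains non-finite values", call. = FALSE)
  invisible(X)
}

# internal: validate labels against a matrix
check_labels <- function(labels, n) {
  if (length(labels) != n)
    stop("labels length (", length(labels),
         ") does not match number of cells (", n, ")", call. = FALSE)
  invisible(labels)
}
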