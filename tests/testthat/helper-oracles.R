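# Independent brute-force implementations used as oracles. These are coded
# from the metric definitions with naive loops and must stay independent of
# the package's code paths.

# Spearman correlation: rank transform then explicit Pearson formula
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# 1-D Wasserstein distance via the quantile-function integral
oracle_emd1d <- function(x, y) {
  xs <- sort(x); ys <- sort(y)
  n <- length(xs); m <- length(ys)
  u <- sort(unique(c(seq_len(n) / n, seq_len(m) / m)))
  lo <- c(0, u[-length(u)])
  total <- 0
  for (i in seq_along(u)) {
    qx <- xs[ceiling(u[i] * n - 1e-12)]
    qy <- ys[ceiling(u[i] * m - 1e-12)]
    total <- total + abs(qx - qy) * (u[i] - lo[i])
  }
  total
}

oracle_minmax <- function(v) {
  if (max(v) == min(v)) rep(0, length(v)) else (v - min(v)) / (max(v) - min(v))
}

# exact kNN index sets by full pairwise distances, lowest-index tie-break
oracle_knn_sets <- function(X, k) {
  n <- nrow(X)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    d <- numeric(n)
    for (j in seq_len(n)) d[j] <- sqrt(sum((X[i, ] - X[j, ])^2))
    d[i] <- Inf
    out[[i]] <- order(d, seq_len(n))[seq_len(k)]
  }
  out
}

oracle_knn_score <- function(X, E, k) {
  a <- oracle_knn_sets(X, k); b <- oracle_knn_sets(E, k)
  mean(vapply(seq_along(a), function(i)
    length(intersect(a[[i]], b[[i]])) / k, numeric(1)))
}

oracle_bw <- function(x) {
  s <- sd(x); iqr <- IQR(x)
  b <- 1.06 * min(s, iqr / 1.34) * length(x)^(-1 / 5)
  if (b <= 0) b <- 1.06 * s * length(x)^(-1 / 5)
  b
}

oracle_kde <- function(x, grid, bw) {
  sapply(grid, function(g) mean(dnorm((g - x) / bw)) / bw)
}

# NPE from raw inputs, following the five printed steps with loops
oracle_npe <- function(X, E, labels, k, grid_size = 1024) {
  n <- nrow(X)
  nbo <- oracle_knn_sets(X, k); nbe <- oracle_knn_sets(E, k)
  po <- pe <- numeric(n)
  for (i in seq_len(n)) {
    po[i] <- sum(labels[nbo[[i]]] == labels[i]) / k
    pe[i] <- sum(labels[nbe[[i]]] == labels[i]) / k
  }
  grid <- seq(0, 1, length.out = grid_size)
  tvs <- c()
  for (cl in sort(unique(labels))) {
    xo <- po[labels == cl]; xe <- pe[labels == cl]
    if (length(xo) < 2 || var(xo) == 0 || var(xe) == 0) next
    P <- oracle_kde(xo, grid, oracle_bw(xo))
    Q <- oracle_kde(xe, grid, oracle_bw(xe))
    tvs <- c(tvs, max(abs(P - Q)))
  }
  if (!length(tvs)) NA_real_ else mean(tvs)
}

# ARI by explicit pair counting
oracle_ari <- function(a, b) {
  n <- length(a)
  n11 <- n10 <- n01 <- n00 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) n11 <- n11 + 1
    else if (sa && !sb) n10 <- n10 + 1
    else if (!sa && sb) n01 <- n01 + 1
    else n00 <- n00 + 1
  }
  2 * (n11 * n00 - n10 * n01) /
    ((n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00))
}

# NMI with explicit loops over the contingency table
oracle_nmi <- function(a, b) {
  n <- length(a)
  ua <- unique(a); ub <- unique(b)
  mi <- 0; ha <- 0; hb <- 0
  for (x in ua) {
    px <- sum(a == x) / n
    ha <- ha - px * log(px)
    for (y in ub) {
      pxy <- sum(a == x & b == y) / n
      py <- sum(b == y) / n
      if (pxy > 0) mi <- mi + pxy * log(pxy / (px * py))
    }
  }
  for (y in ub) { py <- sum(b == y) / n; hb <- hb - py * log(py) }
  if (ha == 0 || hb == 0) return(0)
  mi / ((ha + hb) / 2)
}

oracle_silhouette <- function(E, labels) {
  n <- nrow(E)
  D <- as.matrix(dist(E))
  s <- numeric(n)
  for (i in seq_len(n)) {
    same <- which(labels == labels[i]); same <- setdiff(same, i)
    if (!length(same)) { s[i] <- 0; next }
    a <- mean(D[i, same])
    b <- min(sapply(setdiff(unique(labels), labels[i]), function(cl)
      mean(D[i, labels == cl])))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

oracle_dbi <- function(E, labels) {
  ids <- sort(unique(labels)); k <- length(ids)
  cent <- t(sapply(ids, function(cl) colMeans(E[labels == cl, , drop = FALSE])))
  S <- sapply(seq_len(k), function(i) {
    rows <- E[labels == ids[i], , drop = FALSE]
    mean(apply(rows, 1, function(r) sqrt(sum((r - cent[i, ])^2))))
  })
  r <- numeric(k)
  for (i in seq_len(k)) {
    best <- -Inf
    for (j in seq_len(k)) if (j != i) {
      m <- sqrt(sum((cent[i, ] - cent[j, ])^2))
      best <- max(best, (S[i] + S[j]) / m)
    }
    r[i] <- best
  }
  mean(r)
}

oracle_chi <- function(E, labels) {
  ids <- sort(unique(labels)); k <- length(ids); n <- nrow(E)
  g <- colMeans(E)
  B <- 0; W <- 0
  for (cl in ids) {
    rows <- E[labels == cl, , drop = FALSE]
    c_ <- colMeans(rows)
    B <- B + nrow(rows) * sum((c_ - g)^2)
    W <- W + sum(apply(rows, 1, function(r) sum((r - c_)^2)))
  }
  (B / (k - 1)) / (W / (n - k))
}

# normalized centroid-distance ranks, coded with explicit sorting
oracle_rank_distance <- function(data, types, common) {
  cent <- t(sapply(common, function(cl)
    colMeans(data[types == cl, , drop = FALSE])))
  T_ <- length(common)
  vals <- c(); pairs <- NULL
  for (a in seq_len(T_)) {
    others <- setdiff(seq_len(T_), a)
    d <- sapply(others, function(x) sqrt(sum((cent[a, ] - cent[x, ])^2)))
    for (j in seq_along(others)) {
      rk <- sum(d < d[j]) + sum(d[seq_len(j)] == d[j])  # lowest-index ties
      vals <- c(vals, rk / T_)
      pairs <- rbind(pairs, c(common[a], common[others[j]]))
    }
  }
  list(values = vals, pairs = pairs)
}

oracle_concordance_pool <- function(data, types, common) {
  keep <- types %in% common
  X <- data[keep, , drop = FALSE]; tt <- types[keep]
  n <- nrow(X)
  out <- c()
  for (a in common) {
    ca <- colMeans(X[tt == a, , drop = FALSE])
    d <- apply(X, 1, function(r) sqrt(sum((r - ca)^2)))
    o <- order(d, seq_len(n))
    rk <- integer(n); rk[o] <- seq_len(n)
    for (b in setdiff(common, a)) out <- c(out, rk[tt == b] / n)
  }
  out
}

oracle_concordance_emd <- function(cy, cyt, rn, rnt, common) {
  oracle_emd1d(oracle_concordance_pool(cy, cyt, common),
               oracle_concordance_pool(rn, rnt, common))
}
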