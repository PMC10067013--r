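# Small deterministic fixtures built in code at test time.

# Gaussian blobs: n cells per blob around given centers (rows), sd spread
make_blobs <- function(centers, n_per = 30, sd = 0.5, seed = 1) {
  centers <- as.matrix(centers)
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    matrix(rnorm(n_per * ncol(centers), 0, sd), n_per) +
      matrix(centers[i, ], n_per, ncol(centers), byrow = TRUE)))
  colnames(X) <- paste0("m", seq_len(ncol(centers)))
  list(X = X, labels = rep(seq_len(nrow(centers)), each = n_per))
}

# a childless mixture model with well-separated means
blob_model <- function(P = 3, M = 5, sep = 4, noise_sd = 0.2) {
  mu <- matrix(0, P, M)
  for (p in seq_len(P)) mu[p, ] <- sep * p + seq_len(M) / M
  cytomulate_model(pi = rep(1 / P, P), mu = mu,
                   sigma = matrix(0.5, P, M), noise_sd = noise_sd)
}
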