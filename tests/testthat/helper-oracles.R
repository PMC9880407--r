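# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: spectra via an explicit DFT matrix (no fft),
# spectral filtering via the eigendecomposition closed form.

# Windowed, averaged cross-periodogram by direct DFT (one-sided density).
oracle_welch_cross <- function(x, y, fs, window_len = round(fs),
                               overlap = 0.5) {
  step <- max(1, round(window_len * (1 - overlap)))
  starts <- seq(1, length(x) - window_len + 1, by = step)
  j <- 0:(window_len - 1)
  w <- 0.5 * (1 - cos(2 * pi * j / window_len))
  nf <- floor(window_len / 2) + 1
  E <- exp(-2i * pi * outer(0:(nf - 1), j) / window_len)  # DFT matrix
  acc <- rep(0 + 0i, nf)
  pxx <- pyy <- rep(0, nf)
  for (s in starts) {
    xs <- x[s:(s + window_len - 1)]
    ys <- y[s:(s + window_len - 1)]
    X <- E %*% ((xs - mean(xs)) * w)
    Y <- E %*% ((ys - mean(ys)) * w)
    acc <- acc + Conj(X[, 1]) * Y[, 1]
    pxx <- pxx + Mod(X[, 1])^2
    pyy <- pyy + Mod(Y[, 1])^2
  }
  L <- length(starts)
  sided <- rep(2, nf); sided[1] <- 1
  if (window_len %% 2 == 0) sided[nf] <- 1
  list(frequencies = (0:(nf - 1)) * fs / window_len,
       Pxy = acc / L / (fs * sum(w^2)) * sided,
       msc = ifelse(pxx * pyy > 0, Mod(acc)^2 / (pxx * pyy), 0))
}

# Chebyshev polynomial values T_k(lambda) by scalar three-term recursion.
oracle_cheb_scalar <- function(lambda, K) {
  out <- matrix(0, length(lambda), K)
  out[, 1] <- 1
  if (K >= 2) out[, 2] <- lambda
  if (K >= 3) for (k in 3:K)
    out[, k] <- 2 * lambda * out[, k - 1] - out[, k - 2]
  out
}

# Spectral-domain filtering y = U diag(sum_k theta_k T_k(lambda)) U^T x.
oracle_spectral_filter <- function(x, theta, L_tilde) {
  e <- eigen((L_tilde + t(L_tilde)) / 2, symmetric = TRUE)
  Tk <- oracle_cheb_scalar(e$values, length(theta))
  f <- as.vector(Tk %*% theta)
  y <- e$vectors %*% (f * (t(e$vectors) %*%
                             (if (is.matrix(x)) x else matrix(x))))
  if (is.matrix(x)) y else as.vector(y)
}

# Random connected coherence-like graph: symmetric weights in (0, 1),
# zero diagonal.
random_coherence_graph <- function(n, seed) {
  set.seed(seed)
  A <- matrix(runif(n * n, 0.02, 0.9), n, n)
  A <- (A + t(A)) / 2
  diag(A) <- 0
  eeg_graph(A)
}

# Small simulated dataset shared by model-level tests.
small_dataset <- function(n_per_class = 15, snr = 2, seed = 42) {
  make_dataset(sim_config(n_trials_per_class = n_per_class,
                          coupling_snr = snr, seed = seed))
}
# Small handle on the network internals for direct forward/backward tests.
tiny_net <- function(n = 5, K = 3, filters = c(3, 4), f0 = 6, B = 4,
                     seed = 1, l2 = 0.001) {
  g <- random_coherence_graph(n, seed)
  cfg <- cgcn_config(K = K, filters = filters, l2_lambda = l2, seed = seed)
  hier <- coarsen_graph(g, levels = length(filters))
  laps <- lapply(hier$graphs[seq_along(filters)], function(gl) {
    Ln <- laplacian_normalized(gl)
    scale_laplacian(Ln, lambda_max(Ln))
  })
  n_nodes <- vapply(hier$graphs, function(x) length(x$node_names),
                    integer(1))
  set.seed(seed + 1)
  params <- cgcn:::init_params(cfg, n_nodes, f0)
  X <- array(rnorm(n * f0 * B), dim = c(n, f0, B))
  labels <- rep(c(1, 2), length.out = B)
  P <- matrix(0, 2, B)
  P[cbind(labels, seq_len(B))] <- 1
  list(cfg = cfg, hier = hier, laps = laps, params = params, X = X, P = P,
       l2 = l2)
}

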