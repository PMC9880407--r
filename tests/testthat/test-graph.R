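test_that("neighborhood equals a brute-force row scan", {
  g <- random_coherence_graph(21, seed = 1)
  # sparsify so some weights are exactly zero
  A <- g$adjacency
  A[A < 0.3] <- 0
  A <- (A + t(A)) / 2
  g <- eeg_graph(A)
  for (v in c(1, 7, 21))
    expect_identical(neighborhood(g, v),
                     g$node_names[which(g$adjacency[v, ] > 0)])
  # isolated node and complete graph
  iso <- eeg_graph(matrix(0, 3, 3), c("a", "b", "c"))
  expect_length(neighborhood(iso, "a"), 0)
  comp <- eeg_graph(matrix(1, 3, 3) - diag(3), c("a", "b", "c"))
  expect_identical(neighborhood(comp, "b"), c("a", "c"))
  expect_error(neighborhood(comp, "zz"), "unknown node")
})

test_that("combinatorial Laplacian has zero row sums and PSD spectrum", {
  for (seed in 1:5) {
    g <- random_coherence_graph(12, seed)
    L <- laplacian_combinatorial(g)
    expect_lt(max(abs(rowSums(L))), 1e-10)
    expect_equal(L, t(L))
    expect_gt(min(eigen(L, symmetric = TRUE, only.values = TRUE)$values),
              -1e-10)
  }
  # two nodes with weight w
  g2 <- eeg_graph(matrix(c(0, 2.5, 2.5, 0), 2), c("a", "b"))
  expect_equal(laplacian_combinatorial(g2),
               matrix(c(2.5, -2.5, -2.5, 2.5), 2,
                      dimnames = list(c("a", "b"), c("a", "b"))))
  # empty graph
  expect_equal(laplacian_combinatorial(eeg_graph(matrix(0, 3, 3))),
               matrix(0, 3, 3, dimnames = list(paste0("v", 1:3),
                                               paste0("v", 1:3))))
})

test_that("normalized Laplacian spectrum lies in [0, 2]", {
  # weight cancels for a two-node graph
  g2 <- eeg_graph(matrix(c(0, 7, 7, 0), 2))
  expect_equal(unname(laplacian_normalized(g2)),
               matrix(c(1, -1, -1, 1), 2))
  # complete unweighted graph: eigenvalues {0, n/(n-1) repeated}
  n <- 6
  gc <- eeg_graph(matrix(1, n, n) - diag(n))
  ev <- sort(eigen(laplacian_normalized(gc), symmetric = TRUE,
                   only.values = TRUE)$values)
  expect_equal(ev, c(0, rep(n / (n - 1), n - 1)), tolerance = 1e-10)
  for (seed in 1:5) {
    g <- random_coherence_graph(21, seed + 50)
    ev <- eigen(laplacian_normalized(g), symmetric = TRUE,
                only.values = TRUE)$values
    expect_gt(min(ev), -1e-9)
    expect_lt(max(ev), 2 + 1e-9)
  }
  # zero-degree node convention: isolated node keeps diagonal 1
  A <- matrix(0, 3, 3); A[1, 2] <- A[2, 1] <- 1
  Ln <- laplacian_normalized(eeg_graph(A))
  expect_equal(unname(Ln[3, ]), c(0, 0, 1))
})

test_that("eigendecomposition reconstructs and is orthonormal", {
  set.seed(7)
  M <- matrix(rnorm(21 * 21), 21)
  L <- (M + t(M)) / 2
  e <- eigendecompose(L)
  expect_lt(max(abs(e$U %*% diag(e$lambda) %*% t(e$U) - L)), 1e-8)
  expect_lt(max(abs(crossprod(e$U) - diag(21))), 1e-10)
  expect_true(!is.unsorted(e$lambda))
  # identity input
  expect_equal(eigendecompose(diag(4))$lambda, rep(1, 4))
  # deterministic sign convention
  e2 <- eigendecompose(L)
  expect_identical(e$U, e2$U)
  expect_error(eigendecompose(matrix(1:9, 3)), "symmetric")
})

test_that("Laplacian rescaling maps the spectrum into [-1, 1]", {
  g <- random_coherence_graph(15, seed = 3)
  Ln <- laplacian_normalized(g)
  lmax <- lambda_max(Ln)
  expect_equal(lmax, max(eigen(Ln, symmetric = TRUE,
                               only.values = TRUE)$values),
               tolerance = 1e-9)
  Lt <- scale_laplacian(Ln, lmax)
  evn <- sort(eigen(Ln, symmetric = TRUE, only.values = TRUE)$values)
  evt <- sort(eigen(Lt, symmetric = TRUE, only.values = TRUE)$values)
  expect_equal(evt, 2 * evn / lmax - 1, tolerance = 1e-9)
  expect_gt(min(evt), -1 - 1e-9)
  expect_lt(max(evt), 1 + 1e-9)
  # lmax = 2 shortcut and degenerate guard
  expect_equal(scale_laplacian(Ln, 2), Ln - diag(15))
  expect_equal(scale_laplacian(matrix(0, 2, 2), 1), -diag(2))
  expect_error(scale_laplacian(Ln, 0), "positive")
})

test_that("Chebyshev basis matches its recursion anchors", {
  g <- random_coherence_graph(10, seed = 4)
  lb <- laplacian_bundle(g)
  set.seed(5)
  x <- matrix(rnorm(10 * 3), 10)
  b <- cheb_basis(lb$L_tilde, x, 4)
  expect_equal(b[[1]], x)                      # T0 = identity
  expect_equal(b[[2]], lb$L_tilde %*% x)       # T1 = L~
  expect_equal(b[[4]],
               2 * lb$L_tilde %*% b[[3]] - b[[2]])
  expect_equal(cheb_basis(-diag(10), x, 2)[[2]], -x)
  expect_error(cheb_basis(lb$L_tilde, matrix(0, 4, 2), 3), "nodes")
})

test_that("Chebyshev filtering equals the spectral-domain closed form", {
  set.seed(6)
  for (rep in 1:10) {
    g <- random_coherence_graph(21, seed = 600 + rep)
    lb <- laplacian_bundle(g)
    K <- sample(1:5, 1)
    theta <- rnorm(K)
    x <- rnorm(21)
    y <- spectral_filter(x, theta, lb$L_tilde)
    y_ref <- oracle_spectral_filter(x, theta, lb$L_tilde)
    expect_lt(max(abs(y - y_ref)) / max(abs(y_ref)), 1e-8)
  }
  # trivial coefficient vectors
  g <- random_coherence_graph(8, seed = 9)
  lb <- laplacian_bundle(g)
  x <- rnorm(8)
  expect_equal(spectral_filter(x, c(1, 0, 0), lb$L_tilde), x)
  expect_equal(spectral_filter(x, c(0, 1), lb$L_tilde),
               as.vector(lb$L_tilde %*% x))
})

test_that("spectral filtering is linear in the signal", {
  g <- random_coherence_graph(12, seed = 10)
  lb <- laplacian_bundle(g)
  set.seed(11)
  x1 <- rnorm(12); x2 <- rnorm(12)
  theta <- rnorm(4)
  lhs <- spectral_filter(3 * x1 - 2 * x2, theta, lb$L_tilde)
  rhs <- 3 * spectral_filter(x1, theta, lb$L_tilde) -
    2 * spectral_filter(x2, theta, lb$L_tilde)
  expect_lt(max(abs(lhs - rhs)) / max(abs(lhs)), 1e-10)
})

test_that("K-order filters are (K-1)-localized on a path graph", {
  n <- 12
  A <- matrix(0, n, n)
  for (i in 1:(n - 1)) A[i, i + 1] <- A[i + 1, i] <- 1
  base <- eeg_graph(A)
  K <- 3
  theta <- c(0.3, -0.5, 0.8)
  x <- c(1, rep(0, n - 1))   # impulse at node 1
  filt_at <- function(g) {
    Ln <- laplacian_normalized(g)
    # common rescaling so the perturbation test isolates locality
    spectral_filter(x, theta, scale_laplacian(Ln, 2))[1]
  }
  y0 <- filt_at(base)
  # perturbing an edge beyond graph distance K-1 from node 1 cannot change
  # the output at node 1
  A2 <- A
  A2[7, 8] <- A2[8, 7] <- 5
  expect_equal(filt_at(eeg_graph(A2)), y0, tolerance = 1e-12)
  # perturbing an edge within distance K-1 does
  A3 <- A
  A3[2, 3] <- A3[3, 2] <- 5
  expect_false(isTRUE(all.equal(filt_at(eeg_graph(A3)), y0)))
})
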