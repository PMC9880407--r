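#' Weighted undirected graph over electrodes
#'
#' @param adjacency Symmetric nonnegative matrix; the diagonal is zeroed
#'   (no self-loops).
#' @param node_names Optional node names (default dimnames).
#' @return An object of class `eeg_graph` with fields `adjacency` and
#'   `node_names`; edges are implicit (pairs with positive weight).
#' @export
eeg_graph <- function(adjacency, node_names = rownames(adjacency)) {
  A <- as.matrix(unclass(adjacency))
  stopifnot(nrow(A) == ncol(A))
  if (max(abs(A - t(A))) > 1e-10) stop("adjacency must be symmetric")
  if (min(A) < 0) stop("adjacency weights must be nonnegative")
  A <- (A + t(A)) / 2
  diag(A) <- 0
  if (is.null(node_names)) node_names <- paste0("v", seq_len(nrow(A)))
  dimnames(A) <- list(node_names, node_names)
  structure(list(adjacency = A, node_names = node_names),
            class = "eeg_graph")
}

#' @export
print.eeg_graph <- function(x, ...) {
  cat(sprintf("<eeg_graph> %d nodes, %d weighted edges\n",
              length(x$node_names), sum(x$adjacency[upper.tri(x$adjacency)] > 0)))
  invisible(x)
}

#' Neighborhood of a node
#'
#' @param g An [eeg_graph()].
#' @param v Node name or index.
#' @return Character vector of the nodes adjacent to `v` (positive weight).
#' @export
neighborhood <- function(g, v) {
  stopifnot(inherits(g, "eeg_graph"))
  if (is.character(v)) {
    if (!v %in% g$node_names) stop("unknown node '", v, "'")
    v <- match(v, g$node_names)
  } else if (v < 1 || v > length(g$node_names)) stop("node index out of range")
  g$node_names[g$adjacency[v, ] > 0]
}

#' Combinatorial graph Laplacian
#'
#' `L = D - A` with `D` the diagonal degree (row-sum) matrix.  Rows sum to
#' zero and the matrix is positive semidefinite.
#'
#' @param g An [eeg_graph()].
#' @return Symmetric n x n matrix.
#' @export
laplacian_combinatorial <- function(g) {
  stopifnot(inherits(g, "eeg_graph"))
  A <- g$adjacency
  diag(rowSums(A), nrow(A)) - A
}

#' Symmetric normalized graph Laplacian
#'
#' `L = I - D^(-1/2) A D^(-1/2)`; eigenvalues lie in [0, 2].  A
#' zero-degree node's `D^(-1/2)` entry is defined as 0, leaving that node
#' isolated with diagonal entry 1.
#'
#' @param g An [eeg_graph()].
#' @return Symmetric n x n matrix.
#' @export
laplacian_normalized <- function(g) {
  stopifnot(inherits(g, "eeg_graph"))
  A <- g$adjacency
  d <- rowSums(A)
  dinv <- ifelse(d > 0, 1 / sqrt(d), 0)
  L <- diag(nrow(A)) - (dinv %o% dinv) * A
  (L + t(L)) / 2
}

#' Eigendecomposition of a symmetric Laplacian
#'
#' Symmetric eigendecomposition `L = U diag(lambda) U^T` with eigenvalues
#' sorted ascending and each eigenvector's sign fixed so its
#' largest-magnitude component is positive (determinism).
#'
#' @param L Symmetric matrix.
#' @return List with `U` (orthonormal columns) and `lambda` (ascending).
#' @export
eigendecompose <- function(L) {
  if (max(abs(L - t(L))) > 1e-8) stop("matrix is not symmetric")
  e <- eigen((L + t(L)) / 2, symmetric = TRUE)
  ord <- order(e$values)
  U <- e$vectors[, ord, drop = FALSE]
  lambda <- e$values[ord]
  for (j in seq_len(ncol(U))) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) U[, j] <- -U[, j]
  }
  list(U = U, lambda = lambda)
}

#' Largest Laplacian eigenvalue
#'
#' Dense symmetric eigensolver for small graphs (n <= 64, where it is both
#' exact and cheap); power iteration beyond that (the normalized
#' Laplacian's spectrum is nonnegative, so the dominant eigenvalue in
#' magnitude is the largest one).
#'
#' @param L Symmetric positive semidefinite matrix.
#' @param tol Convergence tolerance on the eigenvalue (default 1e-6).
#' @param maxit Iteration cap (default 1000).
#' @return Scalar largest eigenvalue.
#' @export
lambda_max <- function(L, tol = 1e-6, maxit = 1000) {
  n <- nrow(L)
  if (n <= 64)                       # dense solver: exact at these sizes
    return(max(eigen((L + t(L)) / 2, symmetric = TRUE,
                     only.values = TRUE)$values))
  v <- seq_len(n) / sqrt(sum(seq_len(n)^2))
  lam <- 0
  for (it in seq_len(maxit)) {
    w <- L %*% v
    nw <- sqrt(sum(w^2))
    if (nw < 1e-300) break
    v_new <- as.vector(w / nw)
    lam_new <- as.numeric(crossprod(v_new, L %*% v_new))
    if (abs(lam_new - lam) < tol) return(lam_new)
    lam <- lam_new
    v <- v_new
  }
  lam
}

#' Rescale a Laplacian to the Chebyshev domain
#'
#' `L_tilde = 2 L / lambda_max - I`, mapping the spectrum into [-1, 1] so
#' Chebyshev polynomials are well conditioned on it.
#'
#' @param L Normalized Laplacian.
#' @param lmax Its largest eigenvalue (must be > 0).
#' @return Matrix with spectrum in [-1, 1].
#' @export
scale_laplacian <- function(L, lmax) {
  if (!is.numeric(lmax) || lmax <= 0) stop("lambda_max must be positive")
  2 * L / lmax - diag(nrow(L))
}

#' All Laplacian forms of a graph
#'
#' Convenience bundle: degree matrix, combinatorial and normalized
#' Laplacians, eigendecomposition of the normalized Laplacian, its largest
#' eigenvalue and the Chebyshev-rescaled form.
#'
#' @param g An [eeg_graph()].
#' @param approx_lmax Optional fixed value (e.g. 2) to use instead of the
#'   computed largest eigenvalue.
#' @return An object of class `laplacian_bundle`.
#' @export
laplacian_bundle <- function(g, approx_lmax = NULL) {
  stopifnot(inherits(g, "eeg_graph"))
  L_comb <- laplacian_combinatorial(g)
  L_norm <- laplacian_normalized(g)
  eig <- eigendecompose(L_norm)
  lmax <- if (is.null(approx_lmax)) lambda_max(L_norm) else approx_lmax
  structure(list(D = diag(rowSums(g$adjacency), nrow(g$adjacency)),
                 L_comb = L_comb, L_norm = L_norm,
                 U = eig$U, lambda = eig$lambda, lambda_max = lmax,
                 L_tilde = scale_laplacian(L_norm, lmax)),
            class = "laplacian_bundle")
}

#' Chebyshev polynomial basis applied to a graph signal
#'
#' Computes `[T_0(Lt) x, ..., T_{K-1}(Lt) x]` by the three-term recursion
#' `T_0 = I`, `T_1 = Lt`, `T_k = 2 Lt T_{k-1} - T_{k-2}` without forming
#' matrix powers.
#'
#' @param L_tilde Rescaled Laplacian (n x n).
#' @param x Graph signal: numeric vector of length n or n x f matrix.
#' @param K Number of Chebyshev terms (>= 1).
#' @return List of K signals, each the shape of `x`.
#' @export
cheb_basis <- function(L_tilde, x, K) {
  stopifnot(K >= 1)
  x <- if (is.matrix(x)) x else matrix(x, ncol = 1)
  if (nrow(x) != nrow(L_tilde))
    stop("signal has ", nrow(x), " rows but the graph has ",
         nrow(L_tilde), " nodes")
  out <- vector("list", K)
  out[[1]] <- x
  if (K >= 2) out[[2]] <- L_tilde %*% x
  if (K >= 3) for (k in 3:K)
    out[[k]] <- 2 * (L_tilde %*% out[[k - 1]]) - out[[k - 2]]
  out
}

#' Chebyshev spectral graph filtering
#'
#' `y = sum_k theta_k T_k(L_tilde) x`: a K-order polynomial spectral filter,
#' K-1-localized on the graph, linear in both the signal and the
#' coefficients.
#'
#' @param x Graph signal (vector or n x f matrix).
#' @param theta Numeric vector of K filter coefficients.
#' @param L_tilde Rescaled Laplacian.
#' @return Filtered signal, same shape as `x`.
#' @export
spectral_filter <- function(x, theta, L_tilde) {
  K <- length(theta)
  if (K < 1) stop("theta must have at least one coefficient")
  basis <- cheb_basis(L_tilde, x, K)
  y <- theta[1] * basis[[1]]
  if (K >= 2) for (k in 2:K) y <- y + theta[k] * basis[[k]]
  if (is.null(dim(x))) as.vector(y) else y
}
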