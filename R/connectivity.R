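#' Class- or group-level average coherence network
#'
#' Element-wise mean of per-trial coherence matrices for one class (or for
#' all trials of a group when `class = NULL`).
#'
#' @param trials A `trial_set`.
#' @param band A [frequency_band()].
#' @param class Class label to select, or `NULL` for all trials.
#' @param group Optional group label stored in the result (e.g. patient /
#'   control or a simulated condition).
#' @param window_len,overlap Welch parameters.
#' @return An object of class `network_map`: the mean `coherence_matrix`
#'   plus `group`, `class`, `band` and `n_trials`.
#' @export
group_network <- function(trials, band, class = NULL, group = NULL,
                          window_len = round(attr(trials, "fs")),
                          overlap = 0.5) {
  stopifnot(inherits(trials, "trial_set"))
  if (!is.null(class)) {
    keep <- trial_labels(trials) == class
    if (!any(keep)) stop("no trials with class '", class, "'")
    trials <- trials[keep]
  }
  mats <- trial_graph(trials, band, mode = "per_trial",
                      window_len = window_len, overlap = overlap)
  structure(list(matrix = average_coherence(mats, band), group = group,
                 class = class, band = band, n_trials = length(mats)),
            class = "network_map")
}

#' @export
print.network_map <- function(x, ...) {
  cat(sprintf("<network_map> band %s, class %s, group %s, %d trials\n",
              x$band$name, x$class %||% "all", x$group %||% "-",
              x$n_trials))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Threshold a network into an edge list
#'
#' Keeps either all edges with weight at or above an absolute cutoff, or
#' the strongest `ceiling(density * n_edges)` edges; ties are broken by
#' lexicographic (i, j) order so the result is deterministic.
#'
#' @param map A `network_map` (or a bare `coherence_matrix`).
#' @param tau Absolute threshold in [0, 1] (used when `density` is NULL).
#' @param density Fraction of the n(n-1)/2 edges to keep, in (0, 1].
#' @return A data.frame (class `edge_list`) with columns `node_i`,
#'   `node_j`, `weight` (i < j in node order) and a `threshold_rule`
#'   attribute describing the rule applied.
#' @export
threshold_edges <- function(map, tau = NULL, density = NULL) {
  W <- if (inherits(map, "network_map")) map$matrix else map
  W <- unclass(W)
  n <- nrow(W)
  nm <- rownames(W) %||% paste0("ch", seq_len(n))
  ij <- which(upper.tri(W), arr.ind = TRUE)
  edges <- data.frame(node_i = nm[ij[, 1]], node_j = nm[ij[, 2]],
                      weight = W[ij], i = ij[, 1], j = ij[, 2])
  edges <- edges[order(edges$i, edges$j), ]
  if (!is.null(density)) {
    if (density <= 0 || density > 1) stop("density must be in (0, 1]")
    k <- ceiling(density * nrow(edges))
    ord <- order(-edges$weight, edges$i, edges$j)
    edges <- edges[sort(ord[seq_len(k)]), ]
    rule <- sprintf("top-density %.3g (%d edges)", density, k)
  } else {
    if (is.null(tau)) stop("provide either tau or density")
    if (tau < 0 || tau > 1) stop("tau must be in [0, 1]")
    edges <- edges[edges$weight >= tau, ]
    rule <- sprintf("absolute threshold >= %.3g", tau)
  }
  rownames(edges) <- NULL
  structure(edges[, c("node_i", "node_j", "weight")],
            threshold_rule = rule, class = c("edge_list", "data.frame"))
}

#' Weighted node strength
#'
#' Connection density of each electrode, operationalized as the weighted
#' degree: the sum of a node's off-diagonal coherence weights.
#'
#' @param map A `network_map` or `coherence_matrix`.
#' @return Named numeric vector of node strengths.
#' @export
node_strength <- function(map) {
  W <- if (inherits(map, "network_map")) map$matrix else map
  W <- unclass(W)
  diag(W) <- 0
  rowSums(W)
}

#' Edge-wise contrast between two sets of coherence networks
#'
#' Element-wise mean difference between the networks of two conditions
#' (per-trial coherence matrices), with optional two-sided label-permutation
#' p-values per edge and Benjamini-Hochberg correction across edges.  This
#' statistical layer is an additive utility; the mean-difference map alone
#' reproduces a descriptive group comparison.
#'
#' @param mats_a,mats_b Lists of per-trial `coherence_matrix` objects for
#'   the two conditions (e.g. from [trial_graph()] with `mode =
#'   "per_trial"`); montages must match.
#' @param n_perm Number of label permutations (default 1000; 0 skips the
#'   test and returns the difference only).
#' @param seed Seed for the permutation draws.
#' @return An object of class `network_contrast`: `difference` (mean A -
#'   mean B), and when `n_perm > 0`, `p` and `p_adj` matrices.
#' @export
network_contrast <- function(mats_a, mats_b, n_perm = 1000, seed = 1L) {
  stopifnot(length(mats_a) >= 1, length(mats_b) >= 1)
  if (!identical(dimnames(mats_a[[1]]), dimnames(mats_b[[1]])))
    stop("montages of the two conditions do not match")
  na <- length(mats_a)
  nb <- length(mats_b)
  all_mats <- c(lapply(mats_a, unclass), lapply(mats_b, unclass))
  stk <- simplify2array(all_mats)          # n x n x (na+nb)
  mean_over <- function(idx) apply(stk[, , idx, drop = FALSE], c(1, 2), mean)
  diff_obs <- mean_over(seq_len(na)) - mean_over(na + seq_len(nb))
  out <- list(difference = diff_obs, n_a = na, n_b = nb)
  if (n_perm > 0) {
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(seed)
    exceed <- matrix(0, nrow(diff_obs), ncol(diff_obs))
    for (p in seq_len(n_perm)) {
      idx <- sample.int(na + nb)
      d <- mean_over(idx[seq_len(na)]) - mean_over(idx[na + seq_len(nb)])
      exceed <- exceed + (abs(d) >= abs(diff_obs))
    }
    pmat <- (exceed + 1) / (n_perm + 1)
    diag(pmat) <- NA
    ut <- upper.tri(pmat)
    padj <- pmat
    padj[ut] <- stats::p.adjust(pmat[ut], method = "BH")
    padj[lower.tri(padj)] <- t(padj)[lower.tri(padj)]
    dimnames(pmat) <- dimnames(padj) <- dimnames(diff_obs)
    out$p <- pmat
    out$p_adj <- padj
    out$n_perm <- n_perm
  }
  structure(out, class = "network_contrast")
}

#' @export
print.network_contrast <- function(x, ...) {
  cat(sprintf("<network_contrast> %d vs %d matrices; max |difference| %.4f\n",
              x$n_a, x$n_b, max(abs(x$difference), na.rm = TRUE)))
  if (!is.null(x$p_adj))
    cat(sprintf("  %d / %d edges with BH-adjusted p < 0.05 (%d permutations)\n",
                sum(x$p_adj[upper.tri(x$p_adj)] < 0.05, na.rm = TRUE),
                sum(upper.tri(x$p_adj)), x$n_perm))
  invisible(x)
}
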