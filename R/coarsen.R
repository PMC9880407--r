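#' Graph coarsening by greedy heavy-edge matching
#'
#' Builds a pooling hierarchy: at each level, unmatched nodes (visited in
#' index order) are paired with their heaviest-weight unmatched neighbor
#' (ties broken by lowest index); a node with no unmatched neighbor keeps a
#' zero-weight "fake" partner, i.e. it survives as a singleton supernode.
#' Coarse edge weights are the sums of the merged fine weights, so total
#' edge weight between supernode groups is conserved.
#'
#' @param g An [eeg_graph()].
#' @param levels Number of coarsening levels (>= 1).
#' @param pool_factor Nodes merged per pooling step; only pairwise
#'   matching (2) is supported.
#' @return An object of class `pool_hierarchy`: `graphs` (list of
#'   `levels + 1` graphs, finest first), `groups` (per level, a list
#'   mapping each coarse node to the fine node indices it merges) and
#'   `singleton` (per level, logical marker of fake-partner nodes).
#' @export
coarsen_graph <- function(g, levels, pool_factor = 2) {
  stopifnot(inherits(g, "eeg_graph"), levels >= 1)
  if (pool_factor != 2)
    stop("only pairwise pooling (pool_factor = 2) is implemented")
  graphs <- list(g)
  groups <- vector("list", levels)
  singleton <- vector("list", levels)
  for (l in seq_len(levels)) {
    fine <- graphs[[l]]
    m <- match_heavy_edges(fine$adjacency)
    groups[[l]] <- m
    singleton[[l]] <- lengths(m) == 1L
    A <- fine$adjacency
    nc <- length(m)
    Ac <- matrix(0, nc, nc)
    for (i in seq_len(nc)) for (j in seq_len(nc)) if (i != j)
      Ac[i, j] <- sum(A[m[[i]], m[[j]]])
    names_c <- vapply(m, function(idx)
      paste(fine$node_names[idx], collapse = "+"), character(1))
    graphs[[l + 1]] <- eeg_graph(Ac, names_c)
  }
  structure(list(graphs = graphs, groups = groups, singleton = singleton,
                 pool_factor = pool_factor),
            class = "pool_hierarchy")
}

# Greedy heavy-edge matching; returns a list of index vectors (pairs or
# singletons) ordered by their smallest member.
match_heavy_edges <- function(A) {
  n <- nrow(A)
  matched <- rep(FALSE, n)
  out <- list()
  for (v in seq_len(n)) {
    if (matched[v]) next
    w <- A[v, ]
    w[matched] <- -Inf
    w[v] <- -Inf
    if (all(w <= 0)) {            # no unmatched positive-weight neighbor
      out[[length(out) + 1L]] <- v
      matched[v] <- TRUE
    } else {
      u <- unname(which.max(w))   # ties -> lowest index
      out[[length(out) + 1L]] <- c(v, u)
      matched[c(v, u)] <- TRUE
    }
  }
  out
}

#' Graph max pooling
#'
#' Element-wise maximum of node features over each supernode's merged fine
#' nodes; a singleton (fake-partner) node passes its features through
#' unchanged.
#'
#' @param H Fine-level features: n_fine x f matrix (or vector).
#' @param hierarchy A `pool_hierarchy` from [coarsen_graph()].
#' @param level Which coarsening level to apply (1-based).
#' @return n_coarse x f matrix of pooled features.
#' @export
graph_max_pool <- function(H, hierarchy, level = 1) {
  stopifnot(inherits(hierarchy, "pool_hierarchy"))
  groups <- hierarchy$groups[[level]]
  H <- if (is.matrix(H)) H else matrix(H, ncol = 1)
  n_fine <- length(hierarchy$graphs[[level]]$node_names)
  if (nrow(H) != n_fine)
    stop("feature rows (", nrow(H), ") do not match level ", level,
         " node count (", n_fine, ")")
  out <- matrix(0, length(groups), ncol(H))
  for (i in seq_along(groups)) {
    idx <- groups[[i]]
    out[i, ] <- if (length(idx) == 1L) H[idx, ] else pmax(H[idx[1], ],
                                                          H[idx[2], ])
  }
  rownames(out) <- hierarchy$graphs[[level + 1]]$node_names
  out
}
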