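#' Weighted graph metrics for connectivity matrices
#'
#' All metrics operate on the full weighted matrix (no thresholding or
#' binarization). Path-based metrics use edge lengths `1/w`, the standard
#' convention for connectivity weights in \code{[0, 1]}; clustering uses the
#' Onnela geometric-mean form with weights normalized by the matrix maximum;
#' community structure is found by seeded multi-restart Louvain optimization
#' of Newman's weighted modularity with resolution parameter gamma, and
#' "nodal modularity" is the exact per-node decomposition of Q (it sums to Q).
#'
#' @name network-metrics
NULL

as_weight_matrix <- function(graph) {
  W <- if (inherits(graph, "connectivity_matrix")) graph$values else graph
  stopifnot(is.matrix(W), nrow(W) == ncol(W))
  if (any(!is.finite(W))) stop("weights must be finite")
  if (any(W < 0)) stop("weights must be non-negative")
  if (max(abs(W - t(W))) > 1e-12) stop("weight matrix must be symmetric")
  W <- (W + t(W)) / 2  # exact symmetry for igraph
  if (any(diag(W) != 0)) stop("diagonal must be zero")
  if (is.null(rownames(W))) {
    rownames(W) <- colnames(W) <- paste0("n", seq_len(nrow(W)))
  }
  W
}

# all-pairs shortest path lengths over edge lengths 1/w
shortest_lengths <- function(W) {
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE)
  if (igraph::ecount(g) == 0) {
    return(matrix(Inf, nrow(W), ncol(W)))
  }
  igraph::distances(g, weights = 1 / igraph::E(g)$weight)
}

#' Global efficiency of a weighted graph
#'
#' Mean inverse shortest-path length over all ordered node pairs;
#' disconnected pairs contribute 0. With weights in \code{[0, 1]} the result
#' lies in \code{[0, 1]}.
#'
#' @param graph symmetric non-negative weight matrix (zero diagonal), or a
#'   `connectivity_matrix`
#' @return global efficiency (unitless)
#' @export
global_efficiency <- function(graph) {
  W <- as_weight_matrix(graph)
  n <- nrow(W)
  if (n < 2) stop("need at least 2 nodes")
  D <- shortest_lengths(W)
  inv <- 1 / D
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Nodal (local) efficiency
#'
#' Local efficiency of node i is the global efficiency of the subgraph
#' induced by i's neighbours; nodes with fewer than 2 neighbours score 0.
#'
#' @inheritParams global_efficiency
#' @param node optional node label or index; default all nodes
#' @return named vector of local efficiencies (or a scalar if `node` given)
#' @export
nodal_efficiency <- function(graph, node = NULL) {
  W <- as_weight_matrix(graph)
  idx <- resolve_nodes(W, node)
  out <- vapply(idx, function(i) {
    nb <- which(W[i, ] > 0)
    if (length(nb) < 2) return(0)
    global_efficiency(W[nb, nb, drop = FALSE])
  }, 0)
  names(out) <- rownames(W)[idx]
  if (!is.null(node)) unname(out) else out
}

#' Weighted clustering coefficient (Onnela)
#'
#' `C_i = (1/(k_i (k_i - 1))) * sum_{j != h} (w'_ij w'_ih w'_jh)^(1/3)` with
#' weights normalized by the matrix maximum (`w' = w / max(w)`) and `k_i` the
#' number of non-zero neighbours. Nodes with degree < 2 score 0.
#'
#' @inheritParams nodal_efficiency
#' @return named vector of clustering coefficients (scalar if `node` given)
#' @export
clustering_coefficient <- function(graph, node = NULL) {
  W <- as_weight_matrix(graph)
  if (nrow(W) < 3) stop("need at least 3 nodes")
  idx <- resolve_nodes(W, node)
  mx <- max(W)
  Wn <- if (mx > 0) (W / mx)^(1 / 3) else W
  cyc <- diag(Wn %*% Wn %*% Wn)
  k <- rowSums(W > 0)
  denom <- k * (k - 1)
  ci <- ifelse(denom > 0, cyc / denom, 0)
  out <- ci[idx]
  names(out) <- rownames(W)[idx]
  if (!is.null(node)) unname(out) else out
}

resolve_nodes <- function(W, node) {
  if (is.null(node)) return(seq_len(nrow(W)))
  if (is.character(node)) {
    i <- match(node, rownames(W))
    if (anyNA(i)) stop("unknown node: ", paste(node[is.na(i)], collapse = ", "))
    return(i)
  }
  if (any(node < 1 | node > nrow(W))) stop("node index out of range")
  node
}

#' Newman weighted modularity of a partition
#'
#' `Q = (1/2m) * sum_ij (w_ij - gamma * k_i k_j / (2m)) * [c_i == c_j]`.
#'
#' @inheritParams global_efficiency
#' @param membership integer community label per node
#' @param gamma resolution parameter
#' @return modularity Q
#' @export
modularity_q <- function(graph, membership, gamma = 1) {
  sum(nodal_modularity(graph, membership, gamma))
}

#' Per-node decomposition of modularity
#'
#' `Q_i = (1/2m) * sum_j (w_ij - gamma * k_i k_j / (2m)) * [c_i == c_j]`;
#' the contributions sum exactly to Q, giving an electrode-resolved
#' "local modularity".
#'
#' @inheritParams modularity_q
#' @return named vector of per-node contributions
#' @export
nodal_modularity <- function(graph, membership, gamma = 1) {
  W <- as_weight_matrix(graph)
  n <- nrow(W)
  if (length(membership) != n) stop("partition must cover every node")
  k <- rowSums(W)
  m2 <- sum(k)
  if (m2 <= 0) stop("graph has zero total weight")
  same <- outer(membership, membership, "==")
  contrib <- (W - gamma * outer(k, k) / m2) * same
  out <- rowSums(contrib) / m2
  names(out) <- rownames(W)
  out
}

# one Louvain pass + aggregation, on a matrix that may carry self-loops
# (diagonal = internal weight of an aggregated community, counted twice in
# the degree)
louvain_one_level <- function(W, gamma, order) {
  n <- nrow(W)
  k <- rowSums(W) + diag(W)      # self-loop counts twice
  m2 <- sum(k)
  comm <- seq_len(n)
  sig_tot <- k
  improved_any <- FALSE
  repeat {
    improved <- FALSE
    for (i in order) {
      ci <- comm[i]
      # weights from i to each community (excluding self-loop)
      wi <- W[i, ]
      wi[i] <- 0
      k_ic <- tapply(wi, comm, sum)
      sig_tot[ci] <- sig_tot[ci] - k[i]
      cand <- unique(c(ci, comm[wi > 0]))
      # modularity gain of placing i (removed from its community) into c
      gain <- vapply(cand, function(c) {
        kin <- if (as.character(c) %in% names(k_ic)) k_ic[[as.character(c)]] else 0
        2 * kin / m2 - gamma * 2 * sig_tot[c] * k[i] / (m2^2)
      }, 0)
      best <- cand[which.max(gain)]
      if (best != ci && gain[which.max(gain)] > gain[cand == ci] + 1e-12) {
        improved <- TRUE
        improved_any <- TRUE
      } else {
        best <- ci
      }
      comm[i] <- best
      sig_tot[best] <- sig_tot[best] + k[i]
    }
    if (!improved) break
  }
  comm <- match(comm, unique(comm))
  list(membership = comm, improved = improved_any)
}

aggregate_graph <- function(W, membership) {
  M <- outer(membership, seq_len(max(membership)), "==") * 1
  t(M) %*% W %*% M
}

louvain_once <- function(W, gamma, order_seed) {
  n <- nrow(W)
  set.seed(order_seed)
  Wl <- W
  member <- seq_len(n)
  repeat {
    ord <- sample(nrow(Wl))
    lev <- louvain_one_level(Wl, gamma, ord)
    if (!lev$improved || max(lev$membership) == nrow(Wl)) break
    member <- lev$membership[member]
    Wl <- aggregate_graph(Wl, lev$membership)
    if (nrow(Wl) == 1) break
  }
  member
}

#' Louvain community detection with seeded restarts
#'
#' Runs the Louvain algorithm `n_restarts` times with shuffled node orders
#' and keeps the partition with the highest modularity (first occurrence wins
#' ties). Deterministic given `seed`.
#'
#' @inheritParams global_efficiency
#' @param gamma resolution parameter
#' @param n_restarts number of restarts
#' @param seed integer seed
#' @return list with `membership` (integer labels, 1-based, in order of first
#'   appearance) and `Q`
#' @export
louvain_partition <- function(graph, gamma = 1, n_restarts = 100, seed = 1) {
  W <- as_weight_matrix(graph)
  if (sum(W) <= 0) stop("graph has zero total weight")
  local_rng(seed)
  sub_seeds <- sample.int(2147483646, n_restarts)
  best_q <- -Inf
  best <- NULL
  for (r in seq_len(n_restarts)) {
    mem <- louvain_once(W, gamma, sub_seeds[r])
    q <- modularity_q(W, mem, gamma)
    if (q > best_q + 1e-12) {
      best_q <- q
      best <- mem
    }
  }
  list(membership = match(best, unique(best)), Q = best_q)
}

#' All graph metrics for one connectivity matrix
#'
#' @param cm a `connectivity_matrix` (or weight matrix)
#' @param gamma Louvain resolution parameter
#' @param n_restarts Louvain restarts
#' @param seed integer seed for the Louvain restarts
#' @return a `network_metric_set`: nodal efficiency / clustering / modularity
#'   vectors, their global counterparts (`global_clustering` is the mean of
#'   the nodal values), `modularity_Q`, and the community `partition`
#' @export
metric_set <- function(cm, gamma = 1, n_restarts = 100, seed = 1) {
  W <- as_weight_matrix(cm)
  part <- louvain_partition(W, gamma = gamma, n_restarts = n_restarts,
                            seed = seed)
  ne <- nodal_efficiency(W)
  ncl <- clustering_coefficient(W)
  nm <- nodal_modularity(W, part$membership, gamma)
  structure(list(
    nodal_efficiency = ne,
    nodal_clustering = ncl,
    nodal_modularity = nm,
    global_efficiency = global_efficiency(W),
    global_clustering = mean(ncl),
    modularity_Q = part$Q,
    partition = part$membership
  ), class = "network_metric_set")
}

#' @export
print.network_metric_set <- function(x, ...) {
  cat(sprintf(
    "<network_metric_set> %d nodes: E_glob = %.4f, C_glob = %.4f, Q = %.4f (%d communities)\n",
    length(x$nodal_efficiency), x$global_efficiency, x$global_clustering,
    x$modularity_Q, max(x$partition)))
  invisible(x)
}
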