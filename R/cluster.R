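#' Cluster-level permutation tests
#'
#' Mass-univariate two-group comparison with family-wise error control by the
#' max-statistic permutation scheme: per-feature pooled two-sample t values,
#' supra-threshold features joined into connected clusters under a supplied
#' adjacency, cluster mass = sum of member t values, and a null distribution
#' of the maximum absolute cluster mass over group-label permutations.
#' Features may be connectivity edges (two edges are neighbours when they
#' share a channel) or sensors (neighbours from a Delaunay triangulation of
#' the flattened montage).
#'
#' @name cluster-permutation
NULL

#' Adjacency over connectivity edges
#'
#' Features are the unordered channel pairs in `combn` order (the upper
#' triangle column-wise); two edges are neighbours iff they share a channel.
#'
#' @param channel_labels character vector of >= 3 unique channel labels
#' @return an `adjacency_structure`: list with `features` (labels like
#'   `"C3--Fz"`) and `neighbours` (list of integer vectors)
#' @export
edge_adjacency <- function(channel_labels) {
  if (anyDuplicated(channel_labels)) stop("duplicate channel labels")
  n <- length(channel_labels)
  if (n < 3) stop("need at least 3 channels")
  pairs <- utils::combn(n, 2)
  feats <- paste0(channel_labels[pairs[1, ]], "--", channel_labels[pairs[2, ]])
  # edges incident to each channel form a clique of neighbours
  by_ch <- lapply(seq_len(n), function(ch) which(pairs[1, ] == ch | pairs[2, ] == ch))
  nb <- vector("list", ncol(pairs))
  for (e in seq_along(nb)) {
    cand <- unique(c(by_ch[[pairs[1, e]]], by_ch[[pairs[2, e]]]))
    nb[[e]] <- sort(setdiff(cand, e))
  }
  structure(list(features = feats, neighbours = nb, kind = "edge",
                 channels = channel_labels),
            class = "adjacency_structure")
}

# 2-D azimuthal-equidistant projection of unit-sphere sensor positions
flatten_montage <- function(montage) {
  p <- as.matrix(montage[, c("x", "y", "z")])
  incl <- acos(pmin(pmax(p[, 3], -1), 1))
  r2 <- sqrt(p[, 1]^2 + p[, 2]^2)
  ux <- ifelse(r2 > 1e-12, p[, 1] / r2, 0)
  uy <- ifelse(r2 > 1e-12, p[, 2] / r2, 0)
  cbind(incl * ux, incl * uy)
}

# Delaunay triangulation by the empty-circumcircle definition (points in
# general position; O(n^4), adequate for sensor counts)
delaunay_edges <- function(xy) {
  n <- nrow(xy)
  edges <- matrix(integer(0), ncol = 2)
  tri <- utils::combn(n, 3)
  for (t in seq_len(ncol(tri))) {
    i <- tri[1, t]; j <- tri[2, t]; k <- tri[3, t]
    ax <- xy[i, 1]; ay <- xy[i, 2]
    bx <- xy[j, 1]; by <- xy[j, 2]
    cx <- xy[k, 1]; cy <- xy[k, 2]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(d) < 1e-12) next  # collinear triple
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
             (cx^2 + cy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
             (cx^2 + cy^2) * (bx - ax)) / d
    r2 <- (ax - ux)^2 + (ay - uy)^2
    dd <- (xy[, 1] - ux)^2 + (xy[, 2] - uy)^2
    dd[c(i, j, k)] <- Inf
    if (all(dd > r2 * (1 - 1e-9))) {
      edges <- rbind(edges, c(i, j), c(i, k), c(j, k))
    }
  }
  if (!nrow(edges)) stop("degenerate sensor layout: no Delaunay triangles")
  unique(t(apply(edges, 1, sort)))
}

#' Adjacency over sensors
#'
#' Neighbour relation from the Delaunay triangulation of the 2-D azimuthal
#' projection of the sensor positions.
#'
#' @param montage montage data frame with >= 4 sensors
#' @return an `adjacency_structure` with sensor labels as features
#' @export
sensor_adjacency <- function(montage) {
  validate_montage(montage)
  if (nrow(montage) < 4) stop("need at least 4 sensors")
  xy <- flatten_montage(montage)
  ed <- delaunay_edges(xy)
  nb <- lapply(seq_len(nrow(montage)), function(i) {
    sort(unique(c(ed[ed[, 1] == i, 2], ed[ed[, 2] == i, 1])))
  })
  structure(list(features = montage$label, neighbours = nb, kind = "sensor"),
            class = "adjacency_structure")
}

# clusters for a two-tailed test: positive and negative supra-threshold
# features form separate clusters (opposite-sign effects are distinct
# phenomena and must not cancel within a cluster mass)
signed_clusters <- function(tv, thr, neighbours) {
  c(supra_clusters(which(tv > thr), neighbours),
    supra_clusters(which(tv < -thr), neighbours))
}

# connected components among supra-threshold features; returns list of
# integer vectors (feature indices)
supra_clusters <- function(supra_idx, neighbours) {
  if (!length(supra_idx)) return(list())
  in_supra <- logical(length(neighbours))
  in_supra[supra_idx] <- TRUE
  visited <- logical(length(neighbours))
  out <- list()
  for (s in supra_idx) {
    if (visited[s]) next
    comp <- integer(0)
    queue <- s
    visited[s] <- TRUE
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      comp <- c(comp, v)
      nxt <- neighbours[[v]]
      nxt <- nxt[in_supra[nxt] & !visited[nxt]]
      visited[nxt] <- TRUE
      queue <- c(queue, nxt)
    }
    out[[length(out) + 1]] <- sort(comp)
  }
  out
}

# pooled two-sample t statistics for many permutations at once.
# X: n x F data, P: n_perm x n 0/1 indicator of group-A membership.
perm_tstats <- function(X, P, n_a, n_b) {
  n <- n_a + n_b
  S <- colSums(X)
  S2 <- colSums(X^2)
  SA <- P %*% X          # n_perm x F sums of group A
  SA2 <- P %*% X^2
  SB <- matrix(S, nrow(P), ncol(X), byrow = TRUE) - SA
  SB2 <- matrix(S2, nrow(P), ncol(X), byrow = TRUE) - SA2
  mA <- SA / n_a; mB <- SB / n_b
  ssA <- SA2 - n_a * mA^2
  ssB <- SB2 - n_b * mB^2
  sp2 <- (ssA + ssB) / (n - 2)
  se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
  t <- (mA - mB) / se
  t[se == 0] <- 0
  t
}

#' Cluster-level permutation test between two groups of feature maps
#'
#' @param group_a,group_b numeric matrices, subjects x features, with matching
#'   feature columns in the order of `adjacency$features` (column names, when
#'   present, are checked against it)
#' @param adjacency an `adjacency_structure` from [edge_adjacency()] or
#'   [sensor_adjacency()]
#' @param n_perm number of label permutations (all distinct arrangements are
#'   enumerated instead when there are at most `n_perm` of them)
#' @param cluster_alpha two-tailed alpha defining the cluster-forming t
#'   threshold (pooled df)
#' @param seed integer seed for the permutation draw
#' @return a `cluster_test` list: `clusters` (feature-index vectors),
#'   `cluster_features` (labels), `cluster_mass`, `p_value`, `t_threshold`,
#'   `n_perm` (permutations actually used), `enumerated`, `seed`, `t_obs`
#' @export
cluster_permutation_test <- function(group_a, group_b, adjacency,
                                     n_perm = 1024, cluster_alpha = 0.05,
                                     seed = 1) {
  stopifnot(inherits(adjacency, "adjacency_structure"))
  f <- length(adjacency$features)
  if (ncol(group_a) != f || ncol(group_b) != f) {
    stop("feature columns do not match the adjacency structure")
  }
  for (g in list(group_a, group_b)) {
    if (!is.null(colnames(g)) && !identical(colnames(g), adjacency$features)) {
      stop("feature columns are misaligned with the adjacency structure")
    }
  }
  n_a <- nrow(group_a); n_b <- nrow(group_b)
  if (n_a < 2 || n_b < 2) stop("each group needs at least 2 subjects")
  n <- n_a + n_b
  X <- rbind(group_a, group_b)
  thr <- stats::qt(1 - cluster_alpha / 2, df = n - 2)

  t_obs <- drop(perm_tstats(X, matrix(c(rep(1, n_a), rep(0, n_b)), 1), n_a, n_b))
  cl <- signed_clusters(t_obs, thr, adjacency$neighbours)
  mass <- vapply(cl, function(ix) sum(t_obs[ix]), 0)

  n_arr <- choose(n, n_a)
  enumerated <- n_arr <= n_perm
  if (enumerated) {
    combos <- utils::combn(n, n_a)
    P <- matrix(0, ncol(combos), n)
    P[cbind(rep(seq_len(ncol(combos)), each = n_a), as.vector(combos))] <- 1
  } else {
    local_rng(seed)
    seen <- character(0)
    rows <- list()
    while (length(rows) < n_perm) {
      s <- sort(sample.int(n, n_a))
      key <- paste(s, collapse = ",")
      if (key %in% seen) next
      seen <- c(seen, key)
      rows[[length(rows) + 1]] <- s
    }
    P <- matrix(0, n_perm, n)
    for (r in seq_along(rows)) P[r, rows[[r]]] <- 1
  }
  Tp <- perm_tstats(X, P, n_a, n_b)
  null_max <- apply(Tp, 1, function(tv) {
    cls <- signed_clusters(tv, thr, adjacency$neighbours)
    if (!length(cls)) return(0)
    max(abs(vapply(cls, function(ix) sum(tv[ix]), 0)))
  })
  n_used <- nrow(P)
  p <- vapply(mass, function(m) (1 + sum(null_max >= abs(m))) / (1 + n_used), 0)

  structure(list(
    clusters = cl,
    cluster_features = lapply(cl, function(ix) adjacency$features[ix]),
    cluster_mass = mass,
    p_value = p,
    t_threshold = thr,
    n_perm = n_used,
    enumerated = enumerated,
    seed = seed,
    t_obs = t_obs
  ), class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf("<cluster_test> %d cluster(s), t threshold %.3f, %d permutations%s\n",
              length(x$clusters), x$t_threshold, x$n_perm,
              if (x$enumerated) " (enumerated)" else ""))
  for (i in seq_along(x$clusters)) {
    cat(sprintf("  cluster %d: %d features, mass %.2f, p = %.4f\n",
                i, length(x$clusters[[i]]), x$cluster_mass[i], x$p_value[i]))
  }
  invisible(x)
}

#' Vectorize the upper triangle of subjects' connectivity matrices
#'
#' Stacks per-subject connectivity matrices into a subjects x edges feature
#' matrix whose columns follow [edge_adjacency()] order.
#'
#' @param cms list of `connectivity_matrix` objects (or plain matrices) with
#'   identical channel sets
#' @return numeric matrix, subjects x edges, with edge labels as column names
#' @export
edge_features <- function(cms) {
  mats <- lapply(cms, function(cm) {
    if (inherits(cm, "connectivity_matrix")) cm$values else cm
  })
  labs <- rownames(mats[[1]])
  n <- nrow(mats[[1]])
  pairs <- utils::combn(n, 2)
  out <- t(vapply(mats, function(m) m[cbind(pairs[1, ], pairs[2, ])],
                  numeric(ncol(pairs))))
  colnames(out) <- paste0(labs[pairs[1, ]], "--", labs[pairs[2, ]])
  out
}
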