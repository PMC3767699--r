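# Global and nodal graph metrics on binary undirected networks.
#
# All functions take a symmetric 0/1 adjacency matrix with zero diagonal.
# Conventions for sparse (possibly disconnected) networks follow common
# binary-network practice: nodes of degree < 2 have clustering 0, the
# characteristic path length averages over reachable pairs only, and
# disconnected pairs contribute 0 to efficiencies.

#' Shortest-path distance matrix of a binary network
#'
#' Breadth-first distances for all node pairs via iterated boolean matrix
#' products; unreachable pairs are `Inf`.
#'
#' @param adj symmetric 0/1 adjacency matrix, zero diagonal.
#' @return Numeric matrix of hop counts (diagonal 0).
#' @export
net_distances <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  reach <- adj > 0
  step <- 1
  repeat {
    new <- reach & !is.finite(D)
    if (!any(new)) break
    D[new] <- step
    step <- step + 1
    reach <- (reach %*% adj) > 0
  }
  D
}

#' Clustering coefficient (nodal and mean)
#'
#' For each node, the fraction of realised connections among its
#' neighbours; nodes with fewer than two neighbours score 0 so the network
#' mean stays defined at sparse thresholds (set `exclude_low_degree = TRUE`
#' to average over nodes with degree >= 2 only).
#'
#' @param adj adjacency matrix.
#' @param exclude_low_degree drop degree < 2 nodes from the mean.
#' @return List: `nodal` per-node coefficients, `Cp` the mean.
#' @export
clustering_coefficient <- function(adj, exclude_low_degree = FALSE) {
  check_adjacency(adj)
  n <- nrow(adj)
  deg <- rowSums(adj)
  nodal <- numeric(n)
  for (v in seq_len(n)) {
    if (deg[v] < 2) next
    nb <- which(adj[v, ] == 1)
    nodal[v] <- sum(adj[nb, nb]) / (deg[v] * (deg[v] - 1))
  }
  Cp <- if (exclude_low_degree) {
    if (any(deg >= 2)) mean(nodal[deg >= 2]) else NA_real_
  } else mean(nodal)
  list(nodal = nodal, Cp = Cp)
}

#' Characteristic path length
#'
#' Mean shortest path length over all reachable unordered node pairs
#' (disconnected pairs are excluded from the average, keeping the metric
#' finite on the sparse end of a threshold sweep).
#'
#' @param adj adjacency matrix.
#' @return `Lp` as a scalar.
#' @export
characteristic_path_length <- function(adj) {
  check_adjacency(adj)
  if (sum(adj) == 0) stop_netrel("Lp is undefined on an edgeless network")
  D <- net_distances(adj)
  d <- D[upper.tri(D)]
  mean(d[is.finite(d)])
}

#' Global efficiency
#'
#' Average inverse shortest path length over all unordered node pairs;
#' disconnected pairs contribute 0.
#'
#' @param adj adjacency matrix.
#' @return `Eglob` in `[0, 1]`.
#' @export
global_efficiency <- function(adj) {
  check_adjacency(adj)
  n <- nrow(adj)
  if (n < 2) return(0)
  D <- net_distances(adj)
  inv <- 1 / D
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Nodal efficiency
#'
#' For node v, the mean of `1/d(v, u)` over all other nodes u (the inverse
#' of the harmonic mean of its shortest path lengths).
#'
#' @param adj adjacency matrix.
#' @return Numeric vector, one value in `[0, 1]` per node.
#' @export
nodal_efficiency <- function(adj) {
  check_adjacency(adj)
  n <- nrow(adj)
  D <- net_distances(adj)
  inv <- 1 / D
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  rowSums(inv) / (n - 1)
}

#' Local efficiency
#'
#' For each node, the global efficiency of the subgraph induced on its
#' direct neighbours (0 for fewer than two neighbours); `Eloc` is the mean
#' over all nodes.
#'
#' @param adj adjacency matrix.
#' @return List: `nodal` per-node values, `Eloc` the mean.
#' @export
local_efficiency <- function(adj) {
  check_adjacency(adj)
  n <- nrow(adj)
  nodal <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(adj[v, ] == 1)
    if (length(nb) < 2) next
    nodal[v] <- global_efficiency(adj[nb, nb, drop = FALSE])
  }
  list(nodal = nodal, Eloc = mean(nodal))
}

#' Nodal degree
#'
#' @param adj adjacency matrix.
#' @return Integer vector of per-node edge counts.
#' @export
nodal_degree <- function(adj) {
  check_adjacency(adj)
  as.integer(rowSums(adj))
}

#' Nodal betweenness centrality
#'
#' Raw shortest-path betweenness: for each node v, the sum over unordered
#' pairs (m, n), v not in {m, n}, of the fraction of shortest m-n paths
#' passing through v (Brandes accumulation; no endpoint normalisation).
#'
#' @param adj adjacency matrix.
#' @param normalized divide by `(n-1)(n-2)/2` to map onto `[0, 1]`.
#' @return Numeric vector of per-node betweenness values.
#' @export
nodal_betweenness <- function(adj, normalized = FALSE) {
  check_adjacency(adj)
  n <- nrow(adj)
  nbrs <- lapply(seq_len(n), function(v) which(adj[v, ] == 1))
  bc <- numeric(n)
  for (s in seq_len(n)) {
    # BFS from s
    dist <- rep(-1L, n); dist[s] <- 0L
    sigma <- numeric(n); sigma[s] <- 1
    preds <- vector("list", n)
    order_visited <- integer(0)
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      order_visited <- c(order_visited, v)
      for (w in nbrs[[v]]) {
        if (dist[w] < 0) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- numeric(n)
    for (w in rev(order_visited)) {
      for (v in preds[[w]])
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  bc <- bc / 2                    # undirected: each pair counted twice
  if (normalized && n > 2) bc <- bc / ((n - 1) * (n - 2) / 2)
  bc
}

# modularity of a given partition:  Q = sum_m [ l_m/L - (d_m / 2L)^2 ]
partition_modularity <- function(adj, membership) {
  L <- sum(adj) / 2
  if (L == 0) stop_netrel("modularity is undefined on an edgeless network")
  Q <- 0
  for (m in unique(membership)) {
    nodes <- which(membership == m)
    l_m <- sum(adj[nodes, nodes, drop = FALSE]) / 2
    d_m <- sum(adj[nodes, , drop = FALSE])
    Q <- Q + l_m / L - (d_m / (2 * L))^2
  }
  Q
}

#' Modularity and community partition
#'
#' Deterministic greedy agglomerative modularity optimisation: starting
#' from singleton communities, repeatedly merge the pair of connected
#' communities with the largest modularity gain (lexicographic tie-break)
#' until one community remains, and return the partition with the highest
#' modularity seen along the way. Q is evaluated exactly as
#' `sum_m [ l_m/L - (d_m/2L)^2 ]`.
#'
#' @param adj adjacency matrix with at least one edge.
#' @return List: `Q`, `membership` (integer community labels, renumbered
#'   consecutively).
#' @export
modularity <- function(adj) {
  check_adjacency(adj)
  n <- nrow(adj)
  L <- sum(adj) / 2
  if (L == 0) stop_netrel("modularity is undefined on an edgeless network")

  # community-level edge counts e[i, j] and degree sums d[i]
  e <- adj / 1          # e[i,j]: edges between communities; e[i,i]: 2x within
  d <- rowSums(adj)
  active <- seq_len(n)
  member_of <- seq_len(n)

  best_Q <- partition_modularity(adj, member_of)
  best_membership <- member_of

  cur_membership <- member_of
  while (length(active) > 1) {
    # candidate merges: connected community pairs
    sub <- e[active, active, drop = FALSE]
    cand <- which(upper.tri(sub) & sub > 0, arr.ind = TRUE)
    if (nrow(cand) == 0) break    # disconnected components remain
    i_idx <- active[cand[, 1]]
    j_idx <- active[cand[, 2]]
    dQ <- e[cbind(i_idx, j_idx)] / L - d[i_idx] * d[j_idx] / (2 * L^2)
    pick <- order(-dQ, pmin(i_idx, j_idx), pmax(i_idx, j_idx))[1]
    i <- min(i_idx[pick], j_idx[pick])
    j <- max(i_idx[pick], j_idx[pick])
    # merge j into i
    e[i, ] <- e[i, ] + e[j, ]
    e[, i] <- e[, i] + e[, j]
    d[i] <- d[i] + d[j]
    e[j, ] <- 0; e[, j] <- 0; d[j] <- 0
    active <- setdiff(active, j)
    cur_membership[cur_membership == j] <- i
    Q_now <- partition_modularity(adj, cur_membership)
    if (Q_now > best_Q + 1e-12) {
      best_Q <- Q_now
      best_membership <- cur_membership
    }
  }
  list(Q = best_Q, membership = as.integer(factor(best_membership)))
}

#' Hierarchy exponent
#'
#' Ordinary least-squares slope of `log C(v)` versus `log k(v)` over nodes
#' with degree >= 2 and positive clustering; `beta` is the negative slope
#' (`C ~ k^-beta`). Undefined (NA) when fewer than two eligible nodes or no
#' degree variation remains.
#'
#' @param adj adjacency matrix.
#' @return `beta` as a scalar, or `NA` when the regression is degenerate.
#' @export
hierarchy_beta <- function(adj) {
  check_adjacency(adj)
  k <- rowSums(adj)
  C <- clustering_coefficient(adj)$nodal
  keep <- k >= 2 & C > 0
  if (sum(keep) < 2 || length(unique(k[keep])) < 2) return(NA_real_)
  x <- log(k[keep]); y <- log(C[keep])
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  -slope
}

#' Degree assortativity
#'
#' Standard Newman formulation: the Pearson correlation between the degrees
#' at the two ends of every edge, with each edge counted in both
#' orientations. Undefined (NA) when the endpoint degrees have zero
#' variance (e.g. regular graphs).
#'
#' @param adj adjacency matrix with at least 2 edges.
#' @return `r` in `[-1, 1]`, or `NA` when degenerate.
#' @export
assortativity <- function(adj) {
  check_adjacency(adj)
  pairs <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
  if (nrow(pairs) < 2) stop_netrel("assortativity needs at least 2 edges")
  deg <- rowSums(adj)
  x <- c(deg[pairs[, 1]], deg[pairs[, 2]])
  y <- c(deg[pairs[, 2]], deg[pairs[, 1]])
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' All ten global metrics of a binary network
#'
#' Computes the clustering coefficient `Cp`, characteristic path length
#' `Lp`, local and global efficiency `Eloc`/`Eglob`, modularity `Q`,
#' hierarchy `beta` and assortativity `r`; when `null_config` is supplied,
#' also the null-normalised `gamma`, `lambda` and small-worldness
#' `sigma = gamma/lambda` (see [normalized_smallworld()]). Metrics that are
#' undefined on the given network are `NA`, never zero.
#'
#' @param adj adjacency matrix.
#' @param null_config a [null_model_config()] or `NULL` to skip
#'   `gamma`/`lambda`/`sigma`.
#' @param cm the connectivity matrix behind `adj`; required for the
#'   `"correlation_randomization"` null method.
#' @return Named numeric vector of global metrics.
#' @export
global_metrics <- function(adj, null_config = NULL, cm = NULL) {
  check_adjacency(adj)
  has_edge <- sum(adj) > 0
  Cp <- clustering_coefficient(adj)$Cp
  Lp <- if (has_edge) characteristic_path_length(adj) else NA_real_
  out <- c(Cp = Cp, Lp = Lp,
           gamma = NA_real_, lambda = NA_real_, sigma = NA_real_,
           Eloc = local_efficiency(adj)$Eloc,
           Eglob = global_efficiency(adj),
           Q = if (has_edge) modularity(adj)$Q else NA_real_,
           beta = hierarchy_beta(adj),
           r = if (sum(adj) / 2 >= 2) assortativity(adj) else NA_real_)
  if (!is.null(null_config) && has_edge) {
    sw <- normalized_smallworld(adj, null_config, cm = cm)
    out["gamma"] <- sw["gamma"]; out["lambda"] <- sw["lambda"]
    out["sigma"] <- sw["sigma"]
  }
  out
}
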