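# Brute-force oracles for graph metrics, independent of the package's
# implementations: Floyd-Warshall distances, exhaustive neighbour-pair
# clustering, distance-based shortest-path counting for betweenness, and
# exhaustive partition search for modularity.

random_graph <- function(n, p, seed) {
  set.seed(seed)
  A <- matrix(0, n, n)
  up <- upper.tri(A)
  A[up] <- stats::rbinom(sum(up), 1, p)
  A + t(A)
}

bf_distances <- function(adj) {
  n <- nrow(adj)
  D <- ifelse(adj == 1, 1, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

bf_clustering <- function(adj) {
  n <- nrow(adj)
  C <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(adj[v, ] == 1)
    if (length(nb) < 2) next
    links <- 0
    for (a in nb) for (b in nb) if (a < b && adj[a, b] == 1)
      links <- links + 1
    C[v] <- 2 * links / (length(nb) * (length(nb) - 1))
  }
  C
}

# number of shortest paths between every ordered pair, from distances
bf_path_counts <- function(adj, D) {
  n <- nrow(adj)
  sigma <- matrix(0, n, n)
  diag(sigma) <- 1
  for (len in seq_len(n)) {
    for (u in seq_len(n)) for (w in seq_len(n)) {
      if (u == w || !is.finite(D[u, w]) || D[u, w] != len) next
      preds <- which(adj[, w] == 1 & D[u, ] == len - 1)
      sigma[u, w] <- sum(sigma[u, preds])
    }
  }
  sigma
}

bf_betweenness <- function(adj) {
  n <- nrow(adj)
  D <- bf_distances(adj)
  sigma <- bf_path_counts(adj, D)
  bc <- numeric(n)
  for (v in seq_len(n)) {
    for (m in seq_len(n - 1)) for (w in (m + 1):n) {
      if (v == m || v == w || !is.finite(D[m, w])) next
      if (D[m, v] + D[v, w] == D[m, w] && sigma[m, w] > 0)
        bc[v] <- bc[v] + sigma[m, v] * sigma[v, w] / sigma[m, w]
    }
  }
  bc
}

bf_global_efficiency <- function(adj) {
  D <- bf_distances(adj)
  inv <- 1 / D
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  n <- nrow(adj)
  sum(inv) / (n * (n - 1))
}

# all set partitions of 1..n (Bell-number enumeration; n <= 8)
all_partitions <- function(n) {
  if (n == 1) return(list(c(1L)))
  out <- list()
  for (p in all_partitions(n - 1)) {
    for (g in seq_len(max(p) + 1))
      out[[length(out) + 1]] <- c(p, g)
  }
  out
}

bf_modularity_best <- function(adj) {
  L <- sum(adj) / 2
  best <- -Inf
  for (memb in all_partitions(nrow(adj))) {
    Q <- 0
    for (mm in unique(memb)) {
      nodes <- which(memb == mm)
      l_m <- sum(adj[nodes, nodes, drop = FALSE]) / 2
      d_m <- sum(adj[nodes, , drop = FALSE])
      Q <- Q + l_m / L - (d_m / (2 * L))^2
    }
    if (Q > best) best <- Q
  }
  best
}
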