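# Null models for small-world normalization: degree-preserving topology
# rewiring and correlation-matrix randomization.

#' Null-model configuration
#'
#' @param method `"topology_rewiring"` (Maslov-Sneppen double-edge swaps,
#'   preserving the degree sequence exactly) or
#'   `"correlation_randomization"` (random correlation matrices matching
#'   the observed off-diagonal mean and variance, preserving the transitive
#'   structure that thresholded correlation networks inherit).
#' @param n_null number of null networks (>= 1).
#' @param swaps_per_edge attempted swaps per edge for the rewiring method.
#' @param seed integer seed.
#' @return An object of class `"null_model_config"`.
#' @export
null_model_config <- function(method = c("topology_rewiring",
                                         "correlation_randomization"),
                              n_null = 100L, swaps_per_edge = 100L,
                              seed = 1L) {
  method <- match.arg(method)
  if (n_null < 1) stop_netrel("n_null must be >= 1")
  if (swaps_per_edge < 1) stop_netrel("swaps_per_edge must be >= 1")
  structure(list(method = method, n_null = as.integer(n_null),
                 swaps_per_edge = as.integer(swaps_per_edge),
                 seed = as.integer(seed)),
            class = "null_model_config")
}

#' Degree-preserving rewired null networks
#'
#' Maslov-Sneppen double-edge swaps (via igraph's degree-sequence-preserving
#' rewiring), `swaps_per_edge * |E|` attempted swaps per null. Every null
#' has exactly the original degree sequence, no self-loops and no
#' multi-edges. A complete graph admits no swaps and is returned unchanged
#' with a warning.
#'
#' @param adj adjacency matrix.
#' @param config a [null_model_config()].
#' @return List of `config$n_null` adjacency matrices.
#' @export
rewire_null <- function(adj, config = null_model_config()) {
  check_adjacency(adj)
  n <- nrow(adj)
  n_edges <- sum(adj) / 2
  if (n_edges == n_pairs(n))
    warning("complete graph: no swappable edge pairs; returning copies")
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  set.seed(config$seed)
  lapply(seq_len(config$n_null), function(k) {
    gr <- igraph::rewire(
      g, igraph::keeping_degseq(niter = config$swaps_per_edge * n_edges))
    as.matrix(igraph::as_adjacency_matrix(gr, sparse = FALSE))
  })
}

#' Random correlation matrices matching observed moments
#'
#' Hirschberger-Qi-Steuer-style generation: draws factor matrices
#' `B (n x m)` with normal entries whose product `B B'` has off-diagonal
#' mean and variance equal to the observed ones, then normalises to unit
#' diagonal. Outputs are valid correlation matrices (symmetric, unit
#' diagonal, positive semi-definite) that, once thresholded, preserve the
#' transitive structure real correlation networks carry -- unlike topology
#' rewiring.
#'
#' The factor count `m` is set from the variance equation with the
#' diagonal targeted at 1 (`m = round((1 - e^2)/v)`); because the final
#' unit-diagonal normalisation slightly distorts the moments, the targets
#' are recalibrated once against a pilot ensemble before the final draw.
#'
#' @param cm observed correlation matrix.
#' @param config a [null_model_config()].
#' @param n_pilot size of the calibration ensemble.
#' @return List of `config$n_null` correlation matrices.
#' @export
correlation_null <- function(cm, config = null_model_config(),
                             n_pilot = 100L) {
  n <- nrow(cm)
  off <- cm[upper.tri(cm)]
  e <- mean(off)
  v <- stats::var(off)
  if (abs(e) < 1e-12 && v < 1e-12) {
    # degenerate moments: the identity is its own null
    return(lapply(seq_len(config$n_null), function(k) diag(n)))
  }
  if (e <= 0)
    stop_netrel("infeasible moment combination: mean off-diagonal ",
                "correlation must be positive for moment-matched generation")
  gen <- function(e_t, v_t, n_null) {
    m <- max(2L, round((1 - e_t^2) / v_t))
    mu <- sqrt(e_t / m)
    s2 <- -mu^2 + sqrt(mu^4 + v_t / m)
    lapply(seq_len(n_null), function(k) {
      B <- matrix(stats::rnorm(n * m, mu, sqrt(s2)), n, m)
      stats::cov2cor(B %*% t(B))
    })
  }
  ens_moments <- function(nulls) {
    c(mean(vapply(nulls, function(C) mean(C[upper.tri(C)]), numeric(1))),
      mean(vapply(nulls, function(C) stats::var(C[upper.tri(C)]),
                  numeric(1))))
  }
  set.seed(config$seed)
  pilot <- ens_moments(gen(e, v, n_pilot))
  e_adj <- max(1e-8, e * e / pilot[1])
  v_adj <- v * v / pilot[2]
  gen(e_adj, v_adj, config$n_null)
}

#' Null-normalised small-world indices
#'
#' `gamma = Cp_real / mean(Cp_null)`, `lambda = Lp_real / mean(Lp_null)`,
#' `sigma = gamma / lambda`, with the null ensemble produced either by
#' degree-preserving rewiring of the network itself or by thresholding
#' moment-matched random correlation matrices at the same sparsity.
#'
#' @param adj adjacency matrix of the real network.
#' @param config a [null_model_config()].
#' @param cm the connectivity matrix behind `adj`; required for the
#'   `"correlation_randomization"` method (its attribute `"sparsity"` on
#'   `adj` or `sparsity` must give the threshold).
#' @param sparsity sparsity at which to threshold null correlation
#'   matrices (defaults to `attr(adj, "sparsity")`).
#' @return Named numeric vector `c(gamma, lambda, sigma)`; `gamma` (and
#'   `sigma`) are `NA` when the null ensemble has zero mean clustering.
#' @export
normalized_smallworld <- function(adj, config = null_model_config(),
                                  cm = NULL, sparsity = NULL) {
  check_adjacency(adj)
  nulls <- if (config$method == "topology_rewiring") {
    rewire_null(adj, config)
  } else {
    if (is.null(cm))
      stop_netrel("correlation_randomization needs the connectivity matrix")
    if (is.null(sparsity)) sparsity <- attr(adj, "sparsity")
    if (is.null(sparsity))
      stop_netrel("supply the sparsity used to threshold the network")
    lapply(correlation_null(cm, config),
           threshold_by_sparsity, sparsity = sparsity)
  }
  Cp_real <- clustering_coefficient(adj)$Cp
  Lp_real <- characteristic_path_length(adj)
  Cp_null <- mean(vapply(nulls, function(a) clustering_coefficient(a)$Cp,
                         numeric(1)))
  Lp_null <- mean(vapply(nulls, characteristic_path_length, numeric(1)))
  gamma <- if (Cp_null > 0) Cp_real / Cp_null else NA_real_
  lambda <- Lp_real / Lp_null
  c(gamma = gamma, lambda = lambda,
    sigma = if (is.na(gamma)) NA_real_ else gamma / lambda)
}
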