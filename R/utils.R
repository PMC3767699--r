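# Internal helpers shared across modules.

#' Derive a reproducible child seed from a master seed and a label
#'
#' All stochastic stages (data generation, ICA initialisation, null models)
#' draw their seeds through this function so that per-subject / per-stage
#' substreams are deterministic given one master seed, and independent of
#' evaluation order.
#'
#' @param seed master integer seed.
#' @param ... labels (coerced to character) identifying the substream,
#'   e.g. `"subject", 3, "session", 1`.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  labels <- paste(c(seed, vapply(list(...), as.character, character(1))),
                  collapse = "/")
  bytes <- utf8ToInt(labels)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  as.integer(h %% 2147483645L + 1L)
}

# round half away from zero (platform-stable edge-count rule)
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# number of unique node pairs
n_pairs <- function(n) n * (n - 1) / 2

stop_netrel <- function(...) stop(..., call. = FALSE)

check_adjacency <- function(adj) {
  if (!is.matrix(adj) || nrow(adj) != ncol(adj))
    stop_netrel("adjacency must be a square matrix")
  if (any(adj != 0 & adj != 1))
    stop_netrel("adjacency must be binary (0/1)")
  if (any(diag(adj) != 0))
    stop_netrel("adjacency must have a zero diagonal (no self-loops)")
  if (!isTRUE(all.equal(adj, t(adj))))
    stop_netrel("adjacency must be symmetric (undirected network)")
  invisible(adj)
}

upper_pairs <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  # order by (row, col) lexicographically for deterministic edge identity
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

# vectorize the strict upper triangle in (row, col) lexicographic order
upper_vec <- function(m) {
  t(m)[lower.tri(m)]
}
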