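# Pearson connectivity matrices and sparsity-based binarization.

#' Pearson correlation (connectivity) matrix of a multichannel recording
#'
#' @param ts channel-by-time matrix with at least 3 samples and no constant
#'   channel.
#' @return Symmetric channels x channels correlation matrix with unit
#'   diagonal (class `"connectivity_matrix"`).
#' @export
correlation_matrix <- function(ts) {
  if (ncol(ts) < 3) stop_netrel("need at least 3 samples per channel")
  sds <- apply(ts, 1, stats::sd)
  if (any(sds == 0))
    stop_netrel("constant channel(s) make Pearson r undefined: ",
                paste(which(sds == 0), collapse = ", "))
  cm <- stats::cor(t(ts))
  diag(cm) <- 1
  class(cm) <- c("connectivity_matrix", class(cm))
  cm
}

#' Sparsity grid of thresholds
#'
#' @param from,to,by grid limits and step; defaults 0.01 to 0.99 step 0.01
#'   (99 thresholds).
#' @return Strictly increasing numeric vector in (0, 1).
#' @export
sparsity_grid <- function(from = 0.01, to = 0.99, by = 0.01) {
  g <- seq(from, to, by = by)
  if (any(g <= 0) || any(g >= 1) || any(diff(g) <= 0))
    stop_netrel("sparsity grid must be strictly increasing within (0, 1)")
  g
}

#' Threshold a connectivity matrix into a binary network at a given sparsity
#'
#' Retains the `K = round(sparsity * n(n-1)/2)` strongest edges (largest
#' signed r by default, largest |r| with `absolute = TRUE`); K is computed
#' with round-half-away-from-zero and ties are broken by (row, col)
#' lexicographic order, so the ranking (hence the nestedness of a sweep) is
#' deterministic.
#'
#' @param cm symmetric correlation matrix.
#' @param sparsity fraction of retained edges in (0, 1).
#' @param absolute rank edges by |r| instead of signed r.
#' @return Binary 0/1 adjacency matrix with zero diagonal and attribute
#'   `"sparsity"`.
#' @export
threshold_by_sparsity <- function(cm, sparsity, absolute = FALSE) {
  if (sparsity <= 0 || sparsity >= 1)
    stop_netrel("sparsity must lie strictly between 0 and 1")
  n <- nrow(cm)
  K <- round_half_away(sparsity * n_pairs(n))
  if (K < 1) stop_netrel("sparsity ", sparsity, " retains no edges for n = ", n)
  pairs <- upper_pairs(n)
  vals <- cm[pairs]
  if (absolute) vals <- abs(vals)
  ord <- order(-vals, pairs[, 1], pairs[, 2])
  keep <- pairs[ord[seq_len(K)], , drop = FALSE]
  adj <- matrix(0, n, n)
  adj[keep] <- 1
  adj[keep[, 2:1, drop = FALSE]] <- 1
  attr(adj, "sparsity") <- sparsity
  adj
}

#' Binarize a connectivity matrix across a sparsity sweep
#'
#' @param cm symmetric correlation matrix.
#' @param grid thresholds from [sparsity_grid()].
#' @param absolute passed to [threshold_by_sparsity()].
#' @return Named list of adjacency matrices, one per grid value. Because
#'   edges are ranked once, the edge sets are nested across the sweep.
#' @export
sparsity_sweep <- function(cm, grid = sparsity_grid(), absolute = FALSE) {
  out <- lapply(grid, function(s) threshold_by_sparsity(cm, s, absolute))
  names(out) <- formatC(grid, format = "f", digits = 2)
  out
}

#' Write / read a connectivity matrix as TSV
#'
#' Tab-delimited with channel ids as header row and first column.
#' @param cm matrix to write.
#' @param path file path.
#' @param channel_ids channel labels (default `ch01`, ...).
#' @return `write_connectivity`: invisibly, `path`;
#'   `read_connectivity`: the matrix.
#' @export
write_connectivity <- function(cm, path, channel_ids = NULL) {
  n <- nrow(cm)
  if (is.null(channel_ids)) channel_ids <- sprintf("ch%02d", seq_len(n))
  df <- data.frame(channel = channel_ids, unclass(cm), check.names = FALSE)
  names(df) <- c("channel", channel_ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_connectivity
#' @export
read_connectivity <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  m
}
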