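# Metric-versus-sparsity curves and their area-under-curve summaries.

#' Evaluate metrics across a sparsity sweep
#'
#' Computes the requested global and nodal metrics on every network of a
#' sweep and returns them in long format. Undefined values are recorded as
#' `NA`, never zero.
#'
#' @param networks list of adjacency matrices from [sparsity_sweep()]
#'   (names give the sparsity values, or supply `grid`).
#' @param grid numeric sparsity values (defaults to `names(networks)`).
#' @param global character vector among
#'   `c("Cp", "Lp", "gamma", "lambda", "sigma", "Eloc", "Eglob", "Q",
#'   "beta", "r")`.
#' @param nodal character vector among
#'   `c("degree", "efficiency", "betweenness")`.
#' @param null_config [null_model_config()] for `gamma`/`lambda`/`sigma`
#'   (required if any of those is requested).
#' @param cm connectivity matrix, for the correlation-randomization null.
#' @return A long data.frame: `sparsity`, `metric`, `node` (`NA` for
#'   global metrics), `value`.
#' @export
metric_curves <- function(networks, grid = NULL,
                          global = c("Cp", "Lp", "Eloc", "Eglob",
                                     "Q", "beta", "r"),
                          nodal = c("degree", "efficiency",
                                    "betweenness"),
                          null_config = NULL, cm = NULL) {
  if (length(networks) == 0) stop_netrel("empty sparsity sweep")
  if (is.null(grid)) grid <- as.numeric(names(networks))
  if (anyNA(grid)) stop_netrel("supply numeric sparsity values via 'grid'")
  wants_null <- any(c("gamma", "lambda", "sigma") %in% global)
  if (wants_null && is.null(null_config))
    stop_netrel("gamma/lambda/sigma need a null_model_config")
  rows <- vector("list", length(networks))
  for (idx in seq_along(networks)) {
    adj <- networks[[idx]]
    gm <- global_metrics(adj,
                         null_config = if (wants_null) null_config,
                         cm = cm)
    chunks <- list()
    if (length(global))
      chunks$global <- data.frame(sparsity = grid[idx],
                                  metric = global,
                                  node = NA_integer_,
                                  value = unname(gm[global]))
    n <- nrow(adj)
    for (nm in nodal) {
      vals <- switch(nm,
                     degree = as.numeric(nodal_degree(adj)),
                     efficiency = nodal_efficiency(adj),
                     betweenness = nodal_betweenness(adj),
                     stop_netrel("unknown nodal metric: ", nm))
      chunks[[nm]] <- data.frame(sparsity = grid[idx], metric = nm,
                                 node = seq_len(n), value = vals)
    }
    rows[[idx]] <- do.call(rbind, chunks)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Area under a metric-versus-sparsity curve
#'
#' Trapezoidal integral over the sparsity grid. Missing values are dropped:
#' interior gaps are spanned by a single trapezoid between the adjacent
#' observed points (equivalent to linear interpolation across the gap),
#' while leading/trailing missing stretches shrink the integration range.
#'
#' @param values metric values at `grid` (may contain `NA`).
#' @param grid sparsity values, strictly increasing.
#' @return The integral as a scalar; the integration range actually used is
#'   attached as attribute `"range"`.
#' @export
curve_auc <- function(values, grid) {
  if (length(values) != length(grid))
    stop_netrel("values and grid must have equal length")
  ok <- !is.na(values)
  if (sum(ok) < 2)
    stop_netrel("need at least 2 non-missing points to integrate")
  x <- grid[ok]; y <- values[ok]
  auc <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  attr(auc, "range") <- range(x)
  auc
}
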