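# Test-retest reliability: one-way random-effects intraclass correlation,
# reliability grading, AUC summaries, session similarity and
# between-session statistical tests.

#' Intraclass correlation coefficient, one-way random effects ICC(1,1)
#'
#' Decomposes a subjects-by-sessions measurement table by one-way ANOVA
#' with random participant effects into between-participant (`MS_b`, df
#' `n - 1`) and within-participant (`MS_w`, df `n(k - 1)`) mean squares and
#' returns `ICC = (MS_b - MS_w) / (MS_b + (k - 1) MS_w)`. Negative raw
#' values (within-participant variance exceeding between-participant
#' variance) are clamped to zero and flagged.
#'
#' @param table numeric matrix: rows are subjects (>= 2), columns are
#'   repeated sessions (k >= 2). No missing values.
#' @return An object of class `"icc"`: `icc` (clamped to `[0, 1]`), `raw`,
#'   `ms_between`, `ms_within`, `n`, `k`, `grade` (see [icc_grade()]),
#'   `clamped`. Zero total variance gives `icc = NA` and `grade = NA`.
#' @examples
#' icc(cbind(c(1, 2, 3), c(2, 3, 4)))   # ICC = 0.6
#' @export
icc <- function(table) {
  table <- as.matrix(table)
  n <- nrow(table); k <- ncol(table)
  if (n < 2 || k < 2) stop_netrel("need >= 2 subjects and >= 2 sessions")
  if (anyNA(table)) stop_netrel("measurement table must be complete")
  subject_means <- rowMeans(table)
  grand <- mean(table)
  ms_b <- k * sum((subject_means - grand)^2) / (n - 1)
  ms_w <- sum((table - subject_means)^2) / (n * (k - 1))
  out <- list(icc = NA_real_, raw = NA_real_, ms_between = ms_b,
              ms_within = ms_w, n = n, k = k, grade = NA_character_,
              clamped = FALSE)
  class(out) <- "icc"
  if (ms_b + (k - 1) * ms_w <= 0) return(out)   # zero total variance
  raw <- (ms_b - ms_w) / (ms_b + (k - 1) * ms_w)
  out$raw <- raw
  out$clamped <- raw < 0
  out$icc <- max(0, raw)
  out$grade <- icc_grade(out$icc)
  out
}

#' @export
print.icc <- function(x, ...) {
  if (is.na(x$icc)) {
    cat("ICC(1,1): undefined (zero total variance)\n")
  } else {
    cat(sprintf("ICC(1,1) = %.4f (%s reliability%s)\n", x$icc, x$grade,
                if (x$clamped) sprintf("; raw %.4f clamped to 0", x$raw)
                else ""))
    cat(sprintf("  MS_between = %.6g (df %d), MS_within = %.6g (df %d), k = %d\n",
                x$ms_between, x$n - 1, x$ms_within, x$n * (x$k - 1), x$k))
  }
  invisible(x)
}

#' @export
coef.icc <- function(object, ...) c(icc = object$icc)

#' Reliability grade of an ICC value
#'
#' Five grades partitioning `[0, 1]`: poor `[0, 0.25)`, low `[0.25, 0.4)`,
#' fair `[0.4, 0.6)`, good `[0.6, 0.75)`, excellent `[0.75, 1]`.
#' Boundaries are half-open on the left with the upper end closed at 1, so
#' 0.6 grades as good and 0.75 as excellent.
#'
#' @param icc_value numeric vector of values in `[0, 1]` (NA allowed).
#' @return Character vector of grades.
#' @export
icc_grade <- function(icc_value) {
  if (any(icc_value < 0 | icc_value > 1, na.rm = TRUE))
    stop_netrel("ICC values must lie in [0, 1]")
  labels <- c("poor", "low", "fair", "good", "excellent")
  as.character(cut(icc_value, breaks = c(0, 0.25, 0.4, 0.6, 0.75, 1),
                   labels = labels, right = FALSE, include.lowest = TRUE))
}

# grade cut() maps [0.75, 1] correctly: right = FALSE makes intervals
# [a, b) and include.lowest closes the last interval at 1.

icc_row <- function(table) {
  r <- icc(table)
  data.frame(icc = r$icc, raw = r$raw, ms_b = r$ms_between,
             ms_w = r$ms_within, grade = r$grade, clamped = r$clamped,
             stringsAsFactors = FALSE)
}

#' Edge-wise reliability of connectivity matrices
#'
#' Computes the ICC of the raw Pearson r of every unique channel pair
#' across sessions, plus a distribution summary.
#'
#' @param cms 4-dimensional array `subjects x sessions x channels x
#'   channels` of correlation matrices (every subject must have every
#'   session).
#' @return List of class `"edge_reliability"`: `edges` (data.frame with
#'   `node_i`, `node_j`, `icc`, `grade`, `ms_b`, `ms_w`, `clamped`) and
#'   `summary` (`mean`, `sd`, `grade_counts`, `grade_fractions`).
#' @export
edge_reliability <- function(cms) {
  d <- dim(cms)
  if (length(d) != 4 || d[3] != d[4])
    stop_netrel("cms must be a subjects x sessions x channels x channels array")
  n_sub <- d[1]; n_ses <- d[2]; n_ch <- d[3]
  pairs <- upper_pairs(n_ch)
  n_edges <- nrow(pairs)
  rows <- vector("list", n_edges)
  for (eidx in seq_len(n_edges)) {
    i <- pairs[eidx, 1]; j <- pairs[eidx, 2]
    tab <- matrix(cms[, , i, j], n_sub, n_ses)
    rows[[eidx]] <- cbind(data.frame(node_i = i, node_j = j),
                          icc_row(tab))
  }
  edges <- do.call(rbind, rows)
  grades <- factor(edges$grade,
                   levels = c("poor", "low", "fair", "good", "excellent"))
  counts <- table(grades)
  out <- list(edges = edges,
              summary = list(mean = mean(edges$icc, na.rm = TRUE),
                             sd = stats::sd(edges$icc, na.rm = TRUE),
                             grade_counts = counts,
                             grade_fractions = counts / sum(counts)))
  class(out) <- "edge_reliability"
  out
}

#' @export
print.edge_reliability <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Edge-wise reliability: %d edges, mean ICC %.2f +/- %.2f\n",
              nrow(x$edges), s$mean, s$sd))
  print(s$grade_counts)
  invisible(x)
}

#' Threshold-dependent and AUC-based reliability of metric curves
#'
#' For each metric (and node, for nodal metrics): (a) the ICC at every
#' sparsity value, giving the threshold-dependent reliability profile, and
#' (b) the ICC of the per-subject areas under the curve, a single
#' threshold-independent reliability scalar. Sparsity points at which the
#' metric is missing for any subject/session are dropped from (a); the AUC
#' integrates each subject's curve over its non-missing range.
#'
#' @param curves long data.frame with columns `subject`, `session`,
#'   `metric`, `node` (`NA` for global metrics), `sparsity`, `value`.
#' @return List of class `"metric_reliability"`: `profile` (data.frame
#'   `metric`, `node`, `sparsity`, `icc`, `grade`) and `auc` (data.frame
#'   `metric`, `node`, `auc_icc`, `grade`, `ms_b`, `ms_w`, `clamped`).
#' @export
metric_reliability <- function(curves) {
  need <- c("subject", "session", "metric", "node", "sparsity", "value")
  if (!all(need %in% names(curves)))
    stop_netrel("curves must have columns: ", paste(need, collapse = ", "))
  curves$node[is.na(curves$node)] <- 0L       # 0 = global
  key <- interaction(curves$metric, curves$node, drop = TRUE)
  profile_rows <- list()
  auc_rows <- list()
  for (grp in split(curves, key)) {
    metric <- grp$metric[1]; node <- grp$node[1]
    subjects <- sort(unique(grp$subject))
    sessions <- sort(unique(grp$session))
    grid <- sort(unique(grp$sparsity))
    # value array subjects x sessions x sparsity
    arr <- array(NA_real_, c(length(subjects), length(sessions),
                             length(grid)))
    arr[cbind(match(grp$subject, subjects), match(grp$session, sessions),
              match(grp$sparsity, grid))] <- grp$value
    # (a) per-sparsity ICC on complete points
    for (g in seq_along(grid)) {
      tab <- arr[, , g]
      if (anyNA(tab)) next
      r <- icc(tab)
      profile_rows[[length(profile_rows) + 1]] <-
        data.frame(metric = metric, node = node, sparsity = grid[g],
                   icc = r$icc, grade = r$grade)
    }
    # (b) AUC-based scalar ICC
    aucs <- matrix(NA_real_, length(subjects), length(sessions))
    for (i in seq_along(subjects)) for (s in seq_along(sessions)) {
      vals <- arr[i, s, ]
      if (sum(!is.na(vals)) >= 2) aucs[i, s] <- curve_auc(vals, grid)
    }
    if (!anyNA(aucs)) {
      auc_rows[[length(auc_rows) + 1]] <-
        cbind(data.frame(metric = metric, node = node), icc_row(aucs))
    }
  }
  out <- list(profile = do.call(rbind, profile_rows),
              auc = do.call(rbind, auc_rows))
  if (!is.null(out$auc)) names(out$auc)[names(out$auc) == "icc"] <- "auc_icc"
  class(out) <- "metric_reliability"
  out
}

#' @export
print.metric_reliability <- function(x, ...) {
  cat("AUC-based (threshold-independent) reliability:\n")
  print(x$auc[, c("metric", "node", "auc_icc", "grade")], row.names = FALSE)
  invisible(x)
}

#' Between-session similarity of connectivity patterns
#'
#' Pearson correlation between the session-1 and session-2 vectors of the
#' unique edges, per subject and at the group-mean level, with two-sided
#' p-values from the t distribution on `n_edges - 2` degrees of freedom.
#'
#' @param cms 4-dimensional array as in [edge_reliability()] (2 sessions).
#' @return Data.frame with one row per subject plus a final `"group"` row:
#'   `subject`, `r`, `p`.
#' @export
session_similarity <- function(cms) {
  d <- dim(cms)
  if (length(d) != 4 || d[2] < 2)
    stop_netrel("cms must hold both sessions for every subject")
  n_sub <- d[1]; n_ch <- d[3]
  pairs <- upper_pairs(n_ch)
  v1 <- sapply(seq_len(n_sub), function(i) cms[i, 1, , ][pairs])
  v2 <- sapply(seq_len(n_sub), function(i) cms[i, 2, , ][pairs])
  cor_p <- function(x, y) {
    r <- stats::cor(x, y)
    df <- length(x) - 2
    t <- r * sqrt(df / (1 - r^2))
    c(r = r, p = 2 * stats::pt(-abs(t), df))
  }
  per_sub <- t(vapply(seq_len(n_sub),
                      function(i) cor_p(v1[, i], v2[, i]), numeric(2)))
  grp <- cor_p(rowMeans(v1), rowMeans(v2))
  data.frame(subject = c(as.character(seq_len(n_sub)), "group"),
             r = c(per_sub[, 1], grp[1]),
             p = c(per_sub[, 2], grp[2]))
}

#' Correlation between connection strength and reliability
#'
#' Pearson correlation (with two-sided p) between group-level mean edge
#' strength and edge-wise ICC across the unique connections.
#'
#' @param edge_iccs numeric vector of edge ICC values.
#' @param group_mean_edges numeric vector of group-mean edge correlations
#'   (same length and edge order).
#' @return List: `r`, `p`.
#' @export
strength_reliability_correlation <- function(edge_iccs, group_mean_edges) {
  if (length(edge_iccs) != length(group_mean_edges))
    stop_netrel("edge ICCs and strengths must have equal length")
  if (stats::sd(edge_iccs) == 0 || stats::sd(group_mean_edges) == 0)
    stop_netrel("degenerate variance: correlation undefined")
  ct <- stats::cor.test(group_mean_edges, edge_iccs)
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Paired t-tests on AUC values between sessions
#'
#' Classical paired t-test (two-sided) of session-1 versus session-2
#' per-subject AUC values, one test per metric. When all paired
#' differences are exactly zero the statistic is reported as 0 with p = 1.
#'
#' @param aucs data.frame with columns `subject`, `session` (2 levels),
#'   `metric` and `value`.
#' @return Data.frame: `metric`, `t`, `df`, `p`.
#' @export
session_difference_tests <- function(aucs) {
  need <- c("subject", "session", "metric", "value")
  if (!all(need %in% names(aucs)))
    stop_netrel("aucs must have columns: ", paste(need, collapse = ", "))
  sessions <- sort(unique(aucs$session))
  if (length(sessions) != 2) stop_netrel("exactly two sessions required")
  rows <- lapply(split(aucs, aucs$metric), function(grp) {
    s1 <- grp$value[grp$session == sessions[1]][order(grp$subject[grp$session == sessions[1]])]
    s2 <- grp$value[grp$session == sessions[2]][order(grp$subject[grp$session == sessions[2]])]
    n <- length(s1)
    if (n < 3 || n != length(s2))
      stop_netrel("need paired AUCs for >= 3 subjects")
    d <- s1 - s2
    if (stats::sd(d) == 0) {
      t_stat <- if (all(d == 0)) 0 else sign(mean(d)) * Inf
      p <- if (all(d == 0)) 1 else 0
    } else {
      t_stat <- mean(d) / (stats::sd(d) / sqrt(n))
      p <- 2 * stats::pt(-abs(t_stat), n - 1)
    }
    data.frame(metric = grp$metric[1], t = t_stat, df = n - 1, p = p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Two-factor repeated-measures ANOVA on reliability values
#'
#' Within-unit sums-of-squares decomposition for a complete crossed design
#' (observational units, e.g. nodes, measured under every combination of
#' metric type and signal type). Each main effect is tested against its
#' unit-by-factor interaction; the two-way interaction against the
#' three-way residual. No sphericity correction is applied. Post-hoc
#' paired t-tests compare factor levels on unit-wise means.
#'
#' @param table data.frame with columns `unit`, `metric`, `signal`, `value`
#'   (one value per unit x metric x signal cell).
#' @return List of class `"rm_anova"`: `effects` (data.frame `effect`,
#'   `df1`, `df2`, `F`, `p`) and `posthoc` (data.frame `factor`,
#'   `level_1`, `level_2`, `t`, `df`, `p`).
#' @export
reliability_anova <- function(table) {
  need <- c("unit", "metric", "signal", "value")
  if (!all(need %in% names(table)))
    stop_netrel("table must have columns: ", paste(need, collapse = ", "))
  units <- sort(unique(table$unit))
  metrics <- sort(unique(table$metric))
  signals <- sort(unique(table$signal))
  n <- length(units); a <- length(metrics); b <- length(signals)
  Y <- array(NA_real_, c(n, a, b))
  Y[cbind(match(table$unit, units), match(table$metric, metrics),
          match(table$signal, signals))] <- table$value
  if (anyNA(Y)) stop_netrel("incomplete design: every unit needs every cell")

  g <- mean(Y)
  m_i <- apply(Y, 1, mean); m_j <- apply(Y, 2, mean); m_k <- apply(Y, 3, mean)
  m_ij <- apply(Y, c(1, 2), mean); m_ik <- apply(Y, c(1, 3), mean)
  m_jk <- apply(Y, c(2, 3), mean)

  ss_A <- b * n * sum((m_j - g)^2)
  ss_B <- a * n * sum((m_k - g)^2)
  ss_AB <- n * sum((m_jk - outer(m_j, rep(1, b)) -
                      outer(rep(1, a), m_k) + g)^2)
  ss_Aerr <- b * sum((m_ij - outer(m_i, rep(1, a)) -
                        outer(rep(1, n), m_j) + g)^2)
  ss_Berr <- a * sum((m_ik - outer(m_i, rep(1, b)) -
                        outer(rep(1, n), m_k) + g)^2)
  resid <- Y
  for (i in seq_len(n)) for (j in seq_len(a)) for (k in seq_len(b))
    resid[i, j, k] <- Y[i, j, k] - m_ij[i, j] - m_ik[i, k] - m_jk[j, k] +
      m_i[i] + m_j[j] + m_k[k] - g
  ss_ABerr <- sum(resid^2)

  f_row <- function(effect, ss_eff, df1, ss_err, df2) {
    ms_eff <- ss_eff / df1; ms_err <- ss_err / df2
    if (ms_err <= .Machine$double.eps * max(1, abs(g))) {
      f <- if (ms_eff <= .Machine$double.eps * max(1, abs(g))) 0 else Inf
      p <- if (f == 0) 1 else 0
    } else {
      f <- ms_eff / ms_err
      p <- stats::pf(f, df1, df2, lower.tail = FALSE)
    }
    data.frame(effect = effect, df1 = df1, df2 = df2, F = f, p = p)
  }
  effects <- rbind(
    f_row("metric", ss_A, a - 1, ss_Aerr, (a - 1) * (n - 1)),
    f_row("signal", ss_B, b - 1, ss_Berr, (b - 1) * (n - 1)),
    f_row("metric:signal", ss_AB, (a - 1) * (b - 1), ss_ABerr,
          (a - 1) * (b - 1) * (n - 1)))

  posthoc_pairs <- function(M, levels, factor_name) {
    combs <- utils::combn(seq_along(levels), 2)
    rows <- lapply(seq_len(ncol(combs)), function(cc) {
      d <- M[, combs[1, cc]] - M[, combs[2, cc]]
      if (stats::sd(d) == 0) {
        t_stat <- if (all(d == 0)) 0 else sign(mean(d)) * Inf
        p <- if (all(d == 0)) 1 else 0
      } else {
        t_stat <- mean(d) / (stats::sd(d) / sqrt(length(d)))
        p <- 2 * stats::pt(-abs(t_stat), length(d) - 1)
      }
      data.frame(factor = factor_name,
                 level_1 = levels[combs[1, cc]],
                 level_2 = levels[combs[2, cc]],
                 t = t_stat, df = length(d) - 1, p = p)
    })
    do.call(rbind, rows)
  }
  posthoc <- rbind(posthoc_pairs(m_ij, metrics, "metric"),
                   posthoc_pairs(m_ik, signals, "signal"))
  rownames(posthoc) <- NULL
  out <- list(effects = effects, posthoc = posthoc)
  class(out) <- "rm_anova"
  out
}

#' @export
print.rm_anova <- function(x, ...) {
  print(x$effects, row.names = FALSE)
  invisible(x)
}
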