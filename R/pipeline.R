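# End-to-end orchestration: generate/load -> preprocess -> networks ->
# metrics -> reliability -> report.

#' Build a pipeline run configuration
#'
#' One configuration object drives the whole analysis. Defaults reproduce
#' the study conditions the package emulates: 18 subjects, 46 channels,
#' 25 Hz, 11 minutes recorded of which the first minute is discarded,
#' 0.009--0.08 Hz band-pass, sparsity grid 0.01..0.99.
#'
#' @param input `"synthetic"` (generate data) or `"files"` (read a dataset
#'   written by [write_dataset()] from `input_dir`).
#' @param input_dir directory for `input = "files"`.
#' @param generator a [generator_config()] (synthetic input). Its
#'   `duration` should cover `discard_seconds` plus the retained length.
#' @param signals subset of `c("HbO", "HbR", "HbT")` to analyse.
#' @param discard_seconds initial seconds dropped before analysis.
#' @param filter list `(low_cut, high_cut, order)` for
#'   [bandpass_filter()]; `NULL` disables filtering.
#' @param ica `TRUE` to run ICA denoising before filtering (the
#'   band-pass-only and ICA arms of the analysis); extra arguments for
#'   [classify_noise_components()] can be given as a list in `ica_options`.
#' @param ica_options list of threshold overrides for the ICA noise
#'   criteria.
#' @param grid sparsity thresholds from [sparsity_grid()].
#' @param global,nodal metrics to evaluate (see [metric_curves()]).
#' @param null_config [null_model_config()] used when `gamma`, `lambda` or
#'   `sigma` are requested.
#' @param seed master seed for every stochastic stage.
#' @param out_dir output directory for the TSV/JSON result tree, or `NULL`
#'   to keep results in memory only.
#' @return An object of class `"netrel_config"`.
#' @export
netrel_config <- function(input = c("synthetic", "files"),
                          input_dir = NULL,
                          generator = generator_config(duration = 660),
                          signals = c("HbO", "HbR", "HbT"),
                          discard_seconds = 60,
                          filter = list(low_cut = 0.009, high_cut = 0.08,
                                        order = 4),
                          ica = FALSE,
                          ica_options = list(),
                          grid = sparsity_grid(),
                          global = c("Cp", "Lp", "Eloc", "Eglob", "Q",
                                     "beta", "r"),
                          nodal = c("degree", "efficiency", "betweenness"),
                          null_config = NULL,
                          seed = 1L,
                          out_dir = NULL) {
  cfg <- list(input = match.arg(input), input_dir = input_dir,
              generator = generator, signals = signals,
              discard_seconds = discard_seconds, filter = filter,
              ica = ica, ica_options = ica_options, grid = grid,
              global = global, nodal = nodal, null_config = null_config,
              seed = as.integer(seed), out_dir = out_dir)
  class(cfg) <- "netrel_config"
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks every invariant and returns all violations at once (an empty
#' character vector means the configuration is valid).
#'
#' @param config a [netrel_config()] object (or a bare list with the same
#'   fields).
#' @return Character vector of violation messages; `character(0)` if ok.
#' @export
validate_config <- function(config) {
  v <- character(0)
  say <- function(...) v <<- c(v, paste0(...))
  sig_ok <- c("HbO", "HbR", "HbT")
  if (length(config$signals) == 0) say("signals: empty signal list")
  if (!all(config$signals %in% sig_ok))
    say("signals: unknown signal(s) ",
        paste(setdiff(config$signals, sig_ok), collapse = ", "))
  if (identical(config$input, "files")) {
    if (is.null(config$input_dir) || !dir.exists(config$input_dir %||% ""))
      say("input_dir: does not exist")
  } else {
    gen <- try(validate_generator_config(config$generator), silent = TRUE)
    if (inherits(gen, "try-error"))
      say("generator: ", attr(gen, "condition")$message)
  }
  g <- config$grid
  if (length(g) == 0 || any(g <= 0) || any(g >= 1) ||
      any(diff(g) <= 0))
    say("grid: sparsity grid must be strictly increasing within (0, 1)")
  f <- config$filter
  if (!is.null(f)) {
    fs <- if (identical(config$input, "synthetic")) config$generator$fs
          else NA
    if (!(f$low_cut > 0 && f$low_cut < f$high_cut))
      say("filter: need 0 < low_cut < high_cut")
    if (!is.na(fs) && f$high_cut >= fs / 2)
      say("filter: high_cut must be below the Nyquist frequency fs/2")
  }
  if (config$discard_seconds < 0) say("discard_seconds: must be >= 0")
  wants_null <- any(c("gamma", "lambda", "sigma") %in% config$global)
  if (wants_null && is.null(config$null_config))
    say("null_config: required for gamma/lambda/sigma")
  v
}

preprocess_session <- function(ts, fs, config, warnings_env, tag) {
  if (isTRUE(config$ica)) {
    res <- withCallingHandlers(
      do.call(denoise_ica,
              c(list(data = ts, fs = fs,
                     seed = derive_seed(config$seed, "ica", tag)),
                config$ica_options)),
      warning = function(w) {
        warnings_env$warnings <- c(warnings_env$warnings,
                                   paste0("ica [", tag, "]: ",
                                          conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    ts <- res$data
  }
  if (config$discard_seconds > 0)
    ts <- discard_initial(ts, config$discard_seconds, fs)
  if (!is.null(config$filter))
    ts <- bandpass_filter(ts, config$filter$low_cut, config$filter$high_cut,
                          fs = fs, order = config$filter$order %||% 4)
  ts
}

#' Run the end-to-end reliability analysis
#'
#' Executes the full pipeline in order -- input, optional ICA denoising,
#' initial-sample discard, band-pass filtering, Pearson connectivity,
#' sparsity sweep, graph metrics, and test-retest reliability -- and
#' optionally writes the result tree (edge/global/nodal ICC tables,
#' session similarity, paired session tests, run report) as TSV + JSON.
#' Deterministic given the seed in the configuration.
#'
#' @param config a [netrel_config()].
#' @return An object of class `"netrel_run"`: per-signal results
#'   (`edge_icc`, `metric_icc`, `session_similarity`, `session_tests`,
#'   `strength_reliability`, `nodal_anova` when >1 signal), plus `report`
#'   (warnings, record counts, runtime, config echo).
#' @export
run_pipeline <- function(config) {
  t0 <- Sys.time()
  violations <- validate_config(config)
  if (length(violations))
    stop_netrel("invalid configuration:\n  ",
                paste(violations, collapse = "\n  "))
  wenv <- new.env(); wenv$warnings <- character(0)

  datasets <- if (identical(config$input, "synthetic")) {
    generate_dataset(config$generator)
  } else {
    out <- lapply(config$signals, function(sg)
      read_dataset(config$input_dir, sg))
    names(out) <- config$signals
    out
  }

  results <- list()
  nodal_auc_tables <- list()
  for (sg in config$signals) {
    ds <- datasets[[sg]]
    d <- dim(ds$data)
    n_sub <- d[1]; n_ses <- d[2]; n_ch <- d[3]
    cms <- NULL
    curve_rows <- list()
    for (i in seq_len(n_sub)) for (s in seq_len(n_ses)) {
      tag <- sprintf("%s/sub%d/ses%d", sg, i, s)
      ts <- preprocess_session(ds$data[i, s, , ], ds$fs, config, wenv, tag)
      cm <- correlation_matrix(ts)
      if (is.null(cms))
        cms <- array(NA_real_, c(n_sub, n_ses, n_ch, n_ch))
      cms[i, s, , ] <- cm
      nets <- sparsity_sweep(cm, config$grid)
      null_cfg <- config$null_config
      if (!is.null(null_cfg))
        null_cfg$seed <- derive_seed(config$seed, "null", tag)
      cr <- metric_curves(nets, grid = config$grid,
                          global = config$global, nodal = config$nodal,
                          null_config = null_cfg, cm = cm)
      cr$subject <- i; cr$session <- s
      curve_rows[[length(curve_rows) + 1]] <- cr
    }
    curves <- do.call(rbind, curve_rows)

    er <- edge_reliability(cms)
    n_clamped <- sum(er$edges$clamped, na.rm = TRUE)
    if (n_clamped > 0)
      wenv$warnings <- c(wenv$warnings,
                         sprintf("reliability [%s]: %d edge ICC(s) clamped to 0",
                                 sg, n_clamped))
    mr <- metric_reliability(curves)
    ss <- session_similarity(cms)
    pairs <- upper_pairs(n_ch)
    group_mean <- (apply(cms[, 1, , , drop = FALSE], c(3, 4), mean) +
                     apply(cms[, 2, , , drop = FALSE], c(3, 4), mean)) / 2
    sr <- strength_reliability_correlation(er$edges$icc, group_mean[pairs])

    # per-subject/session AUCs of global metrics -> paired session tests
    glb <- curves[is.na(curves$node) | curves$node == 0, ]
    auc_rows <- list()
    for (grp in split(glb, list(glb$metric, glb$subject, glb$session),
                      drop = TRUE)) {
      vals <- grp$value[order(grp$sparsity)]
      if (sum(!is.na(vals)) < 2) next
      auc_rows[[length(auc_rows) + 1]] <-
        data.frame(subject = grp$subject[1], session = grp$session[1],
                   metric = grp$metric[1],
                   value = curve_auc(vals, sort(grp$sparsity)))
    }
    aucs <- do.call(rbind, auc_rows)
    st <- if (!is.null(aucs)) session_difference_tests(aucs) else NULL

    nodal_auc <- mr$auc[mr$auc$node > 0, , drop = FALSE]
    if (nrow(nodal_auc))
      nodal_auc_tables[[sg]] <-
        data.frame(unit = nodal_auc$node, metric = nodal_auc$metric,
                   signal = sg, value = nodal_auc$auc_icc)

    results[[sg]] <- list(connectivity = cms, curves = curves,
                          edge_icc = er, metric_icc = mr,
                          session_similarity = ss, session_tests = st,
                          strength_reliability = sr)
  }

  nodal_anova <- NULL
  if (length(nodal_auc_tables) > 1) {
    nodal_anova <- reliability_anova(do.call(rbind, nodal_auc_tables))
  }

  report <- list(
    signals = config$signals,
    n_subjects = dim(datasets[[config$signals[1]]]$data)[1],
    n_channels = dim(datasets[[config$signals[1]]]$data)[3],
    n_sparsity = length(config$grid),
    n_edges = n_pairs(dim(datasets[[config$signals[1]]]$data)[3]),
    warnings = wenv$warnings,
    seed = config$seed,
    runtime_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    package_version = as.character(utils::packageVersion("netrel")))

  run <- structure(list(results = results, nodal_anova = nodal_anova,
                        report = report, config = config),
                   class = "netrel_run")
  if (!is.null(config$out_dir)) write_run(run, config$out_dir)
  run
}

#' @export
print.netrel_run <- function(x, ...) {
  r <- x$report
  cat(sprintf("<netrel_run> %d subjects, %d channels, signals: %s\n",
              r$n_subjects, r$n_channels, paste(r$signals, collapse = ", ")))
  for (sg in names(x$results)) {
    s <- x$results[[sg]]$edge_icc$summary
    cat(sprintf("  %s: mean edge ICC %.2f +/- %.2f over %d connections\n",
                sg, s$mean, s$sd, r$n_edges))
  }
  if (length(r$warnings))
    cat(sprintf("  %d warning(s); see $report$warnings\n",
                length(r$warnings)))
  invisible(x)
}

#' @export
summary.netrel_run <- function(object, ...) {
  for (sg in names(object$results)) {
    cat("==", sg, "==\n")
    print(object$results[[sg]]$edge_icc)
    auc <- object$results[[sg]]$metric_icc$auc
    glob <- auc[auc$node == 0, c("metric", "auc_icc", "grade")]
    if (nrow(glob)) {
      cat("Global-metric AUC reliability:\n")
      print(glob, row.names = FALSE)
    }
  }
  if (!is.null(object$nodal_anova)) {
    cat("== nodal metric x signal repeated-measures ANOVA ==\n")
    print(object$nodal_anova)
  }
  invisible(object)
}

write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    utils::write.table(format(df, digits = 7), file.path(dir, name),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (sg in names(run$results)) {
    res <- run$results[[sg]]
    wt(res$edge_icc$edges, sprintf("edge_icc_%s.tsv", sg))
    auc <- res$metric_icc$auc
    wt(auc[auc$node == 0, , drop = FALSE], sprintf("global_icc_%s.tsv", sg))
    if (any(auc$node > 0))
      wt(auc[auc$node > 0, , drop = FALSE], sprintf("nodal_icc_%s.tsv", sg))
    wt(res$metric_icc$profile, sprintf("icc_profile_%s.tsv", sg))
    wt(res$session_similarity, sprintf("session_similarity_%s.tsv", sg))
    if (!is.null(res$session_tests))
      wt(res$session_tests, sprintf("session_tests_%s.tsv", sg))
  }
  if (!is.null(run$nodal_anova)) {
    wt(run$nodal_anova$effects, "anova_effects.tsv")
    wt(run$nodal_anova$posthoc, "anova_posthoc.tsv")
  }
  jsonlite::write_json(run$report, file.path(dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Streamed edge-reliability study
#'
#' Generates the synthetic study one subject at a time (derived seeds) and
#' reduces each session immediately to its connectivity matrix, so large
#' cohorts (hundreds of subjects at full recording length) never have to be
#' held in memory as raw time series. Used to check that the planted
#' reliability level is recovered by the full analysis chain.
#'
#' @param config a [generator_config()]; `n_subjects` gives the cohort
#'   size.
#' @param signal which signal to analyse.
#' @param filter apply the standard 0.009--0.08 Hz band-pass first.
#' @return A `subjects x 2 x channels x channels` array of correlation
#'   matrices, ready for [edge_reliability()].
#' @export
simulate_connectivity_study <- function(config, signal = "HbO",
                                        filter = TRUE) {
  n_sub <- config$n_subjects
  n_ch <- config$n_channels
  cms <- array(NA_real_, c(n_sub, 2, n_ch, n_ch))
  for (i in seq_len(n_sub)) {
    cfg_i <- config
    cfg_i$n_subjects <- 1L
    cfg_i$seed <- derive_seed(config$seed, "stream", i)
    ds <- generate_dataset(cfg_i)[[signal]]
    for (s in 1:2) {
      ts <- ds$data[1, s, , ]
      if (filter)
        ts <- bandpass_filter(ts, 0.009, 0.08, fs = config$fs)
      cms[i, s, , ] <- correlation_matrix(ts)
    }
  }
  cms
}
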