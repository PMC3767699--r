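# Synthetic two-session resting-state hemoglobin data with a planted
# test-retest reliability level.
#
# Each subject owns a set of latent low-frequency "neural" sources that are
# reused in both sessions; each session adds its own independent latent
# sources.  The variance shares of the shared and session-specific parts are
# sqrt(rho) : sqrt(1 - rho), which makes the population edge-wise correlation
# reliability (one-way ICC of channel-pair Pearson r across sessions) equal
# to rho.  Physiological confounds (cardiac, respiratory, Mayer waves) and
# instrument noise sit on top and are removed by the band-pass stage.

#' Configuration for the synthetic hemoglobin data generator
#'
#' Defaults emulate the study conditions the package is designed around:
#' 18 subjects, 2 sessions, 46 measurement channels, 25 Hz sampling and
#' 600 s of retained signal (15,000 samples), with spontaneous neural
#' fluctuations confined to 0.009--0.08 Hz.
#'
#' @param n_subjects number of subjects.
#' @param n_channels number of measurement channels (>= 2).
#' @param fs sampling rate in Hz; must exceed twice the highest confound
#'   frequency in `noise_spec`.
#' @param duration recording length in seconds.
#' @param icc_target planted edge-reliability level in `[0, 1]`: the
#'   population intraclass correlation of edge-wise Pearson r across the
#'   two sessions.
#' @param n_latent number of latent band-limited sources per subject and
#'   per session. Small values give large between-subject spread in the
#'   connectivity structure (edge-r variance roughly `1/n_latent`).
#' @param band frequency band (Hz) of the latent neural sources.
#' @param connectivity_template optional symmetric unit-diagonal matrix;
#'   when supplied, every subject's shared component follows this latent
#'   correlation structure (between-subject variance then comes only from
#'   sampling variability) instead of subject-specific random loadings.
#' @param noise_spec list of physiological/instrument noise amplitudes, in
#'   units of the neural-signal standard deviation:
#'   `cardiac`, `respiratory`, `mayer` are `list(freq, amp)`; `instrument`
#'   is the white-noise standard deviation.
#' @param artifact_spec optional artifact description applied by
#'   [plant_artifacts()] after generation (see that function).
#' @param hbr_ratio scaling of the neural component in HbR relative to HbO;
#'   negative (anti-correlated) by default.
#' @param seed integer master seed; all draws are derived from it.
#' @return An object of class `"generator_config"`.
#' @seealso [generate_dataset()]
#' @export
generator_config <- function(n_subjects = 18L,
                             n_channels = 46L,
                             fs = 25,
                             duration = 600,
                             icc_target = 0.7,
                             n_latent = 3L,
                             band = c(0.009, 0.08),
                             connectivity_template = NULL,
                             noise_spec = list(
                               cardiac     = list(freq = 1.0, amp = 0.8),
                               respiratory = list(freq = 0.3, amp = 0.5),
                               mayer       = list(freq = 0.1, amp = 0.4),
                               instrument  = 0.3),
                             artifact_spec = NULL,
                             hbr_ratio = -0.4,
                             seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_channels = as.integer(n_channels),
              fs = fs, duration = duration,
              icc_target = icc_target, n_latent = as.integer(n_latent),
              band = band,
              connectivity_template = connectivity_template,
              noise_spec = noise_spec, artifact_spec = artifact_spec,
              hbr_ratio = hbr_ratio, seed = as.integer(seed))
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  if (cfg$n_channels < 2) stop_netrel("n_channels must be >= 2")
  if (cfg$n_subjects < 1) stop_netrel("n_subjects must be >= 1")
  if (cfg$icc_target < 0 || cfg$icc_target > 1)
    stop_netrel("icc_target must lie in [0, 1]")
  if (cfg$duration <= 0 || cfg$fs <= 0)
    stop_netrel("duration and fs must be positive")
  freqs <- vapply(cfg$noise_spec[c("cardiac", "respiratory", "mayer")],
                  function(x) if (is.list(x)) x$freq else 0, numeric(1))
  if (cfg$fs <= 2 * max(freqs, 0))
    stop_netrel("fs must exceed twice the highest confound frequency")
  tmpl <- cfg$connectivity_template
  if (!is.null(tmpl)) {
    if (!is.matrix(tmpl) || nrow(tmpl) != cfg$n_channels ||
        !isTRUE(all.equal(tmpl, t(tmpl))) ||
        !isTRUE(all.equal(diag(tmpl), rep(1, cfg$n_channels))))
      stop_netrel("connectivity_template must be a symmetric ",
                  cfg$n_channels, "x", cfg$n_channels,
                  " matrix with unit diagonal")
  }
  invisible(cfg)
}

# Band-limited unit-variance Gaussian rows: white noise hard-limited to
# `band` in the frequency domain, then rescaled per row.
band_limited_noise <- function(n_rows, n_samples, fs, band) {
  freqs <- seq(0, fs, length.out = n_samples + 1)[seq_len(n_samples)]
  freqs <- pmin(freqs, fs - freqs)  # two-sided
  keep <- freqs >= band[1] & freqs <= band[2]
  out <- matrix(0, n_rows, n_samples)
  for (r in seq_len(n_rows)) {
    spec <- stats::fft(stats::rnorm(n_samples))
    spec[!keep] <- 0
    x <- Re(stats::fft(spec, inverse = TRUE)) / n_samples
    s <- stats::sd(x)
    out[r, ] <- if (s > 0) x / s else x
  }
  out
}

# Confound + instrument noise for one session: sinusoids with random
# per-channel phase and small frequency jitter, plus white noise.
session_confounds <- function(n_channels, tt, noise_spec) {
  n_samples <- length(tt)
  out <- matrix(0, n_channels, n_samples)
  for (nm in c("cardiac", "respiratory", "mayer")) {
    comp <- noise_spec[[nm]]
    if (is.null(comp) || comp$amp == 0) next
    f <- comp$freq * (1 + stats::rnorm(n_channels, 0, 0.02))
    phase <- stats::runif(n_channels, 0, 2 * pi)
    out <- out + comp$amp * sqrt(2) *
      sin(outer(2 * pi * f, tt) + phase)  # sd = amp per channel
  }
  inst <- noise_spec$instrument
  if (!is.null(inst) && inst > 0)
    out <- out + matrix(stats::rnorm(n_channels * n_samples, 0, inst),
                        n_channels, n_samples)
  out
}

# Shared or session-specific multichannel latent component with unit
# per-channel variance. Random unit loadings onto `n_latent` band-limited
# sources, or a template correlation structure.
latent_component <- function(cfg, n_samples) {
  if (!is.null(cfg$connectivity_template)) {
    src <- band_limited_noise(cfg$n_channels, n_samples, cfg$fs, cfg$band)
    ev <- eigen(cfg$connectivity_template, symmetric = TRUE)
    L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), cfg$n_channels)
    return(L %*% src)
  }
  src <- band_limited_noise(cfg$n_latent, n_samples, cfg$fs, cfg$band)
  A <- matrix(stats::rnorm(cfg$n_channels * cfg$n_latent),
              cfg$n_channels, cfg$n_latent)
  A <- A / sqrt(rowSums(A^2))
  A %*% src
}

#' Generate a synthetic two-session multi-subject hemoglobin dataset
#'
#' Produces HbO, HbR and HbT channel-by-time series for every subject and
#' session, with a planted edge-reliability level (see
#' [generator_config()]). The identity HbT = HbO + HbR holds exactly.
#' Fully reproducible from `config$seed`.
#'
#' @param config a [generator_config()] object.
#' @return A named list of three `"ts_dataset"` objects (`HbO`, `HbR`,
#'   `HbT`), each a list with elements `data` (array
#'   subjects x sessions x channels x samples), `signal`, `fs` and
#'   `channel_ids`.
#' @examples
#' cfg <- generator_config(n_subjects = 2, n_channels = 6, fs = 5,
#'                         duration = 40, seed = 7)
#' d <- generate_dataset(cfg)
#' stopifnot(all.equal(d$HbT$data, d$HbO$data + d$HbR$data))
#' @export
generate_dataset <- function(config) {
  validate_generator_config(config)
  n_samples <- round(config$duration * config$fs)
  tt <- seq(0, by = 1 / config$fs, length.out = n_samples)
  dims <- c(config$n_subjects, 2L, config$n_channels, n_samples)
  hbo <- array(0, dims)
  hbr <- array(0, dims)

  rho <- config$icc_target
  # variance shares sqrt(rho) : sqrt(1-rho)  =>  population edge ICC = rho
  a <- rho^0.25
  b <- (1 - rho)^0.25
  nrm <- sqrt(a^2 + b^2)

  for (i in seq_len(config$n_subjects)) {
    set.seed(derive_seed(config$seed, "subject", i))
    shared <- latent_component(config, n_samples)
    for (s in 1:2) {
      set.seed(derive_seed(config$seed, "subject", i, "session", s))
      sess <- latent_component(config, n_samples)
      neural <- (a * shared + b * sess) / nrm
      hbo[i, s, , ] <- neural +
        session_confounds(config$n_channels, tt, config$noise_spec)
      hbr[i, s, , ] <- config$hbr_ratio * neural +
        abs(config$hbr_ratio) *
        session_confounds(config$n_channels, tt, config$noise_spec)
    }
  }

  ids <- sprintf("ch%02d", seq_len(config$n_channels))
  mk <- function(data, signal) {
    structure(list(data = data, signal = signal, fs = config$fs,
                   channel_ids = ids),
              class = "ts_dataset")
  }
  out <- list(HbO = mk(hbo, "HbO"), HbR = mk(hbr, "HbR"),
              HbT = mk(hbo + hbr, "HbT"))
  if (!is.null(config$artifact_spec))
    out <- lapply(out, plant_artifacts, artifact_spec = config$artifact_spec)
  out
}

#' @export
print.ts_dataset <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<ts_dataset> %s: %d subjects x %d sessions x %d channels x %d samples @ %g Hz\n",
    x$signal, d[1], d[2], d[3], d[4], x$fs))
  invisible(x)
}

#' Plant artifacts into a dataset
#'
#' Adds motion/interference artifacts of the archetypes seen in optical
#' recordings: sudden step jumps, slowly varying U / inverted-U bumps,
#' trains of fast spikes, and a rank-one spatially global oscillation.
#' The unmodified input is retained in the `clean` element of the result so
#' denoising can be scored against ground truth.
#'
#' @param dataset a `"ts_dataset"` object.
#' @param artifact_spec a list of artifact descriptions. Each element is a
#'   list with `type` in `c("step", "bump", "spikes", "global")` and fields:
#'   `subject`, `session` (indices; `NULL` = all), `channels` (indices;
#'   `NULL` = all for "global", required otherwise), `onset` seconds,
#'   `amplitude`; additionally `duration` (seconds; "bump"/"spikes"),
#'   `times` (explicit spike times, seconds) or `n_spikes` + `seed`
#'   ("spikes"), `freq` (Hz) and optional `weights` ("global").
#' @return A `"ts_dataset"` with artifacts added and `$clean` holding the
#'   input data array.
#' @export
plant_artifacts <- function(dataset, artifact_spec) {
  stopifnot(inherits(dataset, "ts_dataset"))
  out <- dataset
  out$clean <- dataset$data
  if (length(artifact_spec) == 0) return(out)
  fs <- dataset$fs
  d <- dim(dataset$data)
  n_samples <- d[4]
  dur <- n_samples / fs
  tt <- seq(0, by = 1 / fs, length.out = n_samples)

  for (art in artifact_spec) {
    if (is.null(art$type))
      stop_netrel("each artifact needs a 'type'")
    if (!is.finite(art$amplitude %||% NA))
      stop_netrel("artifact amplitude must be finite")
    if ((art$onset %||% 0) < 0 || (art$onset %||% 0) >= dur)
      stop_netrel("artifact onset outside recording duration")
    subjects <- art$subject %||% seq_len(d[1])
    sessions <- art$session %||% seq_len(d[2])
    channels <- art$channels %||% seq_len(d[3])
    course <- switch(art$type,
      step = art$amplitude * (tt >= art$onset),
      bump = {
        len <- art$duration %||% (dur / 10)
        inside <- tt >= art$onset & tt <= art$onset + len
        w <- numeric(n_samples)
        w[inside] <- 0.5 * (1 - cos(2 * pi * (tt[inside] - art$onset) / len))
        art$amplitude * w
      },
      spikes = {
        times <- art$times
        if (is.null(times)) {
          set.seed(art$seed %||% 1L)
          times <- stats::runif(art$n_spikes %||% 12L, art$onset,
                                min(dur, art$onset + (art$duration %||% dur)))
        }
        w <- numeric(n_samples)
        idx <- pmin(pmax(round(times * fs) + 1, 1), n_samples)
        w[idx] <- 1
        art$amplitude * w
      },
      global = art$amplitude *
        sin(2 * pi * (art$freq %||% 0.5) * tt + (art$phase %||% 0)),
      stop_netrel("unknown artifact type: ", art$type))

    if (art$type == "global") {
      weights <- art$weights %||% rep(1, d[3])
      for (i in subjects) for (s in sessions)
        out$data[i, s, , ] <- out$data[i, s, , ] +
          outer(weights, course)
    } else {
      for (i in subjects) for (s in sessions) for (ch in channels)
        out$data[i, s, ch, ] <- out$data[i, s, ch, ] + course
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a dataset as one TSV per subject/session plus a JSON manifest
#'
#' Rows are channels (first column = channel id), columns are samples with a
#' header row of sample indices. The manifest records sampling rate, signal
#' type, channel ids and the generator seed when known.
#'
#' @param dataset a `"ts_dataset"`.
#' @param dir output directory (created if missing).
#' @param config optional [generator_config()] echoed into the manifest.
#' @return Invisibly, the manifest path.
#' @export
write_dataset <- function(dataset, dir, config = NULL) {
  stopifnot(inherits(dataset, "ts_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(dataset$data)
  files <- character(0)
  for (i in seq_len(d[1])) for (s in seq_len(d[2])) {
    f <- file.path(dir, sprintf("sub%03d_ses%d_%s.tsv", i, s, dataset$signal))
    m <- dataset$data[i, s, , , drop = TRUE]
    df <- data.frame(channel = dataset$channel_ids, m, check.names = FALSE)
    names(df) <- c("channel", seq_len(d[4]))
    utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, basename(f))
  }
  manifest <- list(signal = dataset$signal, fs = dataset$fs,
                   channel_ids = dataset$channel_ids,
                   n_subjects = d[1], n_sessions = d[2],
                   n_channels = d[3], n_samples = d[4],
                   files = files)
  if (!is.null(config))
    manifest$generator <- list(seed = config$seed,
                               icc_target = config$icc_target,
                               n_latent = config$n_latent,
                               band = config$band)
  mf <- file.path(dir, sprintf("manifest_%s.json", dataset$signal))
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mf)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir directory holding the TSV files and manifest.
#' @param signal which signal to read (`"HbO"`, `"HbR"` or `"HbT"`).
#' @return A `"ts_dataset"`.
#' @export
read_dataset <- function(dir, signal = "HbO") {
  mf <- file.path(dir, sprintf("manifest_%s.json", signal))
  if (!file.exists(mf)) stop_netrel("manifest not found: ", mf)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  dims <- c(manifest$n_subjects, manifest$n_sessions,
            manifest$n_channels, manifest$n_samples)
  data <- array(NA_real_, dims)
  k <- 0
  for (i in seq_len(dims[1])) for (s in seq_len(dims[2])) {
    k <- k + 1
    df <- utils::read.table(file.path(dir, manifest$files[k]), sep = "\t",
                            header = TRUE, check.names = FALSE)
    data[i, s, , ] <- as.matrix(df[, -1])
  }
  structure(list(data = data, signal = manifest$signal, fs = manifest$fs,
                 channel_ids = manifest$channel_ids),
            class = "ts_dataset")
}
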