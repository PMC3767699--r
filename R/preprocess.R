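# Conversion and cleaning of hemoglobin time series.

#' Default molar extinction coefficients for 690 and 830 nm
#'
#' Tabulated extinction coefficients of oxy- and deoxyhemoglobin
#' (cm^-1 mM^-1, Gratzer/Kollias compilation) at the two wavelengths used
#' by dual-wavelength continuous-wave instruments. Rows are wavelengths,
#' columns are `HbO` and `HbR`. Values affect the concentration scale only,
#' not correlation-based networks; override for other instruments.
#'
#' @return A 2x2 numeric matrix with dimnames.
#' @export
extinction_defaults <- function() {
  matrix(c(0.2764, 2.0520,
           0.9740, 0.6930),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("690", "830"), c("HbO", "HbR")))
}

#' Modified Beer-Lambert conversion of optical density to hemoglobin
#'
#' Inverts the 2x2 extinction-coefficient system per channel and sample:
#' `dOD_lambda = (eps_HbO * dHbO + eps_HbR * dHbR) * distance * DPF_lambda`.
#'
#' @param delta_od_690,delta_od_830 channel-by-time matrices of optical
#'   density changes at the two wavelengths (same shape).
#' @param source_detector_distance source-detector separation in cm
#'   (default 3.2).
#' @param dpf_690,dpf_830 differential pathlength factors (default 6.0).
#' @param extinction_table 2x2 matrix as in [extinction_defaults()].
#' @return List with channel-by-time matrices `HbO`, `HbR` and
#'   `HbT = HbO + HbR` (concentration changes, mM when extinction is in
#'   cm^-1 mM^-1).
#' @examples
#' hbo <- matrix(rnorm(20), 2); hbr <- -0.4 * hbo
#' E <- extinction_defaults()
#' od690 <- (E[1, 1] * hbo + E[1, 2] * hbr) * 3.2 * 6
#' od830 <- (E[2, 1] * hbo + E[2, 2] * hbr) * 3.2 * 6
#' rec <- mbll_convert(od690, od830)
#' stopifnot(all.equal(rec$HbO, hbo))
#' @export
mbll_convert <- function(delta_od_690, delta_od_830,
                         source_detector_distance = 3.2,
                         dpf_690 = 6.0, dpf_830 = 6.0,
                         extinction_table = extinction_defaults()) {
  if (!all(dim(delta_od_690) == dim(delta_od_830)))
    stop_netrel("the two wavelength arrays must have the same shape")
  if (source_detector_distance <= 0)
    stop_netrel("source-detector distance must be positive")
  E <- extinction_table * c(dpf_690, dpf_830) * source_detector_distance
  if (abs(det(E)) < .Machine$double.eps * 100)
    stop_netrel("extinction matrix is singular; wavelengths do not separate HbO/HbR")
  Einv <- solve(E)
  hbo <- Einv[1, 1] * delta_od_690 + Einv[1, 2] * delta_od_830
  hbr <- Einv[2, 1] * delta_od_690 + Einv[2, 2] * delta_od_830
  list(HbO = hbo, HbR = hbr, HbT = hbo + hbr)
}

#' Discard the initial seconds of a recording
#'
#' Drops the first `round(seconds * fs)` samples of each channel, the usual
#' step for removing the unstable settling period at the start of an
#' optical recording.
#'
#' @param ts channel-by-time matrix (or vector).
#' @param seconds seconds to discard.
#' @param fs sampling rate in Hz.
#' @return Matrix (or vector) with the remaining samples.
#' @export
discard_initial <- function(ts, seconds, fs) {
  vec <- is.null(dim(ts))
  if (vec) ts <- matrix(ts, nrow = 1)
  n_drop <- round(seconds * fs)
  if (n_drop >= ncol(ts))
    stop_netrel("discard (", n_drop, " samples) must be shorter than the recording")
  out <- ts[, (n_drop + 1):ncol(ts), drop = FALSE]
  if (vec) drop(out) else out
}

#' Zero-phase band-pass filter
#'
#' Butterworth band-pass applied forward and backward (zero phase shift).
#' The pass band is realised as a cascade of a high-pass at `low_cut` and a
#' low-pass at `high_cut`, each of order `order`, after per-channel mean
#' removal; at the very narrow relative bands used for slow hemodynamics
#' (0.009--0.08 Hz at 25 Hz sampling) this cascade is numerically stable
#' where a directly designed band-pass in transfer-function form is not.
#'
#' @param ts channel-by-time matrix (or vector).
#' @param low_cut,high_cut cutoff frequencies in Hz
#'   (`0 < low_cut < high_cut < fs/2`).
#' @param fs sampling rate in Hz.
#' @param order Butterworth order of each cascade stage (default 4).
#' @return Filtered series, same shape as the input.
#' @export
bandpass_filter <- function(ts, low_cut = 0.009, high_cut = 0.08, fs,
                            order = 4) {
  if (!(low_cut > 0 && low_cut < high_cut && high_cut < fs / 2))
    stop_netrel("need 0 < low_cut < high_cut < fs/2")
  vec <- is.null(dim(ts))
  if (vec) ts <- matrix(ts, nrow = 1)
  hp <- signal::butter(order, low_cut / (fs / 2), type = "high")
  lp <- signal::butter(order, high_cut / (fs / 2), type = "low")
  out <- ts
  for (ch in seq_len(nrow(ts))) {
    x <- ts[ch, ] - mean(ts[ch, ])
    out[ch, ] <- signal::filtfilt(lp, signal::filtfilt(hp, x))
  }
  if (vec) drop(out) else out
}

#' Principal component reduction retaining a target variance fraction
#'
#' Returns the smallest number `m` of principal components whose cumulative
#' eigenvalue share exceeds `variance_target` (at least one component).
#'
#' @param data channel-by-time matrix (channels are variables).
#' @param variance_target fraction of variance to retain (default 0.99).
#' @return List: `m`, `scores` (m x samples), `loadings` (channels x m),
#'   `center` per-channel means, `eigenvalues`, `variance_retained`.
#' @export
pca_reduce <- function(data, variance_target = 0.99) {
  if (nrow(data) < 2) stop_netrel("need >= 2 channels")
  if (!all(is.finite(data))) stop_netrel("data must be finite")
  center <- rowMeans(data)
  xc <- data - center
  cv <- (xc %*% t(xc)) / (ncol(data) - 1)
  if (max(abs(cv)) == 0) stop_netrel("all-zero data has no principal components")
  ev <- eigen(cv, symmetric = TRUE)
  share <- cumsum(ev$values) / sum(ev$values)
  m <- which(share > variance_target)[1]
  if (is.na(m)) m <- length(ev$values)
  m <- max(1L, m)
  loadings <- ev$vectors[, seq_len(m), drop = FALSE]
  list(m = m,
       scores = t(loadings) %*% xc,
       loadings = loadings,
       center = center,
       eigenvalues = ev$values,
       variance_retained = share[m])
}
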