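# ICA-based artifact removal: PCA-whitened deflation ICA with a
# skewness-based contrast, three noise-component criteria, and
# reconstruction with flagged mixing-matrix columns zeroed.

#' Deflation ICA on PCA-whitened data
#'
#' Fixed-point independent component analysis in deflation mode: the data
#' are centred, reduced to `n_components` principal components, whitened,
#' and unmixing vectors extracted one at a time with Gram-Schmidt
#' orthogonalisation. The default contrast is skewness
#' (`g(u) = u^2`), suited to the asymmetric motion artifacts this stage is
#' meant to isolate; `"pow3"` (kurtosis) is available for symmetric
#' sources.
#'
#' @param data channel-by-time matrix.
#' @param n_components number of components (defaults to the 99%-variance
#'   PCA rule of [pca_reduce()]); must not exceed the channel count.
#' @param seed integer seed for the random initial vectors.
#' @param nonlinearity `"skew"` (default) or `"pow3"`.
#' @param max_iter,tol fixed-point iteration controls.
#' @return An object of class `"ica_decomposition"`: `sources`
#'   (components x samples, unit variance), `mixing`
#'   (channels x components), `center`, `pca` (the [pca_reduce()] result),
#'   `converged` per-component logical, `n_components`. The reconstruction
#'   `mixing %*% sources + center` equals the PCA-retained data.
#' @export
ica_decompose <- function(data, n_components = NULL, seed = 1L,
                          nonlinearity = c("skew", "pow3"),
                          max_iter = 500L, tol = 1e-8) {
  nonlinearity <- match.arg(nonlinearity)
  pca <- pca_reduce(data, variance_target = 0.99)
  if (is.null(n_components)) n_components <- pca$m
  if (n_components > nrow(data))
    stop_netrel("n_components must not exceed the number of channels")
  if (n_components > pca$m) {
    # re-run PCA keeping enough components
    pca <- pca_reduce(data, variance_target = 1 - 1e-12)
    n_components <- min(n_components, pca$m)
  }
  K <- n_components
  scores <- pca$scores[seq_len(K), , drop = FALSE]
  sdev <- sqrt(pmax(pca$eigenvalues[seq_len(K)], .Machine$double.eps))
  z <- scores / sdev                       # whitened: cov(z') = I
  n <- ncol(z)

  set.seed(seed)
  W <- matrix(0, K, K)                     # rows: unmixing vectors
  converged <- logical(K)
  for (k in seq_len(K)) {
    w <- stats::rnorm(K)
    w <- w / sqrt(sum(w^2))
    for (it in seq_len(max_iter)) {
      u <- drop(crossprod(z, w))           # length n
      w_new <- if (nonlinearity == "skew") {
        drop(z %*% u^2) / n
      } else {
        drop(z %*% u^3) / n - 3 * w
      }
      # deflation: orthogonalise against previously found vectors
      if (k > 1) {
        prev <- W[seq_len(k - 1), , drop = FALSE]
        w_new <- w_new - drop(t(prev) %*% (prev %*% w_new))
      }
      nw <- sqrt(sum(w_new^2))
      if (nw < .Machine$double.eps) break  # degenerate direction
      w_new <- w_new / nw
      delta <- abs(abs(sum(w_new * w)) - 1)
      w <- w_new
      if (delta < tol) { converged[k] <- TRUE; break }
    }
    W[k, ] <- w
  }
  if (!all(converged))
    warning(sum(!converged), " of ", K,
            " ICA components did not converge; partial result returned")

  sources <- W %*% z                       # unit-variance sources
  # channel-space mixing: data_centered ~ loadings %*% diag(sdev) %*% W' %*% sources
  mixing <- pca$loadings[, seq_len(K), drop = FALSE] %*%
    (t(W) * sdev)
  structure(list(sources = sources, mixing = mixing, center = pca$center,
                 pca = pca, converged = converged, n_components = K),
            class = "ica_decomposition")
}

#' @export
print.ica_decomposition <- function(x, ...) {
  cat(sprintf("<ica_decomposition> %d components x %d samples (%d converged)\n",
              x$n_components, ncol(x$sources), sum(x$converged)))
  invisible(x)
}

welch_dominant_freq <- function(x, fs, seg_len = min(length(x), 4096L)) {
  n <- length(x)
  starts <- seq(1, max(1, n - seg_len + 1), by = max(1, seg_len %/% 2))
  win <- 0.5 * (1 - cos(2 * pi * seq_len(seg_len) / (seg_len + 1)))  # Hann
  acc <- numeric(seg_len)
  for (st in starts) {
    seg <- x[st:(st + seg_len - 1)]
    seg <- (seg - mean(seg)) * win
    acc <- acc + Mod(stats::fft(seg))^2
  }
  half <- 2:(seg_len %/% 2 + 1)            # exclude DC
  freqs <- (half - 1) * fs / seg_len
  freqs[which.max(acc[half])]
}

# participation ratio: effective number of channels a mixing column loads on
participation_ratio <- function(a) {
  s2 <- sum(a^2)
  if (s2 == 0) return(0)
  s2^2 / sum(a^4)
}

#' Classify ICA components as noise
#'
#' A component is flagged as noise if ANY of three criteria fires:
#' (i) temporal anomaly -- its first differences contain a jump exceeding
#' `jump_z` robust z-scores, or at least `spike_count` separate excursions
#' beyond `spike_z` robust z-scores (sudden jumps, slow U-shaped bumps and
#' spike trains all present as such excursions);
#' (ii) the dominant frequency of its Welch power spectrum lies outside
#' `spectral_band`;
#' (iii) its mixing column is spatially dispersive -- the participation
#' ratio exceeds `dispersion_fraction` of the channels, the signature of
#' global superficial interference.
#'
#' @param decomp an [ica_decompose()] result.
#' @param fs sampling rate in Hz.
#' @param spectral_band acceptable dominant-frequency band in Hz
#'   (default `c(0.01, 0.1)`).
#' @param jump_z,spike_z,spike_count,dispersion_fraction thresholds; the
#'   identification of such components is partly a judgement call, so all
#'   thresholds are explicit and tunable.
#' @return A data.frame with one row per component: `noise` (any criterion)
#'   and per-criterion flags `temporal`, `spectral`, `spatial`, plus the
#'   diagnostics `dominant_freq`, `participation_ratio`, `max_jump_z`,
#'   `spike_events`.
#' @export
classify_noise_components <- function(decomp, fs,
                                      spectral_band = c(0.01, 0.1),
                                      jump_z = 6, spike_z = 5,
                                      spike_count = 10L,
                                      dispersion_fraction = 0.7) {
  stopifnot(inherits(decomp, "ica_decomposition"))
  K <- decomp$n_components
  if (K == 0)
    return(data.frame(component = integer(0), noise = logical(0),
                      temporal = logical(0), spectral = logical(0),
                      spatial = logical(0)))
  n_channels <- nrow(decomp$mixing)
  out <- data.frame(component = seq_len(K), noise = FALSE,
                    temporal = FALSE, spectral = FALSE, spatial = FALSE,
                    dominant_freq = NA_real_,
                    participation_ratio = NA_real_,
                    max_jump_z = NA_real_, spike_events = NA_integer_)
  for (k in seq_len(K)) {
    s <- decomp$sources[k, ]
    d <- diff(s)
    scale <- stats::mad(d)
    if (scale == 0) scale <- stats::sd(d)      # degenerate: >half of diffs tied
    z <- if (isTRUE(scale > 0)) abs(d - stats::median(d)) / scale
         else rep(0, length(d))
    out$max_jump_z[k] <- if (length(z)) max(z) else 0
    runs <- rle(z > spike_z)
    out$spike_events[k] <- sum(runs$values)
    out$temporal[k] <- out$max_jump_z[k] > jump_z ||
      out$spike_events[k] >= spike_count
    out$dominant_freq[k] <- welch_dominant_freq(s, fs)
    out$spectral[k] <- out$dominant_freq[k] < spectral_band[1] ||
      out$dominant_freq[k] > spectral_band[2]
    out$participation_ratio[k] <- participation_ratio(decomp$mixing[, k])
    out$spatial[k] <- out$participation_ratio[k] >
      dispersion_fraction * n_channels
  }
  out$noise <- out$temporal | out$spectral | out$spatial
  out
}

#' Reconstruct the data without flagged components
#'
#' Rebuilds the channel-by-time data from the ICA decomposition with the
#' flagged columns of the mixing matrix set to zero, then restores the
#' channel means. With no flags this is the PCA-retained data.
#'
#' @param decomp an [ica_decompose()] result.
#' @param flags logical vector, one per component (`TRUE` = remove), or the
#'   data.frame from [classify_noise_components()] (its `noise` column is
#'   used).
#' @return Denoised channel-by-time matrix.
#' @export
reconstruct_without <- function(decomp, flags) {
  stopifnot(inherits(decomp, "ica_decomposition"))
  if (is.data.frame(flags)) flags <- flags$noise
  if (length(flags) != decomp$n_components)
    stop_netrel("flags length must equal the number of components")
  mixing <- decomp$mixing
  mixing[, flags] <- 0
  if (all(flags))
    warning("all components flagged; returning channel means")
  mixing %*% decomp$sources + decomp$center
}

#' One-call ICA denoising of a channel-by-time matrix
#'
#' Convenience wrapper: [pca_reduce()] (99% variance) + [ica_decompose()] +
#' [classify_noise_components()] + [reconstruct_without()].
#'
#' @inheritParams ica_decompose
#' @inheritParams classify_noise_components
#' @param ... further arguments passed to [classify_noise_components()].
#' @return List: `data` (denoised matrix), `flags` (component report),
#'   `decomposition`.
#' @export
denoise_ica <- function(data, fs, seed = 1L,
                        nonlinearity = "skew", ...) {
  decomp <- ica_decompose(data, seed = seed, nonlinearity = nonlinearity)
  flags <- classify_noise_components(decomp, fs = fs, ...)
  denoised <- reconstruct_without(decomp, flags)
  list(data = denoised, flags = flags, decomposition = decomp)
}
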