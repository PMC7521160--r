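# Welch power spectra with duration-weighted trial averaging, and power-law
# (1/f) adjustment to expose narrowband peaks.

# Welch PSD of a single contiguous segment. Hann taper, zero-padding to the
# next power of two, one-sided density in units^2/Hz.
welch_single <- function(x, fs, window_s = 3, overlap = 0.8) {
  wlen <- round(window_s * fs)
  if (length(x) < wlen) stop("segment shorter than one Welch window")
  hop <- max(1L, round(wlen * (1 - overlap)))
  starts <- seq(1L, length(x) - wlen + 1L, by = hop)
  w <- hann_window(wlen)
  nfft <- next_pow2(wlen)
  scale <- fs * sum(w^2)
  nb <- nfft %/% 2 + 1L
  acc <- numeric(nb)
  for (s in starts) {
    seg <- x[s:(s + wlen - 1L)] * w
    X <- stats::fft(c(seg, numeric(nfft - wlen)))
    pxx <- Mod(X[1:nb])^2 / scale
    pxx[2:(nb - 1L)] <- 2 * pxx[2:(nb - 1L)]
    acc <- acc + pxx
  }
  list(freqs = (0:(nb - 1L)) * fs / nfft, power = acc / length(starts),
       n_windows = length(starts))
}

#' Welch power spectral density over artifact-free trials
#'
#' Per-trial Welch estimates (Hann windows of `window_s` seconds with
#' `overlap` fractional overlap, each window zero-padded to the next power of
#' two; 3-s windows at 1 kHz give the 0.244-Hz bin spacing), averaged across
#' trials with trial durations as weights. Windows never cross a trial
#' boundary.
#'
#' @param x Numeric series for one channel (full recording).
#' @param fs Sampling rate in Hz.
#' @param trials Data frame with columns `start` and `end` (1-based sample
#'   indices, `end` exclusive), each trial at least `window_s` long.
#' @param window_s Window length in seconds (default 3).
#' @param overlap Fractional window overlap (default 0.8).
#' @return Object of class `psd_spectrum`: `freqs` (Hz), `power` (uV^2/Hz),
#'   `total_weight` (seconds of data), `resolution` (Hz).
#' @export
welch_psd <- function(x, fs, trials, window_s = 3, overlap = 0.8) {
  if (is.null(trials) || nrow(trials) == 0) stop("empty input: no trials")
  power <- NULL
  wsum <- 0
  freqs <- NULL
  for (i in seq_len(nrow(trials))) {
    seg <- x[trials$start[i]:(trials$end[i] - 1L)]
    est <- welch_single(seg, fs, window_s, overlap)
    wgt <- length(seg) / fs
    if (is.null(power)) {
      power <- est$power * wgt
      freqs <- est$freqs
    } else {
      power <- power + est$power * wgt
    }
    wsum <- wsum + wgt
  }
  structure(list(freqs = freqs, power = power / wsum, total_weight = wsum,
                 resolution = freqs[2] - freqs[1]),
            class = "psd_spectrum")
}

#' @export
print.psd_spectrum <- function(x, ...) {
  cat(sprintf("Welch PSD: %d bins, %.4g-Hz resolution, %.1f s of data\n",
              length(x$freqs), x$resolution, x$total_weight))
  invisible(x)
}

#' Remove the 1/f component of a power spectrum
#'
#' Notch-filtered regions (centers +- half-width) are first replaced by
#' modified Akima interpolation from the flanking bins. A power law `a f^b` is
#' then fitted by ordinary least squares on log10 power versus log10 frequency
#' over `fit_range` and subtracted from the observed spectrum. The residual is
#' resampled onto `n_log` log-spaced frequencies and smoothed `smooth_passes`
#' times with a centered moving average of `smooth_window` bins (windows
#' shrink symmetrically at the edges).
#'
#' @param spectrum A [welch_psd()] object covering at least 0.5-200 Hz.
#' @param fit_range Frequency range of the power-law fit in Hz
#'   (default `c(4, 175)`).
#' @param notch_centers_hz Line-noise centers to interpolate over
#'   (default `c(50, 100, 150, 200)`).
#' @param notch_halfwidth_hz Half-width of each interpolated region
#'   (default 5).
#' @param resample_range Range of the log-spaced output grid (default
#'   `c(0.5, 200)` Hz).
#' @param n_log Number of log-spaced output bins (default 200).
#' @param smooth_window,smooth_passes Moving-average width and number of
#'   passes (defaults 5 and 3).
#' @return Object of class `adjusted_spectrum`: `freqs_log`, `adjusted_power`
#'   (residual, may be negative), `fit_a`, `fit_b`, plus the
#'   notch-interpolated full-resolution spectrum (`freqs`, `power_interp`,
#'   `residual`).
#' @export
adjust_one_over_f <- function(spectrum, fit_range = c(4, 175),
                              notch_centers_hz = c(50, 100, 150, 200),
                              notch_halfwidth_hz = 5,
                              resample_range = c(0.5, 200), n_log = 200,
                              smooth_window = 5, smooth_passes = 3) {
  stopifnot(inherits(spectrum, "psd_spectrum"))
  f <- spectrum$freqs
  p <- spectrum$power
  if (min(f) > 0.5 || max(f) < 200) stop("spectrum must cover 0.5-200 Hz")

  in_notch <- rep(FALSE, length(f))
  for (cf in notch_centers_hz) {
    in_notch <- in_notch | (f >= cf - notch_halfwidth_hz &
                            f <= cf + notch_halfwidth_hz)
  }
  p_interp <- p
  if (any(in_notch)) {
    src <- !in_notch & f > 0
    p_interp[in_notch] <- makima_interp(f[src], p[src], f[in_notch])
  }

  fit_idx <- which(f >= fit_range[1] & f <= fit_range[2])
  if (any(p_interp[fit_idx] <= 0)) {
    stop("fit-domain error: nonpositive power inside the fit range")
  }
  fit <- stats::lm.fit(cbind(1, log10(f[fit_idx])), log10(p_interp[fit_idx]))
  b <- unname(fit$coefficients[2])
  a <- 10^unname(fit$coefficients[1])

  residual <- p_interp - a * f^b
  freqs_log <- 10^seq(log10(resample_range[1]), log10(resample_range[2]),
                      length.out = n_log)
  pos <- f > 0
  adj <- stats::approx(log10(f[pos]), residual[pos], xout = log10(freqs_log),
                       rule = 2)$y
  for (i in seq_len(smooth_passes)) adj <- moving_average_shrink(adj, smooth_window)

  structure(list(freqs_log = freqs_log, adjusted_power = adj,
                 fit_a = a, fit_b = b,
                 freqs = f, power_interp = p_interp, residual = residual),
            class = "adjusted_spectrum")
}

#' @export
print.adjusted_spectrum <- function(x, ...) {
  cat(sprintf("1/f-adjusted spectrum: a = %.4g, b = %.3f; %d log-spaced bins %.3g-%.4g Hz\n",
              x$fit_a, x$fit_b, length(x$freqs_log),
              min(x$freqs_log), max(x$freqs_log)))
  invisible(x)
}

#' Export a spectrum as delimited text
#'
#' @param spectrum A [welch_psd()] object.
#' @param adjusted Optional matching [adjust_one_over_f()] object.
#' @param path Output path (tab-separated).
#' @export
export_spectrum <- function(spectrum, path, adjusted = NULL) {
  df <- data.frame(freq_hz = spectrum$freqs, power = spectrum$power)
  if (!is.null(adjusted)) {
    df$adjusted_power <- stats::approx(log10(adjusted$freqs_log),
                                       adjusted$adjusted_power,
                                       xout = log10(pmax(df$freq_hz, 1e-6)),
                                       rule = 2)$y
  }
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
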