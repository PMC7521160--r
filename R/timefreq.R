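#' Build a family of FWHM-parametrized complex Morlet wavelets
#'
#' Wavelets are defined by their temporal resolution: kernel
#' `exp(i 2 pi f t) * exp(-4 ln(2) t^2 / h^2)`, where `h` is the full width at
#' half maximum (FWHM) of the Gaussian envelope in seconds. Center frequencies
#' are logarithmically spaced, as are the temporal FWHMs (wide at low
#' frequencies, narrow at high frequencies), trading spectral for temporal
#' precision across the axis. The resulting spectral FWHM of a kernel is
#' `4 ln(2) / (pi h)` (0.3 Hz at h = 3 s, 35 Hz at h = 0.025 s).
#'
#' @param fs Sampling rate in Hz (must be at least twice the highest center
#'   frequency).
#' @param n_freqs Number of center frequencies (default 50).
#' @param f_range Frequency range in Hz (default `c(0.5, 200)`).
#' @param h_range Temporal FWHM at the lowest and highest frequency, in
#'   seconds (default `c(3, 0.025)`).
#' @return Object of class `wavelet_family`: `freqs`, `fwhm_s`, `kernels`
#'   (complex, unit energy, truncated where the envelope falls below 1e-4 of
#'   its peak), `fs`.
#' @export
build_wavelets <- function(fs, n_freqs = 50, f_range = c(0.5, 200),
                           h_range = c(3, 0.025)) {
  if (fs < 2 * max(f_range)) {
    stop("invalid parameter: fs must be at least twice the maximum frequency")
  }
  freqs <- 10^seq(log10(f_range[1]), log10(f_range[2]), length.out = n_freqs)
  fwhm <- 10^seq(log10(h_range[1]), log10(h_range[2]), length.out = n_freqs)
  kernels <- vector("list", n_freqs)
  for (k in seq_len(n_freqs)) {
    h <- fwhm[k]
    # envelope exp(-4 ln2 t^2/h^2) >= 1e-4 -> |t| <= h * sqrt(ln(1e4)/(4 ln2))
    tmax <- h * sqrt(log(1e4) / (4 * log(2)))
    m <- ceiling(tmax * fs)
    t <- (-m:m) / fs
    w <- exp(2i * pi * freqs[k] * t) * exp(-4 * log(2) * t^2 / h^2)
    kernels[[k]] <- w / sqrt(sum(Mod(w)^2))
  }
  structure(list(freqs = freqs, fwhm_s = fwhm, kernels = kernels, fs = fs),
            class = "wavelet_family")
}

#' @export
print.wavelet_family <- function(x, ...) {
  cat(sprintf("Morlet wavelet family: %d log-spaced frequencies %.3g-%.4g Hz at fs = %g Hz\n",
              length(x$freqs), min(x$freqs), max(x$freqs), x$fs))
  cat(sprintf("temporal FWHM %.3g s -> %.3g s (spectral FWHM %.2g -> %.3g Hz)\n",
              x$fwhm_s[1], x$fwhm_s[length(x$fwhm_s)],
              4 * log(2) / (pi * x$fwhm_s[1]),
              4 * log(2) / (pi * x$fwhm_s[length(x$fwhm_s)])))
  invisible(x)
}

#' Measure the spectral FWHM of a wavelet kernel
#'
#' Empirical full width at half maximum of the kernel's amplitude spectrum,
#' computed on a finely zero-padded FFT grid.
#'
#' @param family A [build_wavelets()] object.
#' @param k Kernel index.
#' @return Width in Hz.
#' @export
wavelet_spectral_fwhm <- function(family, k) {
  w <- family$kernels[[k]]
  fs <- family$fs
  nfft <- max(next_pow2(length(w)) * 16, 2^16)
  spec <- Mod(stats::fft(c(w, complex(real = numeric(nfft - length(w))))))
  f <- (0:(nfft - 1)) * fs / nfft
  half <- max(spec) / 2
  above <- which(spec >= half)
  # kernel is analytic: spectrum concentrated around +f, no wrap in practice;
  # half-maximum edges located to sub-bin precision by linear interpolation
  i1 <- min(above)
  i2 <- max(above)
  f_lo <- if (i1 > 1) {
    stats::approx(spec[c(i1 - 1, i1)], f[c(i1 - 1, i1)], xout = half)$y
  } else f[i1]
  f_hi <- if (i2 < nfft) {
    stats::approx(spec[c(i2, i2 + 1)], f[c(i2, i2 + 1)], xout = half)$y
  } else f[i2]
  f_hi - f_lo
}

#' Complex Morlet time-frequency decomposition of one trial
#'
#' The trial is mirror-extended by `pad_s` seconds on each side to limit edge
#' artifacts, convolved with every kernel, trimmed back, and decimated by
#' `downsample` (keeping samples 1, 1+downsample, ...; the magnitude and phase
#' series are already band-limited by the wavelet, so no anti-alias filter is
#' applied).
#'
#' @param x Numeric series (one trial, at least 3 s).
#' @param fs Sampling rate in Hz.
#' @param family A [build_wavelets()] object built at the same `fs`.
#' @param pad_s Mirror padding per side in seconds (default 5).
#' @param downsample Decimation factor (default 4).
#' @param start_sample Index of the trial's first sample in the recording
#'   (1-based); used to keep a map from output columns to recording time.
#' @return Complex matrix `n_freqs x ceiling(length(x)/downsample)` with
#'   attributes `freqs`, `fs_eff`, and `col_sample` (recording sample index of
#'   each column).
#' @export
tf_decompose <- function(x, fs, family, pad_s = 5, downsample = 4,
                         start_sample = 1L) {
  stopifnot(inherits(family, "wavelet_family"), family$fs == fs)
  n <- length(x)
  if (n < 3 * fs) stop("trial shorter than 3 s")
  np <- round(pad_s * fs)
  xp <- x[fold_index((1 - np):(n + np), n)]
  npad <- length(xp)
  klen <- max(vapply(family$kernels, length, integer(1)))
  if (npad < klen) stop("trial too short for the longest kernel after padding")
  nfft <- next_pow2(npad + klen - 1)
  X <- stats::fft(c(xp, numeric(nfft - npad)))
  keep <- seq(1L, n, by = downsample)
  out <- matrix(complex(real = 0), nrow = length(family$kernels),
                ncol = length(keep))
  for (k in seq_along(family$kernels)) {
    w <- family$kernels[[k]]
    nw <- length(w)
    W <- stats::fft(c(w, complex(real = numeric(nfft - nw))))
    y <- stats::fft(X * W, inverse = TRUE) / nfft
    half <- (nw - 1) %/% 2
    # center-aligned "same" convolution, then trim the padding
    y <- y[(half + np + 1):(half + np + n)]
    out[k, ] <- y[keep]
  }
  structure(out,
            freqs = family$freqs,
            fs_eff = fs / downsample,
            col_sample = as.integer(start_sample - 1L + keep))
}

#' Concatenate decomposed trials of one sleep stage
#'
#' @param tfs List of [tf_decompose()] outputs in temporal order.
#' @param stage Optional stage label to attach.
#' @return Object of class `tf_concat`: `values` (complex matrix
#'   `n_freqs x total_columns`), `freqs`, `fs_eff`, `col_sample`, `stage`.
#' @export
tf_concatenate <- function(tfs, stage = NA_character_) {
  stopifnot(length(tfs) >= 1)
  freqs <- attr(tfs[[1]], "freqs")
  fs_eff <- attr(tfs[[1]], "fs_eff")
  structure(list(
    values = do.call(cbind, lapply(tfs, unclass)),
    freqs = freqs,
    fs_eff = fs_eff,
    col_sample = unlist(lapply(tfs, attr, "col_sample")),
    stage = stage
  ), class = "tf_concat")
}

#' Cut concatenated time-frequency data into 60-s segments
#'
#' Segments are taken in concatenation (temporal) order; the trailing
#' incomplete segment is discarded. Each segment keeps the recording sample
#' index of its columns so that downstream bookkeeping can trace any column
#' back to the raw series.
#'
#' @param concat A [tf_concatenate()] object.
#' @param seg_s Segment length in seconds (default 60).
#' @return List of `tf_segment` objects (`values`, `freqs`, `fs_eff`,
#'   `col_sample`, `segment`); empty (with a warning) if less than one
#'   segment of data is available.
#' @export
segment_60s <- function(concat, seg_s = 60) {
  stopifnot(inherits(concat, "tf_concat"))
  seg_len <- round(seg_s * concat$fs_eff)
  total <- ncol(concat$values)
  n_seg <- total %/% seg_len
  if (n_seg == 0) {
    warning("less than one full segment of decomposed data")
    return(list())
  }
  lapply(seq_len(n_seg), function(i) {
    cols <- ((i - 1) * seg_len + 1):(i * seg_len)
    structure(list(values = concat$values[, cols, drop = FALSE],
                   freqs = concat$freqs, fs_eff = concat$fs_eff,
                   col_sample = concat$col_sample[cols], segment = i),
              class = "tf_segment")
  })
}
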