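# Internal numerical helpers shared across modules.

next_pow2 <- function(n) {
  2^ceiling(log2(max(n, 1)))
}

# Symmetric Hann window (first/last sample zero), as used for Welch tapers.
hann_window <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

# Analytic signal z(t) = x(t) + i H[x](t) via one-sided spectrum doubling.
# Mod(analytic_signal(x)) is the Hilbert envelope.
analytic_signal <- function(x) {
  n <- length(x)
  if (n < 2) stop("series too short for analytic signal")
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Circular cross-correlation sums over all integer delays s = 0 .. n-1.
#
# circ_corr_conj(a, b)[s + 1] = sum_t a[t] * Conj(b[(t - s) mod n])
# circ_corr(a, b)[s + 1]      = sum_t a[t] * b[(t - s) mod n]
#
# Both are exact (FFT identity), so a surrogate metric evaluated at a random
# circular shift equals the direct recomputation on the shifted series.
circ_corr_conj <- function(a, b) {
  n <- length(a)
  stats::fft(stats::fft(a) * Conj(stats::fft(b)), inverse = TRUE) / n
}

circ_corr <- function(a, b) {
  n <- length(a)
  stats::fft(stats::fft(a) * Conj(stats::fft(Conj(b))), inverse = TRUE) / n
}

# Modified Akima piecewise cubic Hermite interpolation (makima slope weights
# w1 = |d_{i+1} - d_i| + |d_{i+1} + d_i|/2). Flat in regions where all four
# neighbouring secant slopes vanish.
makima_interp <- function(x, y, xq) {
  n <- length(x)
  stopifnot(n >= 2, length(y) == n, !is.unsorted(x))
  d <- diff(y) / diff(x)
  # virtual secant slopes: d0 = 2 d1 - d2, d_{-1} = 2 d0 - d1 (mirrored right)
  if (n == 2) {
    dl2 <- dl1 <- dr1 <- dr2 <- d[1]
  } else {
    dl1 <- 2 * d[1] - d[2]
    dl2 <- 2 * dl1 - d[1]
    dr1 <- 2 * d[n - 1] - d[n - 2]
    dr2 <- 2 * dr1 - d[n - 1]
  }
  dd <- c(dl2, dl1, d, dr1, dr2)  # dd[i + 2] corresponds to interval i
  s <- numeric(n)
  for (i in seq_len(n)) {
    dm2 <- dd[i]       # d_{i-2}
    dm1 <- dd[i + 1]   # d_{i-1}
    dp0 <- dd[i + 2]   # d_i
    dp1 <- dd[i + 3]   # d_{i+1}
    w1 <- abs(dp1 - dp0) + abs(dp1 + dp0) / 2
    w2 <- abs(dm1 - dm2) + abs(dm1 + dm2) / 2
    s[i] <- if (w1 + w2 == 0) 0 else (w1 * dm1 + w2 * dp0) / (w1 + w2)
  }
  # cubic Hermite evaluation
  idx <- findInterval(xq, x, rightmost.closed = TRUE)
  idx[idx < 1] <- 1
  idx[idx >= n] <- n - 1
  h <- x[idx + 1] - x[idx]
  tt <- (xq - x[idx]) / h
  h00 <- 2 * tt^3 - 3 * tt^2 + 1
  h10 <- tt^3 - 2 * tt^2 + tt
  h01 <- -2 * tt^3 + 3 * tt^2
  h11 <- tt^3 - tt^2
  h00 * y[idx] + h10 * h * s[idx] + h01 * y[idx + 1] + h11 * h * s[idx + 1]
}

# Centered moving average of window `w` (odd) with symmetrically shrinking
# windows at the edges.
moving_average_shrink <- function(x, w = 5) {
  n <- length(x)
  half <- (w - 1) %/% 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    h <- min(half, i - 1, n - i)
    out[i] <- mean(x[(i - h):(i + h)])
  }
  out
}

# Zero-phase filtering of x with a symmetric linear-phase FIR kernel by
# centered FFT convolution (exact zero phase for odd-length symmetric taps).
fir_filt_zerophase <- function(x, kernel) {
  nk <- length(kernel)
  stopifnot(nk %% 2 == 1)
  n <- length(x)
  nfft <- next_pow2(n + nk - 1)
  X <- stats::fft(c(x, numeric(nfft - n)))
  K <- stats::fft(c(kernel, numeric(nfft - nk)))
  y <- Re(stats::fft(X * K, inverse = TRUE)) / nfft
  half <- (nk - 1) %/% 2
  y[(half + 1):(half + n)]
}

# Zero-phase IIR filtering with odd (point-symmetric) end extension, which
# keeps value and slope continuous at the joins and so suppresses the
# start/end transients of plain forward-backward filtering.
filtfilt_pad <- function(filt, x, fs, pad_s = 2) {
  n <- length(x)
  np <- min(round(pad_s * fs), n - 1L)
  head_ext <- 2 * x[1] - x[(np + 1):2]
  tail_ext <- 2 * x[n] - x[(n - 1):(n - np)]
  y <- signal::filtfilt(filt, c(head_ext, x, tail_ext))
  y[(np + 1):(np + n)]
}

# Reflective (mirror, no edge repetition) index folding: maps any integer
# m (possibly < 1 or > n) into 1..n by repeated reflection about the ends.
fold_index <- function(m, n) {
  if (n == 1) return(rep(1L, length(m)))
  period <- 2L * (n - 1L)
  m <- (m - 1L) %% period
  m <- ifelse(m >= n, period - m, m)
  as.integer(m + 1L)
}

# Draw an integer sub-seed (< 2^31) from a named stream, deterministically
# derived from a master seed.
derive_seed <- function(seed, stream) {
  vals <- utf8ToInt(stream)
  h <- as.numeric(seed) %% 2147483647
  for (v in vals) h <- (h * 31 + v) %% 2147483647
  as.integer(h)
}
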