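# Synthetic two-channel NREM LFP generator with full ground truth.
#
# Emulates the phenomenology the downstream pipeline is built to quantify:
# 1/f background, ~80-Hz ripple bursts riding on 2-8-Hz sharp-wave (SPW)
# transients, ~13-Hz waxing-waning spindles, controllable cross-channel ripple
# co-occurrence, delta-phase modulation of ripple amplitude, and injected
# high-amplitude artifacts.

#' Configuration for the synthetic LFP generator
#'
#' Defaults follow the study conditions the pipeline targets: 1-kHz sampling,
#' a 1/f^2 background, hippocampal (channel 1) ripple density ~5.5/min and
#' amygdalar (channel 2) ~2.6/min including spawned co-occurrences, 80-Hz
#' ripples of ~50-ms mean duration with amplitudes of ~12 and ~6 uV, SPW
#' transients drawn from the 2-8-Hz band, and ~13-Hz spindles.
#'
#' @param duration_s Recording length in seconds.
#' @param fs Sampling rate in Hz (default 1000; must exceed twice the ripple
#'   frequency).
#' @param background_a,background_b Power-law background: PSD = a * f^b
#'   (b negative).
#' @param ripple_rate_per_min Length-2 ripple rate per channel; channel 2's
#'   value counts only its independent events (spawned co-occurrences add to
#'   it).
#' @param ripple_freq_hz Ripple carrier frequency (default 80).
#' @param ripple_dur_ms,ripple_dur_sd_ms Mean and SD of ripple duration
#'   (truncated at 35 ms).
#' @param ripple_amp_uv Length-2 ripple peak amplitude per channel (uV).
#' @param spw_freq_hz Length-2 band the per-event SPW frequency is drawn from.
#' @param spw_amp_uv SPW transient amplitude (uV).
#' @param spw_ripple_phase SPW phase (radians) at the ripple peak.
#' @param spw_polarity +1 or -1; sign convention of the SPW deflection
#'   (free parameter: bipolar referencing leaves polarity unconstrained).
#' @param spindle_rate_per_min,spindle_freq_hz,spindle_dur_s,spindle_amp_uv
#'   Spindle event parameters.
#' @param spindle_shared_prob Probability a channel-1 spindle is copied
#'   (identical waveform) into channel 2.
#' @param cooccurrence_prob Probability a channel-1 ripple spawns a channel-2
#'   ripple.
#' @param cooccurrence_lag_sd_ms SD of the Gaussian lag of spawned ripples.
#' @param pac_depth In `[0, 1]`: modulation of ripple amplitude by the phase
#'   of a common delta carrier, factor `1 + pac_depth * cos(phase)`. The
#'   carrier (at `pac_delta_freq_hz`, amplitude `delta_amp_uv`) is added to
#'   both channels only when `pac_depth > 0`.
#' @param pac_delta_freq_hz,delta_amp_uv Delta carrier parameters.
#' @param artifact_rate_per_min,artifact_amp_uv High-amplitude spike/step
#'   artifacts per channel.
#' @param seed Integer master seed; all randomness derives from it through
#'   named sub-streams.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(duration_s = 300, fs = 1000,
                         background_a = 100, background_b = -2,
                         ripple_rate_per_min = c(5.5, 2.0),
                         ripple_freq_hz = 80,
                         ripple_dur_ms = 50, ripple_dur_sd_ms = 10,
                         ripple_amp_uv = c(12, 6.3),
                         spw_freq_hz = c(2, 8), spw_amp_uv = 30,
                         spw_ripple_phase = 0, spw_polarity = 1,
                         spindle_rate_per_min = 2, spindle_freq_hz = 13,
                         spindle_dur_s = 1, spindle_amp_uv = 15,
                         spindle_shared_prob = 0.5,
                         cooccurrence_prob = 0.1,
                         cooccurrence_lag_sd_ms = 15,
                         pac_depth = 0, pac_delta_freq_hz = 4,
                         delta_amp_uv = 20,
                         artifact_rate_per_min = 0.5,
                         artifact_amp_uv = 1500,
                         seed = 1L) {
  cfg <- as.list(environment())
  if (duration_s <= 0) stop("invalid parameter: duration_s must be positive")
  if (fs <= 2 * ripple_freq_hz) {
    stop("invalid parameter: fs must exceed twice the ripple frequency")
  }
  rates <- c(ripple_rate_per_min, spindle_rate_per_min, artifact_rate_per_min)
  if (any(rates < 0)) stop("invalid parameter: rates must be nonnegative")
  if (pac_depth < 0 || pac_depth > 1) stop("invalid parameter: pac_depth in [0,1]")
  if (cooccurrence_prob < 0 || cooccurrence_prob > 1) {
    stop("invalid parameter: cooccurrence_prob in [0,1]")
  }
  if (length(ripple_rate_per_min) != 2 || length(ripple_amp_uv) != 2) {
    stop("ripple_rate_per_min and ripple_amp_uv must have length 2")
  }
  # feasibility: expected events at 200-ms separation must fit
  if (max(ripple_rate_per_min) * duration_s / 60 * 0.2 > duration_s) {
    stop("impossible spec: ripple rate incompatible with 200-ms separation")
  }
  structure(cfg, class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf("synthetic LFP config: %g s at %g Hz, ripple rates %.2g/%.2g per min, seed %d\n",
              x$duration_s, x$fs, x$ripple_rate_per_min[1],
              x$ripple_rate_per_min[2], x$seed))
  invisible(x)
}

#' Generate 1/f background noise
#'
#' Frequency-domain shaping of Gaussian noise: spectral amplitudes
#' proportional to `sqrt(a) * f^(b/2)` with random phases, so that the
#' expected one-sided power spectral density equals `a * f^b` (uV^2/Hz).
#' `b = 0` gives white noise.
#'
#' @param duration_s Length in seconds (> 0).
#' @param fs Sampling rate in Hz (> 0).
#' @param a Power scale.
#' @param b Spectral exponent (typically negative).
#' @param seed Integer seed; the output is deterministic given it.
#' @return Zero-mean numeric series of `round(duration_s * fs)` samples.
#' @export
generate_background <- function(duration_s, fs, a = 100, b = -2, seed = 1L) {
  if (duration_s <= 0 || fs <= 0) {
    stop("invalid parameter: duration_s and fs must be positive")
  }
  set.seed(seed)
  n <- round(duration_s * fs)
  X <- complex(real = numeric(n))
  kmax <- floor((n - 1) / 2)
  f <- (1:kmax) * fs / n
  amp <- sqrt(a * f^b * fs * n / 2)
  z <- complex(real = stats::rnorm(kmax), imaginary = stats::rnorm(kmax)) / sqrt(2)
  X[2:(kmax + 1)] <- amp * z
  X[n:(n - kmax + 1)] <- Conj(X[2:(kmax + 1)])
  if (n %% 2 == 0) {
    fny <- fs / 2
    X[n / 2 + 1] <- sqrt(a * fny^b * fs * n / 2) * stats::rnorm(1)
  }
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  x - mean(x)
}

# Poisson event times in [margin, duration - margin], sorted, thinned so that
# consecutive kept events are at least min_gap_s apart.
draw_event_times <- function(rate_per_min, duration_s, margin_s, min_gap_s) {
  n <- stats::rpois(1, rate_per_min * duration_s / 60)
  if (n == 0) return(numeric(0))
  t <- sort(stats::runif(n, margin_s, duration_s - margin_s))
  keep <- rep(TRUE, n)
  last <- -Inf
  for (i in seq_len(n)) {
    if (t[i] - last < min_gap_s) keep[i] <- FALSE else last <- t[i]
  }
  t[keep]
}

# Add a windowed waveform (values w, centered at sample c0) in place.
add_waveform <- function(x, c0, w) {
  half <- (length(w) - 1) %/% 2
  idx <- (c0 - half):(c0 + half)
  ok <- idx >= 1 & idx <= length(x)
  x[idx[ok]] <- x[idx[ok]] + w[ok]
  x
}

ripple_waveform <- function(fs, freq, dur_ms, amp) {
  ns <- round(dur_ms / 1000 * fs)
  if (ns %% 2 == 0) ns <- ns + 1
  t <- ((1:ns) - (ns + 1) / 2) / fs
  amp * hann_window(ns) * cos(2 * pi * freq * t)
}

spw_waveform <- function(fs, freq, amp, phase_at_peak, polarity) {
  sigma <- 1 / (2 * freq)
  half <- round(3 * sigma * fs)
  t <- (-half:half) / fs
  polarity * amp * sin(2 * pi * freq * t + phase_at_peak) *
    exp(-t^2 / (2 * sigma^2))
}

spindle_waveform <- function(fs, freq, dur_s, amp, phase) {
  ns <- round(dur_s * fs)
  if (ns %% 2 == 0) ns <- ns + 1
  t <- ((1:ns) - (ns + 1) / 2) / fs
  amp * hann_window(ns) * sin(2 * pi * freq * t + phase)
}

#' Inject ground-truth events into a two-channel background
#'
#' Ripples are raised-cosine (Hann) windowed sinusoids, each riding on a
#' biphasic Gaussian-windowed SPW transient whose phase at the ripple peak
#' equals `spw_ripple_phase`; spindles are waxing-waning sinusoids; with
#' probability `cooccurrence_prob` a channel-1 ripple spawns a channel-2
#' ripple at a Gaussian lag (sharing the parent's SPW frequency); when
#' `pac_depth > 0` a common delta carrier is added and ripple amplitudes are
#' scaled by `1 + pac_depth * cos(delta phase at peak)`; artifacts are
#' high-amplitude spikes and steps. Everything injected is recorded in the
#' returned ground truth.
#'
#' @param background Numeric matrix `n x 2` (channels in columns).
#' @param config A [synth_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return List with `signals` (matrix `n x 2`, columns `HPC`, `AMY`) and
#'   `ground_truth` (class `synth_ground_truth`).
#' @export
inject_events <- function(background, config, seed = config$seed) {
  stopifnot(inherits(config, "synth_config"),
            is.matrix(background), ncol(background) == 2)
  n <- nrow(background)
  fs <- config$fs
  dur <- config$duration_s
  margin <- 1.5
  if (dur <= 2 * margin) margin <- dur / 4
  sig <- background
  colnames(sig) <- c("HPC", "AMY")

  delta_phase <- function(t_s) 2 * pi * config$pac_delta_freq_hz * t_s
  if (config$pac_depth > 0) {
    tt <- (seq_len(n) - 1) / fs
    carrier <- config$delta_amp_uv * cos(delta_phase(tt))
    sig[, 1] <- sig[, 1] + carrier
    sig[, 2] <- sig[, 2] + carrier
  }

  # --- ripple times ------------------------------------------------------
  set.seed(derive_seed(seed, "ripples_ch1"))
  t1 <- draw_event_times(config$ripple_rate_per_min[1], dur, margin, 0.2)
  spawned <- logical(length(t1))
  lag_s <- numeric(length(t1))
  if (length(t1) > 0) {
    set.seed(derive_seed(seed, "cooccurrence"))
    spawned <- stats::runif(length(t1)) < config$cooccurrence_prob
    lag_s <- stats::rnorm(length(t1), 0, config$cooccurrence_lag_sd_ms / 1000)
  }
  t2_spawned <- t1[spawned] + lag_s[spawned]
  ok2 <- t2_spawned > margin & t2_spawned < dur - margin
  t2_spawned <- t2_spawned[ok2]
  parent_idx <- which(spawned)[ok2]

  set.seed(derive_seed(seed, "ripples_ch2"))
  t2_own <- draw_event_times(config$ripple_rate_per_min[2], dur, margin, 0.2)
  # spawned events take priority; own events within 200 ms of any other
  # channel-2 event are dropped
  keep_own <- vapply(t2_own, function(t) {
    all(abs(t - t2_spawned) >= 0.2)
  }, logical(1))
  t2_own <- t2_own[keep_own]
  t2 <- c(t2_spawned, t2_own)
  ord2 <- order(t2)
  t2 <- t2[ord2]
  spawn_flag <- c(rep(TRUE, length(t2_spawned)), rep(FALSE, length(t2_own)))[ord2]
  parent_of <- c(parent_idx, rep(NA_integer_, length(t2_own)))[ord2]

  # --- per-event parameters and waveforms --------------------------------
  build_channel_ripples <- function(times, ch, stream, spw_freq_fixed = NULL) {
    set.seed(derive_seed(seed, stream))
    m <- length(times)
    if (m == 0) {
      return(data.frame(time_s = numeric(0), duration_ms = numeric(0),
                        amplitude_uv = numeric(0), spw_freq_hz = numeric(0)))
    }
    durs <- pmax(35, stats::rnorm(m, config$ripple_dur_ms, config$ripple_dur_sd_ms))
    spwf <- if (is.null(spw_freq_fixed)) {
      stats::runif(m, config$spw_freq_hz[1], config$spw_freq_hz[2])
    } else spw_freq_fixed
    amps <- rep(config$ripple_amp_uv[ch], m)
    if (config$pac_depth > 0) {
      amps <- amps * (1 + config$pac_depth * cos(delta_phase(times)))
    }
    data.frame(time_s = times, duration_ms = durs, amplitude_uv = amps,
               spw_freq_hz = spwf)
  }

  rip1 <- build_channel_ripples(t1, 1, "ripple_params_ch1")
  rip2 <- build_channel_ripples(t2, 2, "ripple_params_ch2")
  # spawned channel-2 events inherit the parent's SPW frequency
  if (any(spawn_flag)) {
    rip2$spw_freq_hz[spawn_flag] <- rip1$spw_freq_hz[parent_of[spawn_flag]]
  }

  add_ripples <- function(x, rip) {
    for (i in seq_len(nrow(rip))) {
      c0 <- round(rip$time_s[i] * fs) + 1L
      x <- add_waveform(x, c0, ripple_waveform(fs, config$ripple_freq_hz,
                                               rip$duration_ms[i],
                                               rip$amplitude_uv[i]))
      x <- add_waveform(x, c0, spw_waveform(fs, rip$spw_freq_hz[i],
                                            config$spw_amp_uv,
                                            config$spw_ripple_phase,
                                            config$spw_polarity))
    }
    x
  }
  sig[, 1] <- add_ripples(sig[, 1], rip1)
  sig[, 2] <- add_ripples(sig[, 2], rip2)

  # --- spindles ----------------------------------------------------------
  spn <- vector("list", 2)
  for (ch in 1:2) {
    set.seed(derive_seed(seed, paste0("spindles_ch", ch)))
    ts <- draw_event_times(config$spindle_rate_per_min, dur, margin,
                           config$spindle_dur_s)
    ph <- stats::runif(length(ts), 0, 2 * pi)
    spn[[ch]] <- data.frame(time_s = ts,
                            duration_s = rep(config$spindle_dur_s, length(ts)),
                            phase = ph, shared = rep(FALSE, length(ts)))
  }
  if (nrow(spn[[1]]) > 0 && config$spindle_shared_prob > 0) {
    set.seed(derive_seed(seed, "spindle_sharing"))
    sh <- stats::runif(nrow(spn[[1]])) < config$spindle_shared_prob
    if (any(sh)) {
      copied <- spn[[1]][sh, ]
      copied$shared <- TRUE
      spn[[2]] <- rbind(spn[[2]], copied)
      spn[[2]] <- spn[[2]][order(spn[[2]]$time_s), ]
      spn[[1]]$shared[sh] <- TRUE
    }
  }
  for (ch in 1:2) {
    s <- spn[[ch]]
    for (i in seq_len(nrow(s))) {
      sig[, ch] <- add_waveform(sig[, ch], round(s$time_s[i] * fs) + 1L,
                                spindle_waveform(fs, config$spindle_freq_hz,
                                                 s$duration_s[i],
                                                 config$spindle_amp_uv,
                                                 s$phase[i]))
    }
  }

  # --- artifacts ---------------------------------------------------------
  art <- vector("list", 2)
  for (ch in 1:2) {
    set.seed(derive_seed(seed, paste0("artifacts_ch", ch)))
    ts <- draw_event_times(config$artifact_rate_per_min, dur, margin, 1)
    kind <- sample(c("spike", "step"), length(ts), replace = TRUE)
    starts <- ends <- numeric(length(ts))
    for (i in seq_along(ts)) {
      c0 <- round(ts[i] * fs) + 1L
      if (kind[i] == "spike") {
        w <- config$artifact_amp_uv * hann_window(9)
        starts[i] <- ts[i] - 4 / fs
        ends[i] <- ts[i] + 4 / fs
      } else {
        ns <- round(0.2 * fs)
        if (ns %% 2 == 0) ns <- ns + 1
        w <- rep(config$artifact_amp_uv / 3, ns)
        starts[i] <- ts[i] - 0.1
        ends[i] <- ts[i] + 0.1
      }
      sig[, ch] <- add_waveform(sig[, ch], c0, w)
    }
    art[[ch]] <- data.frame(start_s = starts, end_s = ends, kind = kind,
                            stringsAsFactors = FALSE)
  }

  pairs <- data.frame(ch1_index = parent_of[spawn_flag],
                      ch2_index = which(spawn_flag),
                      lag_ms = (rip2$time_s[spawn_flag] -
                                rip1$time_s[parent_of[spawn_flag]]) * 1000)
  gt <- structure(list(
    channels = list(
      HPC = list(ripples = rip1, spindles = spn[[1]], artifacts = art[[1]]),
      AMY = list(ripples = rip2, spindles = spn[[2]], artifacts = art[[2]])
    ),
    pairs = pairs, fs = fs, duration_s = dur
  ), class = "synth_ground_truth")
  list(signals = sig, ground_truth = gt)
}

#' @export
print.synth_ground_truth <- function(x, ...) {
  cat(sprintf("ground truth: %d HPC + %d AMY ripples (%d pairs), %d/%d spindles, %d/%d artifacts\n",
              nrow(x$channels$HPC$ripples), nrow(x$channels$AMY$ripples),
              nrow(x$pairs),
              nrow(x$channels$HPC$spindles), nrow(x$channels$AMY$spindles),
              nrow(x$channels$HPC$artifacts), nrow(x$channels$AMY$artifacts)))
  invisible(x)
}

#' Synthesize a two-channel NREM-like LFP recording
#'
#' Generates per-channel 1/f backgrounds (independent sub-streams of the
#' master seed) and injects all configured events.
#'
#' @param config A [synth_config()].
#' @return Object of class `synth_lfp`: `signals` (`n x 2` matrix, uV),
#'   `fs`, `ground_truth`, `config`.
#' @export
synthesize_lfp <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  bg <- cbind(
    generate_background(config$duration_s, config$fs, config$background_a,
                        config$background_b,
                        derive_seed(config$seed, "background_ch1")),
    generate_background(config$duration_s, config$fs, config$background_a,
                        config$background_b,
                        derive_seed(config$seed, "background_ch2"))
  )
  inj <- inject_events(bg, config)
  structure(list(signals = inj$signals, fs = config$fs,
                 ground_truth = inj$ground_truth, config = config),
            class = "synth_lfp")
}

#' @export
print.synth_lfp <- function(x, ...) {
  cat(sprintf("synthetic LFP: %g s, 2 channels at %g Hz\n",
              x$config$duration_s, x$fs))
  print(x$ground_truth)
  invisible(x)
}

#' Assemble a synthetic LFP into a recording container
#'
#' @param synth A [synthesize_lfp()] object.
#' @param stages Optional per-epoch (20-s) stage labels; defaults to all
#'   `"N2"`.
#' @return An [lfp_recording()].
#' @export
as_recording <- function(synth, stages = NULL) {
  stopifnot(inherits(synth, "synth_lfp"))
  n <- nrow(synth$signals)
  if (is.null(stages)) stages <- rep("N2", ceiling(n / (20 * synth$fs)))
  lfp_recording(channels = list(HPC = synth$signals[, 1],
                                AMY = synth$signals[, 2]),
                fs = synth$fs, stages = stages)
}
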