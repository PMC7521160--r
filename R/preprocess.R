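# Filtering, artifact detection, and stage-aware trial segmentation.

#' Continuous multichannel recording container
#'
#' @param channels Named list of equal-length numeric series (uV).
#' @param fs Sampling rate in Hz.
#' @param stages Character vector of 20-s epoch labels
#'   (`N1`, `N2`, `N3`, `REM`, `Wake`); must cover the recording (the last
#'   epoch may be partial).
#' @param artifact_mask Optional named list of logical series (TRUE =
#'   rejected sample), same lengths as `channels`.
#' @param epoch_s Epoch length in seconds (default 20).
#' @return Object of class `lfp_recording`.
#' @export
lfp_recording <- function(channels, fs, stages, artifact_mask = NULL,
                          epoch_s = 20) {
  stopifnot(is.list(channels), length(channels) >= 1, !is.null(names(channels)))
  n <- length(channels[[1]])
  if (!all(vapply(channels, length, integer(1)) == n)) {
    stop("all channels must have the same length")
  }
  n_epochs <- ceiling(n / (epoch_s * fs))
  if (length(stages) < n_epochs) {
    stop(sprintf("stage sequence (%d epochs) does not cover the recording (%d epochs)",
                 length(stages), n_epochs))
  }
  if (!is.null(artifact_mask)) {
    stopifnot(identical(names(artifact_mask), names(channels)),
              all(vapply(artifact_mask, length, integer(1)) == n))
  }
  structure(list(channels = channels, fs = fs, stages = stages,
                 artifact_mask = artifact_mask, epoch_s = epoch_s),
            class = "lfp_recording")
}

#' @export
print.lfp_recording <- function(x, ...) {
  n <- length(x$channels[[1]])
  cat(sprintf("LFP recording: %d channel(s) [%s], %.1f s at %g Hz, %d epochs\n",
              length(x$channels), paste(names(x$channels), collapse = ", "),
              n / x$fs, x$fs, length(x$stages)))
  invisible(x)
}

# RBJ biquad notch coefficients (b, a) for center f0 and quality Q.
notch_biquad <- function(f0, fs, q = 35) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  list(b = b, a = a)
}

#' High-pass and notch filter a channel
#'
#' Zero-phase (forward-backward) filtering: 2nd-order Butterworth high-pass
#' at `highpass_hz`, then 2nd-order notches (Q about 35) at `notch_hz` and
#' its listed harmonics.
#'
#' @param x Numeric series.
#' @param fs Sampling rate in Hz; must exceed 600 Hz so the highest notch
#'   (300 Hz) stays below Nyquist.
#' @param highpass_hz High-pass cutoff (default 0.3).
#' @param notch_hz Notch centers (default 50 Hz and harmonics to 300 Hz).
#' @param notch_q Notch quality factor (default 35).
#' @return Filtered series, same length.
#' @export
apply_filters <- function(x, fs, highpass_hz = 0.3,
                          notch_hz = seq(50, 300, by = 50), notch_q = 35) {
  if (fs <= 600) stop("invalid parameter: fs must exceed 600 Hz")
  hp <- signal::butter(2, highpass_hz / (fs / 2), type = "high")
  y <- filtfilt_pad(hp, x, fs)
  for (f0 in notch_hz) {
    nb <- notch_biquad(f0, fs, notch_q)
    y <- filtfilt_pad(signal::Arma(b = nb$b, a = nb$a), y, fs)
  }
  y
}

#' Detect artifacts by gradient and high-frequency z thresholds
#'
#' A sample is flagged when the absolute z-score of the first difference or
#' of the >250-Hz Hilbert envelope (250 Hz to Nyquist - 10 Hz band-pass)
#' exceeds `z_thresh`; flags are dilated by `pad_s` on each side. z statistics
#' are computed per channel over the whole recording (channel-specific
#' thresholds).
#'
#' @param x Numeric series (at least 10 s).
#' @param fs Sampling rate in Hz.
#' @param z_thresh z threshold (default 6).
#' @param pad_s Dilation margin in seconds (default 0.25).
#' @return Logical mask, TRUE = rejected sample.
#' @export
detect_artifacts <- function(x, fs, z_thresh = 6, pad_s = 0.25) {
  n <- length(x)
  if (n < 10 * fs) stop("series shorter than 10 s")
  if (stats::sd(x) == 0) stop("zero-variance (constant) series")
  g <- c(0, diff(x))
  zg <- abs(g - mean(g)) / stats::sd(g)
  hi <- min(fs / 2 - 10, fs / 2 * 0.95)
  bp <- signal::butter(2, c(250, hi) / (fs / 2), type = "pass")
  xhf <- filtfilt_pad(bp, x, fs)
  env <- Mod(analytic_signal(xhf))
  # guard: with no measurable high-frequency content the envelope is numerical
  # noise and z-scoring it is meaningless
  ze <- if (stats::sd(env) < 1e-5 * stats::sd(x)) {
    numeric(n)
  } else {
    abs(env - mean(env)) / stats::sd(env)
  }
  flag <- zg > z_thresh | ze > z_thresh
  dilate_mask(flag, round(pad_s * fs))
}

# Dilate a logical mask by m samples on each side.
dilate_mask <- function(flag, m) {
  if (m <= 0 || !any(flag)) return(flag)
  cs <- cumsum(as.integer(flag))
  n <- length(flag)
  lo <- pmax(seq_len(n) - m, 1L)
  hi <- pmin(seq_len(n) + m, n)
  (cs[hi] - c(0L, cs)[lo]) > 0L
}

#' Attach artifact masks to a recording
#'
#' Runs [detect_artifacts()] on each (already filtered) channel.
#'
#' @param recording An [lfp_recording()].
#' @param z_thresh,pad_s Passed to [detect_artifacts()].
#' @return The recording with `artifact_mask` filled in.
#' @export
mask_artifacts <- function(recording, z_thresh = 6, pad_s = 0.25) {
  stopifnot(inherits(recording, "lfp_recording"))
  recording$artifact_mask <- lapply(recording$channels, detect_artifacts,
                                    fs = recording$fs, z_thresh = z_thresh,
                                    pad_s = pad_s)
  recording
}

#' Cut artifact-free stage-labeled trials
#'
#' Maximal contiguous artifact-free runs lying entirely within spans of
#' epochs of a single admissible stage, retained when at least `min_dur_s`
#' long. Trials never span a stage change. When more than one channel is
#' selected, the union of the channels' artifact masks is used, so trials are
#' clean on every selected channel simultaneously (as cross-channel analyses
#' require).
#'
#' @param recording An [lfp_recording()] with artifact masks.
#' @param channels Channel names to combine (default all).
#' @param stages Admissible stages (default `c("N2", "N3")`).
#' @param min_dur_s Minimum trial duration in seconds (default 3).
#' @return Data frame of class `trial_set` with columns `start`, `end`
#'   (1-based, `end` exclusive), `stage`, `duration_s`; sorted and
#'   non-overlapping.
#' @export
segment_trials <- function(recording, channels = NULL,
                           stages = c("N2", "N3"), min_dur_s = 3) {
  stopifnot(inherits(recording, "lfp_recording"))
  if (is.null(recording$artifact_mask)) {
    stop("recording has no artifact mask; run mask_artifacts() first")
  }
  if (is.null(channels)) channels <- names(recording$channels)
  fs <- recording$fs
  n <- length(recording$channels[[1]])
  mask <- Reduce(`|`, recording$artifact_mask[channels])

  epoch_len <- recording$epoch_s * fs
  epoch_of <- pmin(((seq_len(n) - 1L) %/% epoch_len) + 1L,
                   length(recording$stages))
  stage_per_sample <- recording$stages[epoch_of]

  out <- list()
  for (st in unique(stages)) {
    ok <- stage_per_sample == st & !mask
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    sel <- which(r$values & r$lengths >= min_dur_s * fs)
    for (i in sel) {
      out[[length(out) + 1]] <- data.frame(
        start = starts[i], end = ends[i] + 1L, stage = st,
        duration_s = r$lengths[i] / fs, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    trials <- data.frame(start = integer(0), end = integer(0),
                         stage = character(0), duration_s = numeric(0))
  } else {
    trials <- do.call(rbind, out)
    trials <- trials[order(trials$start), , drop = FALSE]
    rownames(trials) <- NULL
  }
  class(trials) <- c("trial_set", class(trials))
  attr(trials, "fs") <- fs
  trials
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("%d trial(s), %.1f s total\n", nrow(x), sum(x$duration_s)))
  if (nrow(x) > 0) print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' Export artifact intervals as delimited text
#'
#' Three columns: channel, start_s, end_s.
#'
#' @param recording An [lfp_recording()] with masks.
#' @param path Output path (tab-separated).
#' @export
export_artifacts <- function(recording, path) {
  stopifnot(!is.null(recording$artifact_mask))
  fs <- recording$fs
  rows <- list()
  for (ch in names(recording$artifact_mask)) {
    r <- rle(recording$artifact_mask[[ch]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    sel <- which(r$values)
    for (i in sel) {
      rows[[length(rows) + 1]] <- data.frame(
        channel = ch, start_s = (starts[i] - 1) / fs, end_s = ends[i] / fs)
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(channel = character(0), start_s = numeric(0), end_s = numeric(0))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
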