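# Ripple-locked ERP, ERP spectra, time-frequency power and ITPC maps, each
# normalized against the surrogate event distributions.

# Gather mean-centered snippets (events x samples) around peak samples.
locked_snippets <- function(x, peaks, half) {
  offs <- (-half):half
  idx <- outer(peaks, offs, `+`)
  snip <- matrix(x[idx], nrow = length(peaks))
  snip - rowMeans(snip)
}

#' Ripple-locked event-related potential with surrogate confidence band
#'
#' Mean of mean-centered 1.5-s raw-signal snippets centered on each ripple
#' peak; the same average over each surrogate event set gives the pointwise
#' 95% confidence interval (2.5th-97.5th percentiles across surrogate ERPs).
#'
#' @param x Numeric series (raw/filtered channel at the acquisition rate).
#' @param fs Sampling rate in Hz.
#' @param peaks Integer event peak samples (>= 10 events recommended; fewer
#'   triggers a warning but is computed).
#' @param surrogate_sets A [make_surrogate_events()] matrix (or NULL to skip
#'   the confidence band).
#' @param half_s Half window in seconds (default 0.75).
#' @return Object of class `locked_erp`: `time_s`, `erp`, `ci_lo`, `ci_hi`,
#'   `n_events`, `surrogate_erps` (sets x samples matrix).
#' @export
locked_erp <- function(x, fs, peaks, surrogate_sets = NULL, half_s = 0.75) {
  if (length(peaks) < 10) {
    warning(sprintf("only %d events: ERP computed but unreliable", length(peaks)))
  }
  half <- round(half_s * fs)
  erp <- colMeans(locked_snippets(x, peaks, half))
  ci_lo <- ci_hi <- surr <- NULL
  if (!is.null(surrogate_sets)) {
    surr <- t(apply(surrogate_sets, 1, function(pk) {
      colMeans(locked_snippets(x, pk, half))
    }))
    ci <- apply(surr, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
    ci_lo <- ci[1, ]
    ci_hi <- ci[2, ]
  }
  structure(list(time_s = ((-half):half) / fs, erp = erp,
                 ci_lo = ci_lo, ci_hi = ci_hi, n_events = length(peaks),
                 surrogate_erps = surr, fs = fs),
            class = "locked_erp")
}

#' @export
print.locked_erp <- function(x, ...) {
  cat(sprintf("ripple-locked ERP: %d events, %.2f-s window, %s surrogate sets\n",
              x$n_events, diff(range(x$time_s)),
              if (is.null(x$surrogate_erps)) "no" else nrow(x$surrogate_erps)))
  invisible(x)
}

#' Spectrum of the ripple-locked ERP, raw and surrogate-normalized
#'
#' Welch spectrum of the 1.5-s ERP (1.25-s Hann windows, 95% overlap,
#' zero-padded to 2048 bins at 1 kHz giving 0.488-Hz resolution; all full
#' windows are averaged), z-scored per bin against the surrogate ERP
#' spectra.
#'
#' @param erp A [locked_erp()] with surrogate ERPs.
#' @param window_s,overlap Welch design (defaults 1.25 s, 0.95).
#' @return List with `freqs`, `raw`, `surrogate_mean`, `z`, `resolution`.
#' @export
erp_spectrum <- function(erp, window_s = 1.25, overlap = 0.95) {
  stopifnot(inherits(erp, "locked_erp"), !is.null(erp$surrogate_erps))
  fs <- erp$fs
  est <- welch_single(erp$erp, fs, window_s, overlap)
  surr <- apply(erp$surrogate_erps, 1, function(e) {
    welch_single(e, fs, window_s, overlap)$power
  })  # bins x sets
  mu <- rowMeans(surr)
  sdev <- apply(surr, 1, stats::sd)
  z <- (est$power - mu) / sdev
  z[sdev == 0] <- NA
  list(freqs = est$freqs, raw = est$power, surrogate_mean = mu, z = z,
       resolution = est$freqs[2] - est$freqs[1])
}

# Map event peak samples (acquisition rate) to columns of concatenated TF
# data, requiring the full +-half window to be contiguous within one trial.
tf_event_columns <- function(concat, peaks, half_cols, tol_samples = 2) {
  cols <- vapply(peaks, function(pk) {
    j <- which.min(abs(concat$col_sample - pk))
    if (abs(concat$col_sample[j] - pk) > tol_samples + 2) {
      stop("coverage error: event not covered by time-frequency data")
    }
    as.integer(j)
  }, integer(1))
  ds <- concat$col_sample[2] - concat$col_sample[1]
  for (j in cols) {
    if (j - half_cols < 1 || j + half_cols > ncol(concat$values)) {
      stop("coverage error: event window exceeds time-frequency data")
    }
    span <- concat$col_sample[j + half_cols] - concat$col_sample[j - half_cols]
    if (span != 2 * half_cols * ds) {
      stop("coverage error: event window crosses a trial boundary")
    }
  }
  cols
}

# Mean over events of windowed rows of a (real or complex) matrix:
# returns rows x (2*half+1).
window_mean <- function(mat, cols, half) {
  offs <- (-half):half
  idx <- as.vector(outer(offs, cols, `+`))
  w <- mat[, idx, drop = FALSE]
  arr <- array(w, c(nrow(mat), length(offs), length(cols)))
  rowMeans(arr, dims = 2)
}

#' Ripple-locked time-frequency power map
#'
#' Power (squared magnitude) is z-scored per frequency over all NREM
#' time-frequency samples, averaged over ripple-centered windows, the same
#' average is computed for each surrogate event set, and the true response is
#' z-scored against the surrogate responses. Cluster outlines are drawn at up
#' to 5 integer z levels chosen by [choose_outline_levels()].
#'
#' @param concat A [tf_concatenate()] object covering all event windows.
#' @param peaks Integer event peak samples (acquisition rate).
#' @param surrogate_sets A [make_surrogate_events()] matrix.
#' @param half_s Half window in seconds (default 0.75).
#' @return Object of class `locked_map` (`kind = "power"`): `z_map`
#'   (freqs x time), `freqs`, `time_s`, `levels`, `clusters`, `n_events`.
#' @export
locked_tf_power <- function(concat, peaks, surrogate_sets, half_s = 0.75) {
  stopifnot(inherits(concat, "tf_concat"))
  half <- floor(half_s * concat$fs_eff)
  pw <- Mod(concat$values)^2
  mu <- rowMeans(pw)
  sdev <- apply(pw, 1, stats::sd)
  pz <- (pw - mu) / sdev

  cols_true <- tf_event_columns(concat, peaks, half)
  true_resp <- window_mean(pz, cols_true, half)

  n_sets <- nrow(surrogate_sets)
  s1 <- s2 <- matrix(0, nrow(pz), 2 * half + 1)
  for (k in seq_len(n_sets)) {
    cols_k <- tf_event_columns(concat, surrogate_sets[k, ], half)
    resp <- window_mean(pz, cols_k, half)
    s1 <- s1 + resp
    s2 <- s2 + resp^2
  }
  smu <- s1 / n_sets
  ssd <- sqrt(pmax((s2 - n_sets * smu^2) / (n_sets - 1), 0))
  z_map <- (true_resp - smu) / ssd
  z_map[ssd == 0] <- NA
  finalize_locked_map(z_map, concat, half, length(peaks), "power")
}

#' Ripple-locked intertrial phase clustering map
#'
#' ITPC(f, t) = |mean over events of exp(i phase(f, t))| within the 1.5-s
#' ripple-centered window, computed for the true events and each surrogate
#' set, then z-scored against the surrogate distribution.
#'
#' @inheritParams locked_tf_power
#' @return Object of class `locked_map` (`kind = "itpc"`).
#' @export
locked_itpc <- function(concat, peaks, surrogate_sets, half_s = 0.75) {
  stopifnot(inherits(concat, "tf_concat"))
  if (length(peaks) < 10) {
    warning(sprintf("only %d events: ITPC computed but unreliable", length(peaks)))
  }
  half <- floor(half_s * concat$fs_eff)
  ph <- unit_phasor(concat$values)

  cols_true <- tf_event_columns(concat, peaks, half)
  true_itpc <- Mod(window_mean(ph, cols_true, half))

  n_sets <- nrow(surrogate_sets)
  s1 <- s2 <- matrix(0, nrow(ph), 2 * half + 1)
  for (k in seq_len(n_sets)) {
    cols_k <- tf_event_columns(concat, surrogate_sets[k, ], half)
    it <- Mod(window_mean(ph, cols_k, half))
    s1 <- s1 + it
    s2 <- s2 + it^2
  }
  smu <- s1 / n_sets
  ssd <- sqrt(pmax((s2 - n_sets * smu^2) / (n_sets - 1), 0))
  z_map <- (true_itpc - smu) / ssd
  z_map[ssd == 0] <- NA
  finalize_locked_map(z_map, concat, half, length(peaks), "itpc")
}

finalize_locked_map <- function(z_map, concat, half, n_events, kind) {
  levels <- choose_outline_levels(z_map)
  clusters <- list()
  for (lv in levels) {
    clusters <- c(clusters, find_clusters(z_map, lv))
  }
  structure(list(z_map = z_map, freqs = concat$freqs,
                 time_s = ((-half):half) / concat$fs_eff,
                 levels = levels, clusters = clusters,
                 n_events = n_events, kind = kind),
            class = "locked_map")
}

#' @export
print.locked_map <- function(x, ...) {
  cat(sprintf("ripple-locked %s map: %d x %d (freq x time), %d events; outline levels: %s; %d cluster(s)\n",
              x$kind, nrow(x$z_map), ncol(x$z_map), x$n_events,
              if (length(x$levels)) paste(x$levels, collapse = ", ") else "none",
              length(x$clusters)))
  invisible(x)
}

#' Export cluster outlines of a locked map as delimited text
#'
#' @param map A `locked_map`.
#' @param path Output path (tab-separated): level, sign, n_bins, f_min_hz,
#'   f_max_hz, t_min_ms, t_max_ms, mass.
#' @export
export_clusters <- function(map, path) {
  rows <- lapply(map$clusters, function(cl) {
    data.frame(level = cl$level, sign = cl$sign, n_bins = cl$n_bins,
               f_min_hz = map$freqs[cl$row_range[1]],
               f_max_hz = map$freqs[cl$row_range[2]],
               t_min_ms = map$time_s[cl$col_range[1]] * 1000,
               t_max_ms = map$time_s[cl$col_range[2]] * 1000,
               mass = cl$mass)
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(level = numeric(0), sign = numeric(0), n_bins = integer(0),
               f_min_hz = numeric(0), f_max_hz = numeric(0),
               t_min_ms = numeric(0), t_max_ms = numeric(0), mass = numeric(0))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
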