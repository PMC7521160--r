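# Cross-channel ripple co-occurrence rates, surrogate significance, and
# peak-timing differences.

#' Ripple co-occurrence rate
#'
#' Percentage of events in the first list whose peak lies within
#' +- `window_ms / 2` (closed interval) of any peak in the second list.
#'
#' @param peaks_a_s,peaks_b_s Numeric vectors of ripple peak times in
#'   seconds (`peaks_a_s` nonempty).
#' @param window_ms Full window length in ms (1500, 500, or 100 in the
#'   standard analysis).
#' @return Rate in percent.
#' @export
cooccurrence_rate <- function(peaks_a_s, peaks_b_s, window_ms) {
  if (length(peaks_a_s) == 0) stop("undefined rate: no events in first channel")
  if (length(peaks_b_s) == 0) return(0)
  half <- window_ms / 2 / 1000
  hit <- vapply(peaks_a_s, function(t) min(abs(t - peaks_b_s)) <= half,
                logical(1))
  100 * mean(hit)
}

#' Surrogate significance of a co-occurrence rate
#'
#' Computes the co-occurrence rate between a channel's true ripples and each
#' surrogate event set from the other channel, and returns the proportion of
#' surrogate rates at least as large as the observed one.
#'
#' @param peaks_a_s True ripple peak times (seconds) of the reference
#'   channel.
#' @param peaks_b_s True ripple peak times (seconds) of the other channel.
#' @param surrogate_b A [make_surrogate_events()] object for the other
#'   channel.
#' @param window_ms Full window length in ms.
#' @return List with `rate` (observed, percent), `surrogate_rates`, `p`
#'   (empirical), `label` (formatted, `"P < 1/n"` when observed beats all
#'   surrogates).
#' @export
cooccurrence_significance <- function(peaks_a_s, peaks_b_s, surrogate_b,
                                      window_ms) {
  stopifnot(inherits(surrogate_b, "surrogate_events"))
  fs <- attr(surrogate_b, "fs")
  obs <- cooccurrence_rate(peaks_a_s, peaks_b_s, window_ms)
  surr <- apply(surrogate_b, 1, function(pk) {
    cooccurrence_rate(peaks_a_s, (pk - 1) / fs, window_ms)
  })
  p <- empirical_p(obs, surr, "ge")
  list(rate = obs, surrogate_rates = surr, p = p,
       label = format_empirical_p(p, length(surr)))
}

#' Ripple peak timing differences within precise co-occurrences
#'
#' For each event in the first list with a partner within
#' +- `window_ms / 2`, the signed lag to the nearest partner
#' (first channel minus second, ms), with a one-sample t test against zero.
#'
#' @inheritParams cooccurrence_rate
#' @param window_ms Full window length in ms (default 100).
#' @return List with `lags_ms`, `mean_ms`, `sd_ms`, `t`, `p` (empty lags
#'   give NA statistics).
#' @export
timing_differences <- function(peaks_a_s, peaks_b_s, window_ms = 100) {
  half <- window_ms / 2 / 1000
  lags <- numeric(0)
  for (t in peaks_a_s) {
    d <- t - peaks_b_s
    j <- which.min(abs(d))
    if (length(j) == 1 && abs(d[j]) <= half) lags <- c(lags, d[j] * 1000)
  }
  if (length(lags) < 2) {
    return(list(lags_ms = lags, mean_ms = if (length(lags)) mean(lags) else NA_real_,
                sd_ms = NA_real_, t = NA_real_, p = NA_real_))
  }
  if (stats::sd(lags) == 0) {
    # degenerate spread: t is 0 when the common lag is 0, otherwise unbounded
    tt <- if (mean(lags) == 0) 0 else sign(mean(lags)) * Inf
    return(list(lags_ms = lags, mean_ms = mean(lags), sd_ms = 0,
                t = tt, p = if (tt == 0) 1 else 0))
  }
  tt <- stats::t.test(lags, mu = 0)
  list(lags_ms = lags, mean_ms = mean(lags), sd_ms = stats::sd(lags),
       t = unname(tt$statistic), p = tt$p.value)
}

#' Full co-occurrence table (both directions, all windows)
#'
#' @param peaks_a_s,peaks_b_s Peak times (seconds) of the two channels.
#' @param surrogate_a,surrogate_b [make_surrogate_events()] objects for each
#'   channel.
#' @param labels Channel labels, e.g. `c("HPC", "AMY")`.
#' @param windows_ms Window lengths (default `c(1500, 500, 100)`).
#' @return Data frame of class `cooccurrence_table` with `direction`,
#'   `window_ms`, `rate_percent`, `p`, `p_label`.
#' @export
cooccurrence_table <- function(peaks_a_s, peaks_b_s, surrogate_a, surrogate_b,
                               labels = c("a", "b"),
                               windows_ms = c(1500, 500, 100)) {
  rows <- list()
  for (w in windows_ms) {
    ab <- cooccurrence_significance(peaks_a_s, peaks_b_s, surrogate_b, w)
    ba <- cooccurrence_significance(peaks_b_s, peaks_a_s, surrogate_a, w)
    rows[[length(rows) + 1]] <- data.frame(
      direction = sprintf("%s during %s", labels[1], labels[2]),
      window_ms = w, rate_percent = ab$rate, p = ab$p, p_label = ab$label)
    rows[[length(rows) + 1]] <- data.frame(
      direction = sprintf("%s during %s", labels[2], labels[1]),
      window_ms = w, rate_percent = ba$rate, p = ba$p, p_label = ba$label)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("cooccurrence_table", class(out))
  out
}
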