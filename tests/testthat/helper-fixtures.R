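# Shared fixtures, memoized across test files (built once per session).

.fix_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fix_cache)) {
    assign(name, builder(), envir = .fix_cache)
  }
  get(name, envir = .fix_cache)
}

# One full-length clean trial covering a series.
whole_trial <- function(x, fs) {
  data.frame(start = 1L, end = length(x) + 1L, stage = "N2",
             duration_s = length(x) / fs)
}

# Default-condition synthetic recording, preprocessed, with trials and
# detected ripples on both channels.
fix_default_run <- function() {
  fixture("default_run", function() {
    cfg <- synth_config(duration_s = 300, seed = 42)
    syn <- synthesize_lfp(cfg)
    rec <- as_recording(syn)
    rec$channels <- lapply(rec$channels, apply_filters, fs = rec$fs)
    rec <- mask_artifacts(rec)
    trials <- segment_trials(rec)
    events <- lapply(names(rec$channels), function(ch) {
      ev <- detect_ripples(rec$channels[[ch]], rec$fs, trials)
      if (nrow(ev) > 0) ripple_properties(ev) else ev
    })
    names(events) <- names(rec$channels)
    list(cfg = cfg, syn = syn, rec = rec, trials = trials, events = events)
  })
}

# Standard 50-frequency wavelet family at 1 kHz.
fix_family <- function() {
  fixture("family", function() build_wavelets(1000))
}

# Reduced 20-frequency family used by the null-calibration suites.
fix_family20 <- function() {
  fixture("family20", function() build_wavelets(1000, n_freqs = 20))
}

# Decompose a full series into one 60-s segment list.
decompose_segments <- function(x, fs, family) {
  tf <- tf_decompose(x, fs, family, start_sample = 1L)
  segment_60s(tf_concatenate(list(tf)))
}
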