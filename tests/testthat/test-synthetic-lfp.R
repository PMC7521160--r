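# Ground-truth generator: spectral shape, determinism, event bookkeeping.

test_that("background spectral exponent is recovered by log-log regression", {
  fs <- 1000
  for (b in c(0, -2)) {
    bg <- generate_background(300, fs, a = 10, b = b, seed = 3)
    sp <- welch_psd(bg, fs, whole_trial(bg, fs))
    sel <- sp$freqs >= 4 & sp$freqs <= 175
    slope <- unname(stats::lm.fit(cbind(1, log10(sp$freqs[sel])),
                                  log10(sp$power[sel]))$coefficients[2])
    expect_lt(abs(slope - b), 0.1)
  }
  expect_lt(abs(mean(generate_background(10, fs, 10, -2, seed = 1))), 1e-10)
})

test_that("background generation is deterministic and validates inputs", {
  expect_identical(generate_background(5, 1000, 10, -2, seed = 9),
                   generate_background(5, 1000, 10, -2, seed = 9))
  expect_false(identical(generate_background(5, 1000, 10, -2, seed = 9),
                         generate_background(5, 1000, 10, -2, seed = 10)))
  expect_error(generate_background(0, 1000), "invalid")
  expect_error(generate_background(10, -5), "invalid")
})

test_that("zero event rates leave the background untouched sample-for-sample", {
  cfg <- synth_config(duration_s = 20, seed = 5,
                      ripple_rate_per_min = c(0, 0), spindle_rate_per_min = 0,
                      artifact_rate_per_min = 0, cooccurrence_prob = 0)
  bg <- cbind(generate_background(20, 1000, 100, -2, 1),
              generate_background(20, 1000, 100, -2, 2))
  out <- inject_events(bg, cfg)
  expect_equal(unname(out$signals), unname(bg))
  expect_equal(nrow(out$ground_truth$channels$HPC$ripples), 0)
})

test_that("full synthesis is reproducible from the config seed", {
  cfg <- synth_config(duration_s = 30, seed = 11)
  a <- synthesize_lfp(cfg)
  b <- synthesize_lfp(cfg)
  expect_identical(a$signals, b$signals)
  expect_identical(a$ground_truth, b$ground_truth)
})

test_that("forced co-occurrence pairs every channel-1 ripple with the stated lag spread", {
  cfg <- synth_config(duration_s = 1200, seed = 13,
                      ripple_rate_per_min = c(6, 0), cooccurrence_prob = 1,
                      cooccurrence_lag_sd_ms = 10,
                      spindle_rate_per_min = 0, artifact_rate_per_min = 0)
  syn <- synthesize_lfp(cfg)
  gt <- syn$ground_truth
  n1 <- nrow(gt$channels$HPC$ripples)
  expect_gt(n1, 80)
  expect_equal(nrow(gt$pairs), nrow(gt$channels$AMY$ripples))
  # all but boundary-clipped parents are paired
  expect_gte(nrow(gt$pairs), n1 - 2)
  expect_true(stats::sd(gt$pairs$lag_ms) >= 6 &&
              stats::sd(gt$pairs$lag_ms) <= 14)
  # every injected event lies inside the recording
  for (ch in c("HPC", "AMY")) {
    tt <- gt$channels[[ch]]$ripples$time_s
    expect_true(all(tt >= 0 & tt <= cfg$duration_s))
  }
})

test_that("pac_depth modulates ripple-band amplitude by delta phase", {
  cfg <- synth_config(duration_s = 600, seed = 17, pac_depth = 1,
                      ripple_rate_per_min = c(30, 0), spw_amp_uv = 0,
                      spindle_rate_per_min = 0, artifact_rate_per_min = 0,
                      cooccurrence_prob = 0)
  syn <- synthesize_lfp(cfg)
  gt <- syn$ground_truth$channels$HPC$ripples
  phase <- (2 * pi * cfg$pac_delta_freq_hz * gt$time_s) %% (2 * pi)
  near0 <- gt$amplitude_uv[phase < pi / 2 | phase > 3 * pi / 2]
  nearpi <- gt$amplitude_uv[phase > pi / 2 & phase < 3 * pi / 2]
  expect_gt(mean(near0), mean(nearpi))
  # and the injected envelope follows 1 + cos(phase)
  expect_equal(gt$amplitude_uv,
               cfg$ripple_amp_uv[1] * (1 + cos(2 * pi * 4 * gt$time_s)),
               tolerance = 1e-8)
})

test_that("adjusted spectra recover a ripple-band peak iff ripples are injected", {
  fam_check <- function(rate) {
    cfg <- synth_config(duration_s = 300, seed = 23,
                        ripple_rate_per_min = c(rate, 0),
                        spindle_rate_per_min = 0, artifact_rate_per_min = 0,
                        spw_amp_uv = 0, cooccurrence_prob = 0)
    syn <- synthesize_lfp(cfg)
    x <- syn$signals[, 1]
    adj <- adjust_one_over_f(welch_psd(x, 1000, whole_trial(x, 1000)))
    band <- adj$freqs_log >= 60 & adj$freqs_log <= 100
    flank <- (adj$freqs_log >= 40 & adj$freqs_log < 60) |
      (adj$freqs_log > 100 & adj$freqs_log <= 140)
    max(adj$adjusted_power[band]) - max(adj$adjusted_power[flank])
  }
  expect_gt(fam_check(8), 0)      # clear local ripple-band peak
  expect_lt(fam_check(0), 1e-3)   # absent without injection
})

test_that("infeasible or invalid configurations are rejected", {
  expect_error(synth_config(duration_s = -1), "duration")
  expect_error(synth_config(fs = 100), "fs")
  expect_error(synth_config(pac_depth = 2), "pac_depth")
  expect_error(synth_config(cooccurrence_prob = 1.5), "cooccurrence")
  expect_error(synth_config(ripple_rate_per_min = c(-1, 0)), "rates")
})
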