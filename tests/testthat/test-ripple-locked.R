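# Event-locked ERP, ERP spectra, TF power and ITPC with surrogate nulls.

# Small locked-analysis scenario reused across tests: SPW-ripple events
# placed on a 1/f background, 20-frequency decomposition.
fix_locked <- function() {
  fixture("locked", function() {
    fs <- 1000
    cfg <- synth_config(duration_s = 240, seed = 81,
                        ripple_rate_per_min = c(12, 0),
                        spindle_rate_per_min = 0, artifact_rate_per_min = 0,
                        cooccurrence_prob = 0)
    syn <- synthesize_lfp(cfg)
    x <- apply_filters(syn$signals[, 1], fs)
    tr <- whole_trial(x, fs)
    ev <- detect_ripples(x, fs, tr)
    ss <- make_surrogate_events(ev, tr, fs, n_sets = 400, seed = 82)
    fam <- fix_family20()
    concat <- tf_concatenate(list(tf_decompose(x, fs, fam, start_sample = 1L)))
    list(x = x, fs = fs, ev = ev, ss = ss, concat = concat, syn = syn, tr = tr)
  })
}

test_that("a noiseless repeated waveform is recovered exactly by the locked ERP", {
  fs <- 1000
  x <- numeric(120 * fs)
  shape <- sin(2 * pi * 4 * ((-750:750) / fs)) * exp(-((-750:750) / 300)^2)
  peaks <- seq(5000, 115000, by = 5000)
  for (p in peaks) x[(p - 750):(p + 750)] <- x[(p - 750):(p + 750)] + shape
  erp <- locked_erp(x, fs, peaks)
  expect_equal(erp$erp, shape - mean(shape), tolerance = 1e-10)
  expect_equal(length(erp$time_s), 1501)
})

test_that("locked ERP of events on noise stays inside the surrogate CI", {
  fs <- 1000
  set.seed(83)
  x <- generate_background(240, fs, 100, -2, seed = 84)
  tr <- whole_trial(x, fs)
  peaks <- sort(sample(2000:(238 * fs), 25))
  fake <- data.frame(start = peaks - 20L, end = peaks + 20L, peak = peaks,
                     peak_s = (peaks - 1) / fs, duration_ms = 40)
  class(fake) <- c("ripple_events", class(fake))
  attr(fake, "fs") <- fs
  ss <- make_surrogate_events(fake, tr, fs, n_sets = 400, seed = 85)
  erp <- locked_erp(x, fs, peaks, ss)
  covered <- mean(erp$erp >= erp$ci_lo & erp$erp <= erp$ci_hi)
  expect_gte(covered, 0.9)
})

test_that("SPW-ripple events produce a supra-CI deflection and an SPW-band ERP spectrum", {
  fx <- fix_locked()
  erp <- locked_erp(fx$x, fx$fs, fx$ev$peak, fx$ss)
  center <- abs(erp$time_s) < 0.2
  expect_true(any(erp$erp[center] > erp$ci_hi[center] |
                  erp$erp[center] < erp$ci_lo[center]))
  es <- erp_spectrum(erp)
  expect_equal(round(es$resolution, 3), 0.488)
  spw <- es$freqs >= 2 & es$freqs <= 8
  expect_gt(max(es$z[spw]), 3)
})

test_that("the ERP spectrum Welch design resolves a pure tone", {
  fs <- 1000
  erp <- structure(list(erp = sin(2 * pi * 4 * (0:1500) / fs),
                        surrogate_erps = matrix(stats::rnorm(20 * 1501), 20),
                        fs = fs, time_s = (-750:750) / fs, n_events = 20),
                   class = "locked_erp")
  es <- erp_spectrum(erp)
  expect_lt(abs(es$freqs[which.max(es$raw)] - 4), es$resolution)
})

test_that("locked TF power shows a ripple-band response and calibrated surrogate-as-true nulls", {
  fx <- fix_locked()
  pmap <- locked_tf_power(fx$concat, fx$ev$peak, fx$ss)
  rb <- pmap$freqs >= 65 & pmap$freqs <= 110
  tc <- abs(pmap$time_s) < 0.05
  expect_gt(max(pmap$z_map[rb, tc]), max(pmap$levels))
  expect_gte(length(pmap$clusters), 1)
  # locking on a surrogate set instead of true events leaves the map null
  fake_peaks <- fx$ss[1, ]
  ss_rest <- fx$ss[-1, ]
  pnull <- locked_tf_power(fx$concat, fake_peaks, ss_rest)
  # |z| > 2 has two-sided normal mass 4.6%; allow finite-surrogate inflation
  expect_lt(mean(abs(pnull$z_map) > 2), 0.07)
  # same events and surrogates give identical maps
  pmap2 <- locked_tf_power(fx$concat, fx$ev$peak, fx$ss)
  expect_identical(pmap$z_map, pmap2$z_map)
})

test_that("locked ITPC is 1 for identical snippets and finds SPW phase alignment", {
  # identical phase structure across events
  fs_eff <- 250
  n <- 20000
  tt <- (0:(n - 1)) / fs_eff
  vals <- rbind(exp(2i * pi * 4 * tt), exp(2i * pi * 13 * tt))
  concat <- structure(list(values = vals, freqs = c(4, 13), fs_eff = fs_eff,
                           col_sample = seq_len(n) * 4L, stage = "N2"),
                      class = "tf_concat")
  peaks <- seq(2000, 70000, by = 1000)  # all at the same 4-Hz phase
  cols <- ripplekit:::tf_event_columns(concat, peaks, 187)
  itpc_direct <- Mod(rowMeans(matrix(vals[1, cols], nrow = 1)))
  expect_equal(itpc_direct, 1, tolerance = 1e-10)

  fx <- fix_locked()
  imap <- locked_itpc(fx$concat, fx$ev$peak, fx$ss)
  spw <- imap$freqs >= 2 & imap$freqs <= 8
  tc <- abs(imap$time_s) < 0.1
  expect_gt(max(imap$z_map[spw, tc]), 3)
  # null calibration with surrogate-as-true
  inull <- locked_itpc(fx$concat, fx$ss[2, ], fx$ss[-2, ])
  expect_lt(mean(abs(inull$z_map) > 2), 0.07)
})

test_that("event windows that leave the decomposed data are refused", {
  fx <- fix_locked()
  expect_error(locked_tf_power(fx$concat, c(100L), fx$ss), "coverage")
})
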