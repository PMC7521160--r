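# AEC / PLV and their time-shift surrogate normalization.

mk_seg <- function(values, fs_eff = 250, freqs = NULL) {
  if (is.null(freqs)) freqs <- seq_len(nrow(values))
  structure(list(values = values, freqs = freqs, fs_eff = fs_eff,
                 col_sample = seq_len(ncol(values)) * 4L, segment = 1L),
            class = "tf_segment")
}

rand_tf <- function(nf, n, seed) {
  set.seed(seed)
  matrix(complex(real = stats::rnorm(nf * n), imaginary = stats::rnorm(nf * n)),
         nf, n)
}

test_that("AEC is a rank correlation: self = 1, monotone-invariant, tight null", {
  a <- mk_seg(rand_tf(50, 15000, 1))
  expect_equal(aec(a, a), rep(1, 50))
  b <- a
  b$values <- matrix(complex(modulus = exp(Mod(a$values)),
                             argument = Arg(a$values)), nrow = 50)
  expect_equal(aec(a, b), rep(1, 50))
  indep <- mk_seg(rand_tf(50, 15000, 2))
  expect_true(all(abs(aec(a, indep)) < 0.03))
})

test_that("PLV is 1 for identical or constant-lag segments and Rayleigh-small under independence", {
  a <- mk_seg(rand_tf(20, 15000, 3))
  expect_equal(plv(a, a), rep(1, 20))
  b <- a
  b$values <- a$values * exp(-1i * pi / 3)
  expect_equal(plv(a, b), rep(1, 20))
  # Rayleigh null: E[PLV] ~ sqrt(pi)/(2 sqrt(n)) for uniform phases
  set.seed(4)
  n <- 15000
  draws <- replicate(100, {
    pa <- mk_seg(matrix(exp(2i * pi * stats::runif(n)), 1))
    pb <- mk_seg(matrix(exp(2i * pi * stats::runif(n)), 1))
    plv(pa, pb)
  })
  expected <- sqrt(pi) / (2 * sqrt(n))
  expect_lt(abs(mean(draws) - expected) / expected, 0.5)
})

test_that("FFT-based shifted metrics equal direct recomputation on shifted series", {
  nf <- 4
  n <- 2000
  a <- mk_seg(rand_tf(nf, n, 5), fs_eff = 250)
  b <- mk_seg(rand_tf(nf, n, 6), fs_eff = 250)
  res <- normalize_by_timeshift(a, b, metric = "plv", n_surr = 5,
                                shift_range_s = c(1, 7), seed = 7)
  expect_equal(res$raw, plv(a, b))
  set.seed(7)
  shifts <- sample(250:(7 * 250), 5, replace = TRUE)
  for (s in shifts[1:2]) {
    bs <- b
    bs$values <- b$values[, c((n - s + 1):n, 1:(n - s)), drop = FALSE]
    direct_plv <- plv(a, bs)
    direct_aec <- aec(a, bs)
    # the circular identity reproduces the directly shifted metrics
    pa <- ripplekit:::unit_phasor(a$values[1, ])
    pb <- ripplekit:::unit_phasor(b$values[1, ])
    all_shifts <- Mod(ripplekit:::circ_corr_conj(pa, pb)) / n
    expect_equal(all_shifts[s + 1], direct_plv[1], tolerance = 1e-10)
    ra <- rank(Mod(a$values[1, ])); rb <- rank(Mod(b$values[1, ]))
    zra <- (ra - mean(ra)) / (stats::sd(ra) * sqrt((n - 1) / n))
    zrb <- (rb - mean(rb)) / (stats::sd(rb) * sqrt((n - 1) / n))
    corr_all <- Re(ripplekit:::circ_corr_conj(zra, zrb)) / n
    expect_equal(corr_all[s + 1], direct_aec[1], tolerance = 1e-10)
  }
})

test_that("time-shift z-scores separate aligned from independent channels", {
  fam <- fix_family20()
  x <- generate_background(62, 1000, 100, -2, seed = 31)
  y <- generate_background(62, 1000, 100, -2, seed = 32)
  sx <- decompose_segments(x, 1000, fam)[[1]]
  sy <- decompose_segments(y, 1000, fam)[[1]]
  same <- normalize_by_timeshift(sx, sx, metric = "aec", seed = 41)
  expect_true(all(same$z > 2))
  indep <- normalize_by_timeshift(sx, sy, metric = "aec", seed = 42)
  expect_gte(mean(abs(indep$z) < 2), 0.9)
  # reproducibility
  again <- normalize_by_timeshift(sx, sy, metric = "aec", seed = 42)
  expect_identical(indep$z, again$z)
  # rough symmetry of the two null choices
  rev_dir <- normalize_by_timeshift(sy, sx, metric = "aec", seed = 43)
  expect_lt(abs(mean(indep$z) - mean(rev_dir$z)), 0.5)
})

test_that("generator co-occurrence and shared events elevate band-specific connectivity", {
  fam <- fix_family20()
  mk <- function(prob, seed) {
    cfg <- synth_config(duration_s = 125, seed = seed,
                        ripple_rate_per_min = c(20, 2),
                        cooccurrence_prob = prob, cooccurrence_lag_sd_ms = 5,
                        spindle_rate_per_min = 6, spindle_shared_prob = 1,
                        artifact_rate_per_min = 0)
    syn <- synthesize_lfp(cfg)
    sa <- decompose_segments(apply_filters(syn$signals[, 1], 1000), 1000, fam)
    sb <- decompose_segments(apply_filters(syn$signals[, 2], 1000), 1000, fam)
    connectivity_spectrum(sa, sb, seed = seed)
  }
  coupled <- as.data.frame(mk(0.9, 61))
  uncoupled <- as.data.frame(mk(0, 62))
  band_mean <- function(df, metric, lo, hi) {
    mean(df$mean_z[df$metric == metric & df$freq_hz >= lo & df$freq_hz <= hi])
  }
  # ripple-band amplitude correlation rises with forced co-occurrence
  expect_gt(band_mean(coupled, "AEC", 70, 85),
            band_mean(uncoupled, "AEC", 70, 85))
  # shared spindles phase-lock the spindle-band wavelet rows (the 20-center
  # log grid has its spindle-range centers at 11.7 and 16.1 Hz)
  expect_gt(band_mean(coupled, "PLV", 11, 17), 2)
  expect_gt(band_mean(coupled, "PLV", 11, 17), band_mean(uncoupled, "PLV", 11, 17))
})
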