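# Debiased phase-amplitude coupling.

test_that("dPAC has its analytic value for sinusoidal modulation", {
  n <- 3600
  phi <- (0:(n - 1)) * 2 * pi / n  # full cycles, uniform
  expect_equal(dpac(phi, 1 + cos(phi)), 0.5, tolerance = 1e-12)
  expect_equal(dpac(phi, rep(3, n)), 0, tolerance = 1e-12)
  expect_error(dpac(numeric(0), numeric(0)), "empty")
  expect_error(dpac(phi, 1:10), "equal length")
})

test_that("debiasing removes spurious coupling from clustered phases", {
  set.seed(21)
  n <- 20000
  phi <- stats::rnorm(n, 0, 0.7)  # clustered (wrapped-normal) phases
  amp <- abs(stats::rnorm(n)) + 0.5  # independent of phase
  raw_mvl <- Mod(mean(amp * exp(1i * phi)))
  expect_gt(raw_mvl, 0.1 * mean(amp))   # undebiased metric is fooled
  expect_lt(dpac(phi, amp), 0.02 * mean(amp))  # dPAC is not
})

test_that("dPAC scales linearly with amplitude and reduces to MVL for uniform phases", {
  set.seed(22)
  n <- 5000
  phi <- stats::runif(n, 0, 2 * pi)
  amp <- abs(stats::rnorm(n)) + 0.2
  expect_equal(dpac(phi, 3 * amp), 3 * dpac(phi, amp), tolerance = 1e-12)
  # with near-zero bias B the debiased and classic mean vector lengths agree
  phi_u <- (0:(n - 1)) * 2 * pi / n
  amp_u <- stats::runif(n)
  expect_equal(dpac(phi_u, amp_u), Mod(mean(amp_u * exp(1i * phi_u))),
               tolerance = 1e-10)
})

test_that("the comodulogram grid respects the f2 > 2 f1 admissibility rule", {
  fam <- fix_family20()
  x <- generate_background(62, 1000, 100, -2, seed = 51)
  segs <- decompose_segments(x, 1000, fam)
  pg <- comodulogram(segs, segs, n_surr = 10, seed = 1)
  for (i in seq_along(pg$f1)) {
    for (j in seq_along(pg$f2)) {
      if (pg$f2[j] <= 2 * pg$f1[i]) {
        expect_true(is.na(pg$dpac_raw[i, j, 1]))
      }
    }
  }
  expect_true(all(pg$dpac_raw[!is.na(pg$dpac_raw)] >= 0))
})

test_that("comodulogram raw and z match direct per-pair computation", {
  fam <- fix_family20()
  x <- generate_background(62, 1000, 100, -2, seed = 52)
  segs <- decompose_segments(x, 1000, fam)
  pg <- comodulogram(segs, segs, n_surr = 20, seed = 9)
  seg <- segs[[1]]
  i1 <- 5
  i2 <- which(pg$admissible[i1, ])[3]
  expect_equal(pg$dpac_raw[i1, i2, 1],
               dpac(Arg(seg$values[i1, ]), Mod(seg$values[i2, ])),
               tolerance = 1e-10)
  # shifted value from the FFT identity equals direct dpac on shifted phases
  n <- ncol(seg$values)
  s <- 3000
  ph <- Arg(seg$values[i1, ])
  ph_s <- ph[c((n - s + 1):n, 1:(n - s))]
  direct <- dpac(ph_s, Mod(seg$values[i2, ]))
  M <- Mod(seg$values[i2, ]); P <- exp(1i * ph)
  D <- stats::fft(stats::fft(M) * stats::fft(P)[c(1, n:2)], inverse = TRUE) / n
  vals <- Mod(D / n - mean(M) * mean(P))
  expect_equal(vals[s + 1], direct, tolerance = 1e-10)
})

test_that("injected SPW-ripple coupling is localized in the comodulogram", {
  fam <- fix_family()
  cfg <- synth_config(duration_s = 125, seed = 9, ripple_rate_per_min = c(30, 0),
                      spindle_rate_per_min = 0, artifact_rate_per_min = 0,
                      spw_freq_hz = c(4, 4), cooccurrence_prob = 0, pac_depth = 1)
  syn <- synthesize_lfp(cfg)
  segs <- decompose_segments(apply_filters(syn$signals[, 1], 1000), 1000, fam)
  pg <- comodulogram(segs, segs, seed = 7)
  zbar <- apply(pg$dpac_z, c(1, 2), mean)
  im <- which(zbar == max(zbar, na.rm = TRUE), arr.ind = TRUE)
  expect_gt(max(zbar, na.rm = TRUE), 3)
  expect_true(pg$f1[im[1]] >= 2.5 && pg$f1[im[1]] <= 10)  # delta/theta modulator
  # the global maximum may sit on the ripple burst's spectral skirt; the
  # ripple band proper must carry strong coupling too
  expect_true(pg$f2[im[2]] >= 50 && pg$f2[im[2]] <= 110)
  expect_gt(max(zbar[pg$f1 >= 2.5 & pg$f1 <= 10,
                     pg$f2 >= 65 & pg$f2 <= 100], na.rm = TRUE), 3)
  prof <- ripple_band_modulation_profile(pg)
  expect_equal(nrow(prof), sum(pg$f1 <= 85))
  pk <- prof$f1_hz[which.max(prof$mean_z)]
  expect_true(pk >= 2.5 && pk <= 8)

  # cross-site grids in both directions see forced cross-regional coupling
  cfg2 <- synth_config(duration_s = 125, seed = 10, ripple_rate_per_min = c(30, 1),
                       spindle_rate_per_min = 0, artifact_rate_per_min = 0,
                       spw_freq_hz = c(4, 4), cooccurrence_prob = 1,
                       cooccurrence_lag_sd_ms = 5, pac_depth = 1)
  syn2 <- synthesize_lfp(cfg2)
  sa <- decompose_segments(apply_filters(syn2$signals[, 1], 1000), 1000, fam)
  sb <- decompose_segments(apply_filters(syn2$signals[, 2], 1000), 1000, fam)
  for (grids in list(comodulogram(sa, sb, seed = 11, site = "a_phase_b_amp"),
                     comodulogram(sb, sa, seed = 12, site = "b_phase_a_amp"))) {
    zc <- apply(grids$dpac_z, c(1, 2), mean)
    sub <- zc[grids$f1 >= 2 & grids$f1 <= 10, grids$f2 >= 65 & grids$f2 <= 100]
    expect_gt(max(sub, na.rm = TRUE), 3)
  }
})

test_that("an uncoupled recording keeps the comodulogram near its null", {
  fam <- fix_family20()
  cfg <- synth_config(duration_s = 125, seed = 10, ripple_rate_per_min = c(30, 0),
                      spindle_rate_per_min = 0, artifact_rate_per_min = 0,
                      spw_amp_uv = 0, cooccurrence_prob = 0, pac_depth = 0)
  syn <- synthesize_lfp(cfg)
  segs <- decompose_segments(apply_filters(syn$signals[, 1], 1000), 1000, fam)
  pg <- comodulogram(segs, segs, seed = 13)
  zbar <- apply(pg$dpac_z, c(1, 2), mean)
  expect_lte(mean(zbar > 2, na.rm = TRUE), 0.08)
})

test_that("cluster significance finds planted coupling and rejects single-bin effects", {
  set.seed(30)
  nf <- 12
  freqs <- 10^seq(log10(0.5), log10(200), length.out = nf)
  adm <- outer(freqs, freqs, function(f1, f2) f2 > 2 * f1)
  mk_grid <- function(bump) {
    zz <- array(NA_real_, c(nf, nf, 30))
    for (s in 1:30) {
      m <- matrix(stats::rnorm(nf * nf), nf, nf)
      if (bump) m[2:4, 9:11] <- m[2:4, 9:11] + 1.5
      m[!adm] <- NA
      zz[, , s] <- m
    }
    structure(list(f1 = freqs, f2 = freqs, admissible = adm,
                   dpac_raw = abs(zz), dpac_z = zz, site = "same",
                   n_segments = 30), class = "pac_grid")
  }
  res <- pac_significance(mk_grid(TRUE), seed = 31)
  sig <- Filter(function(cl) cl$significant, res$clusters)
  expect_gte(length(sig), 1)
  res0 <- pac_significance(mk_grid(FALSE), seed = 32)
  expect_length(Filter(function(cl) cl$significant, res0$clusters), 0)
})
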