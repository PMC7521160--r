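---
title: "Sharp wave-ripple analysis in two-channel NREM iEEG: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sharp wave-ripple analysis in two-channel NREM iEEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ripplekit)
```

## What the package computes

ripplekit analyzes two simultaneously recorded bipolar intracranial LFP
channels (canonically hippocampus, HPC, and amygdala, AMY) during NREM sleep
and quantifies sharp wave-ripple (SPW-ripple) activity and its coordination
between the two sites. The stages are:

1. **Preprocessing.** Zero-phase 0.3-Hz high-pass and 50-Hz-harmonic notch
   filtering; artifact rejection by channel-specific z thresholds (z > 6) on
   the signal gradient and on >250-Hz Hilbert-envelope activity; segmentation
   into artifact-free "trials" of at least 3 s that never span a sleep-stage
   change (stages N2/N3 only).
2. **Spectra.** Welch power spectral densities with 3-s Hann windows, 80%
   overlap and zero-padding to 4096 points (0.244-Hz bins at 1 kHz), averaged
   across trials with trial durations as weights; then a power-law fit
   `a f^b` (ordinary least squares on log10-log10, 4-175 Hz, after modified
   Akima interpolation across the notched regions) is subtracted, and the
   residual is resampled to 200 log-spaced bins and smoothed three times with
   a 5-bin moving average, exposing narrowband peaks such as the 70-85-Hz
   ripple band.
3. **Time-frequency decomposition.** Complex Morlet wavelets parametrized by
   their temporal FWHM `h`: kernel `exp(i 2 pi f t) exp(-4 ln2 t^2 / h^2)`,
   50 log-spaced center frequencies 0.5-200 Hz, `h` log-spaced from 3 s to
   25 ms (spectral FWHM `4 ln2 / (pi h)`: 0.3 Hz to 35 Hz). Trials are
   mirror-extended by 5 s, convolved, trimmed, decimated by 4 (250-Hz
   effective rate), concatenated per stage and cut into 60-s segments
   (trailing remainder discarded).
4. **Connectivity.** Per 60-s segment and frequency: amplitude envelope
   correlation (Spearman of the magnitude series) and phase locking value
   `|mean exp(i (phi_a - phi_b))|`, each z-scored against 100 surrogates made
   by circularly time-shifting one channel by 1-59 s.
5. **Phase-amplitude coupling.** Debiased PAC,
   `dPAC = |mean(amp_f2 (exp(i phi_f1) - B))|` with bias `B = mean exp(i
   phi_f1)`, over all frequency pairs with `f2 > 2 f1`, z-scored against 100
   time shifts of the phase series; same-site and cross-site grids; cluster
   significance by one-tailed one-sample t tests across segments with a
   cluster-based permutation test (clusteralpha 0.1, 1000 sign-flip
   permutations, minimum 2 x 2 extent, P < 0.05).
6. **Ripple detection.** 70-110-Hz zero-phase FIR band-pass (5-Hz
   transitions), Hilbert envelope z-scored over all clean NREM samples of the
   channel; events seeded where z > 2.5 and extended to the surrounding
   z = 2 crossings; kept if at least 35 ms long with 0.75 s of clean data on
   both sides of the envelope peak. Per event: duration, maximum
   ripple-filtered amplitude, main frequency (8x zero-padded FFT argmax), and
   per channel the density per clean minute.
7. **Surrogate events.** 1000 sets of pseudo-event times, each the size of
   the true event list, drawn uniformly from clean samples whose 1.5-s window
   does not overlap any true ripple's 1.5-s window.
8. **Co-occurrence.** Percentage of one channel's ripple peaks falling within
   a centered 1.5-s / 500-ms / 100-ms window of any peak in the other
   channel; empirical P as the proportion of the 1000 surrogate-set rates at
   least as large; signed peak-lag distribution for precise (100-ms)
   co-occurrences.
9. **Ripple-locked maps.** Over 1.5-s windows centered on ripple peaks:
   mean-centered ERP with a pointwise 95% surrogate CI; Welch ERP spectra
   (1.25-s windows, 95% overlap, 0.488-Hz bins) z-scored against surrogate
   ERP spectra; time-frequency power (z-scored per frequency over all NREM
   data, averaged over events, z-scored against the 1000 surrogate means) and
   intertrial phase clustering, with cluster outlines at up to five integer z
   levels between the lowest informative Z >= 3 and the highest productive
   Z <= 25 (clusters must span >= 2 frequency bins and 10 time bins = 36 ms).

`run_pipeline()` executes all stages deterministically from one master seed.

## The synthetic generator and what it emulates

Because clinical recordings of this kind are not public, the package ships a
generator (`synth_config()`, `synthesize_lfp()`) whose ground truth makes
every stage testable. It produces, per channel:

* a 1/f background (frequency-domain shaping: spectral amplitude
  `sqrt(a) f^(b/2)` with random phases, so the PSD is `a f^b`);
* ripples: Hann-windowed sinusoids at 80 Hz, duration ~N(50, 10^2) ms
  truncated at 35 ms, each riding on a biphasic SPW transient (one
  Gaussian-windowed cycle at a frequency drawn from 2-8 Hz) whose phase at
  the ripple peak is fixed (`spw_ripple_phase`), so ripples are locked to a
  consistent SPW phase;
* spindles: 1-s waxing-waning 13-Hz sinusoids, optionally copied verbatim
  into the other channel (`spindle_shared_prob`) to create spindle-band phase
  locking;
* cross-channel co-occurrence: each channel-1 ripple spawns a channel-2
  ripple with probability `cooccurrence_prob` at a Gaussian lag
  (`cooccurrence_lag_sd_ms`), sharing the parent's SPW frequency;
* optional delta-phase modulation of ripple amplitude
  (`1 + pac_depth cos(phase)`) against a common delta carrier;
* artifacts: high-amplitude spikes (8 ms) and steps (200 ms).

Event times are Poisson, thinned so same-channel ripples are at least 200 ms
apart (the detector assumes separable events). All randomness flows through
named sub-streams of one master seed, so identical configurations give
bit-identical signals and ground truth.

**Default conditions.** The defaults encode the study conditions the
pipeline targets: 1 kHz sampling; HPC ripple rate 5.5/min; AMY independent
rate 2.0/min, which with the default `cooccurrence_prob = 0.1` gives a total
AMY rate near 2.6/min; ripple amplitudes 12 and 6.3 uV; ripple duration
~50 ms at 80 Hz; SPW transients of 30 uV drawn from 2-8 Hz; background
`a = 100, b = -2` (~15-uV RMS, ripple-band SD ~0.9 uV, placing the default
ripple amplitudes at roughly 14x and 7x the in-band background). Lag SD
15 ms reflects the pooled cross-site timing spread reported for precise
co-occurrences.

**What the generator does not model**, and hence what passing tests do not
establish about real data: bursty (non-Poisson) ripple trains — real HPC
ripples cluster, which is why observed direction asymmetries of co-occurrence
can be opposite to the generator's (the spawning model makes the sparser
channel's partnered fraction the larger one); epileptiform discharges beyond
simple spike/step artifacts; state transitions inside an epoch;
nonstationary background spectra; and genuine conduction/propagation delays
beyond a fixed Gaussian lag.

## Numerical choices

* **Filtering.** High-pass and notches are 2nd-order zero-phase IIR
  (Butterworth; RBJ biquad notch, Q = 35) applied forward-backward with odd
  (point-symmetric) end extension, which keeps value and slope continuous at
  the joins and suppresses edge transients. The ripple band-pass is a ~1-s
  linear-phase FIR applied by centered convolution (exactly zero phase),
  giving >= 40 dB stopband with the 5-Hz transitions; phase linearity ahead
  of the Hilbert transform is mandatory.
* **Artifact rejection** runs on filtered signals; the >250-Hz criterion is
  the Hilbert envelope of a 250-(Nyquist-10)-Hz band-pass; flags are dilated
  by 250 ms to keep filter ringing out of trials. A numerical guard skips
  the criterion when the high-frequency envelope is below 1e-5 of the signal
  SD (otherwise z-scoring amplifies numerical noise on synthetic tones).
* **Welch.** Windows never cross trial boundaries; NFFT is the next power of
  two above the window, which reproduces the 0.244-Hz and 0.488-Hz bin
  spacings; one-sided densities in uV^2/Hz (Parseval-checked).
* **Power-law adjustment.** The fit uses the notch-interpolated spectrum,
  base-10 logs, `a = 10^intercept`; 200 log-spaced resample points; the
  5-bin moving average shrinks symmetrically at the edges.
* **Wavelets** are truncated where the envelope falls below 1e-4 of its peak
  and normalized to unit energy (the normalization cancels in every z-scored
  quantity). Decimation keeps every 4th sample with no anti-alias filter —
  the magnitude and phase series are already band-limited by the kernel.
  Mirror padding (5 s) uses reflective index folding so that trials shorter
  than the pad still extend cleanly.
* **Surrogate time shifts** are evaluated through the circular
  cross-correlation identity, so the metric at every integer shift is exact
  and identical to direct recomputation on the shifted series (unit-tested
  both ways); shifts are drawn once per iteration and applied to all
  frequencies jointly.
* **Cluster machinery** uses 4-connectivity, sign-homogeneous clusters,
  bounding-box extent rules, and sign-flip permutations with the maximum
  cluster mass statistic. Outline levels are spaced evenly with ties rounded
  down (3, 8, 14, 19, 25 for the full 3-25 range).
* **Degenerate inputs** fail loudly: constant series (zero-variance z), empty
  trial sets, spectra with nonpositive power in the fit range, surrogate
  nulls with zero spread, event windows that would cross a trial boundary.

## Design decisions that were genuinely open

* **Trials for cross-channel analyses** are cut from the union of both
  channels' artifact masks, because AEC/PLV/PAC/co-occurrence all require
  simultaneously clean data. z thresholds stay channel-specific.
* **Time-shift surrogates and stationary carriers.** A circular shift of a
  stationary sinusoid's phase series only rotates its phasors, and both PLV
  (through the phase difference) and dPAC (through the modulus) are
  invariant to a global rotation; a continuous sinusoidal carrier is
  therefore invisible to this null. Detectable coupling and phase locking
  must be carried by transients — which is precisely what SPW-ripple
  complexes and spindles are. Tests that must localize injected coupling fix
  the SPW frequency at 4 Hz; the comodulogram maximum then falls in the
  delta/theta band, slightly above 4 Hz, because a one-cycle transient has
  ~1.3-Hz spectral spread and the 1/f background weighs its upper edge.
* **Detector operating point.** With the stated thresholds (envelope
  z 2.5/2.0, >= 35 ms between the lower crossings), detection of ~50-ms
  Hann-windowed bursts requires amplitudes well above the in-band background:
  a burst at 3x the ripple-band SD has an envelope z peak near the upper
  threshold and lower-crossing spans of ~16-30 ms, so recall at that level is
  poor by construction; recall exceeds 90% from roughly 10x, where the
  default (study-scale) amplitudes sit. The same thresholds produce an
  intrinsic false-positive rate of ~2 events/min on pure Gaussian 1/f
  background (scale-free in the z-scored envelope). The envelope is not
  smoothed before thresholding.
* **Locked-map windows** use 187 columns per side at the 250-Hz effective
  rate (+-0.748 s), the largest symmetric window guaranteed to stay inside
  the 0.75-s clean margins after decimation.
* **Surrogate seed sharing**: ERP, ERP spectra, power and ITPC all consume
  the same 1000 surrogate sets, mirroring the single surrogate construction
  per channel.
* **Problem sizes in the shipped tests** are chosen for a desk-scale run:
  5-125-s syntheses for unit properties, a 420-s recording with 1000
  surrogate sets for the end-to-end suite, 20-frequency wavelet grids for
  null-calibration loops (200 runs), the full 50-frequency grid wherever a
  spectral location is asserted.

## Known limitations

* Rates, amplitudes and co-occurrence probabilities are homogeneous in time;
  there is no ripple burstiness, so direction asymmetries of co-occurrence do
  not reproduce the clustered-event pattern seen in real recordings.
* The EDF writer/reader covers continuous 16-bit EDF with a common sampling
  rate — not EDF+ annotations.
* Cross-site PAC assumes the two channels share one clock and the same trial
  mask; no lag compensation is attempted.
* The 1/f adjustment subtracts a single power law over 4-175 Hz; knees or
  multi-slope spectra are not modeled.
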