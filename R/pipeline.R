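# End-to-end orchestration: synthesize or load, preprocess, spectra,
# time-frequency, connectivity, PAC, ripples, co-occurrence, locked maps.

#' Run the full two-channel ripple analysis pipeline
#'
#' Executes every stage in order on a synthetic recording (from a
#' [synth_config()]) or on an EDF file with stage annotations, and returns a
#' report bundle. Deterministic given `seed`: every stochastic stage draws
#' its own sub-seed from it.
#'
#' @param input A [synth_config()], a [synthesize_lfp()] object, or a list
#'   `list(edf = path, stages = path)`.
#' @param seed Master seed (default 1).
#' @param out_dir Optional output directory for delimited-text exports.
#' @param n_freqs Number of wavelet center frequencies (default 50).
#' @param n_surrogate_sets Surrogate event sets for locked analyses
#'   (default 1000).
#' @param n_shift_surrogates Time-shift surrogates for connectivity and PAC
#'   (default 100).
#' @param stages Sleep stages to analyze (default `c("N2", "N3")`).
#' @param do_connectivity,do_pac,do_locked,do_pac_clusters Stage switches.
#' @return Object of class `ripple_report`.
#' @export
run_pipeline <- function(input, seed = 1L, out_dir = NULL,
                         n_freqs = 50, n_surrogate_sets = 1000,
                         n_shift_surrogates = 100,
                         stages = c("N2", "N3"),
                         do_connectivity = TRUE, do_pac = TRUE,
                         do_locked = TRUE, do_pac_clusters = FALSE) {
  t0 <- Sys.time()
  # --- input -------------------------------------------------------------
  if (inherits(input, "synth_config")) {
    synth <- synthesize_lfp(input)
    rec <- as_recording(synth)
  } else if (inherits(input, "synth_lfp")) {
    synth <- input
    rec <- as_recording(synth)
  } else if (is.list(input) && !is.null(input$edf)) {
    synth <- NULL
    edf <- read_edf(input$edf)
    stopifnot(ncol(edf$signals) == 2)
    stage_labels <- if (!is.null(input$stages)) {
      read_stage_annotations(input$stages)
    } else rep("N2", ceiling(nrow(edf$signals) / (20 * edf$fs)))
    rec <- lfp_recording(
      channels = stats::setNames(list(edf$signals[, 1], edf$signals[, 2]),
                                 edf$labels[1:2]),
      fs = edf$fs, stages = stage_labels)
  } else {
    stop("input must be a synth_config, a synth_lfp, or list(edf=, stages=)")
  }
  fs <- rec$fs
  labels <- names(rec$channels)

  # --- preprocess --------------------------------------------------------
  rec$channels <- lapply(rec$channels, apply_filters, fs = fs)
  rec <- mask_artifacts(rec)
  trials <- segment_trials(rec, stages = stages)
  if (nrow(trials) == 0) stop("pipeline aborted at segmentation: no clean trials")

  # --- spectra -----------------------------------------------------------
  spectra <- lapply(rec$channels, function(x) {
    sp <- welch_psd(x, fs, trials)
    list(psd = sp, adjusted = adjust_one_over_f(sp))
  })

  # --- time-frequency ----------------------------------------------------
  family <- build_wavelets(fs, n_freqs = n_freqs)
  concat <- lapply(rec$channels, function(x) {
    tfs <- lapply(seq_len(nrow(trials)), function(i) {
      tf_decompose(x[trials$start[i]:(trials$end[i] - 1L)], fs, family,
                   start_sample = trials$start[i])
    })
    tf_concatenate(tfs)
  })
  segs <- lapply(concat, function(cc) {
    suppressWarnings(segment_60s(cc))
  })
  n_segments <- length(segs[[1]])

  # --- connectivity ------------------------------------------------------
  connectivity <- NULL
  if (do_connectivity && n_segments >= 1) {
    connectivity <- connectivity_spectrum(segs[[1]], segs[[2]],
                                          n_surr = n_shift_surrogates,
                                          seed = derive_seed(seed, "connectivity"))
  }

  # --- PAC ---------------------------------------------------------------
  pac <- NULL
  if (do_pac && n_segments >= 1) {
    modes <- list(
      same_1 = list(p = 1, a = 1), same_2 = list(p = 2, a = 2),
      cross_1p_2a = list(p = 1, a = 2), cross_2p_1a = list(p = 2, a = 1))
    pac <- lapply(names(modes), function(nm) {
      m <- modes[[nm]]
      grid <- comodulogram(segs[[m$p]], segs[[m$a]],
                           n_surr = n_shift_surrogates,
                           seed = derive_seed(seed, paste0("pac_", nm)),
                           site = nm)
      sig <- if (do_pac_clusters && n_segments >= 3) {
        pac_significance(grid, seed = derive_seed(seed, paste0("pacsig_", nm)))
      } else NULL
      list(grid = grid, significance = sig,
           profile = ripple_band_modulation_profile(grid))
    })
    names(pac) <- names(modes)
  }

  # --- ripples -----------------------------------------------------------
  ripples <- lapply(seq_along(labels), function(ch) {
    ev <- detect_ripples(rec$channels[[ch]], fs, trials)
    if (nrow(ev) > 0) ev <- ripple_properties(ev)
    ev
  })
  names(ripples) <- labels
  surr <- lapply(seq_along(labels), function(ch) {
    if (nrow(ripples[[ch]]) == 0) return(NULL)
    make_surrogate_events(ripples[[ch]], trials, fs, n_sets = n_surrogate_sets,
                          seed = derive_seed(seed, paste0("surr_", labels[ch])))
  })
  names(surr) <- labels

  clean_min <- sum(trials$duration_s) / 60
  ripple_summary <- do.call(rbind, lapply(seq_along(labels), function(ch) {
    ev <- ripples[[ch]]
    m <- function(v) if (nrow(ev) > 0 && !is.null(v)) mean(v) else NA_real_
    s <- function(v) if (nrow(ev) > 1 && !is.null(v)) stats::sd(v) else NA_real_
    data.frame(
      channel = labels[ch], n = nrow(ev),
      density_per_min = nrow(ev) / clean_min,
      duration_ms = m(ev$duration_ms), duration_sd = s(ev$duration_ms),
      main_freq_hz = m(ev$main_freq_hz), main_freq_sd = s(ev$main_freq_hz),
      amplitude_uv = m(ev$amplitude_uv), amplitude_sd = s(ev$amplitude_uv))
  }))

  # --- co-occurrence -----------------------------------------------------
  cooccurrence <- NULL
  timing <- NULL
  if (nrow(ripples[[1]]) > 0 && nrow(ripples[[2]]) > 0) {
    cooccurrence <- cooccurrence_table(ripples[[1]]$peak_s, ripples[[2]]$peak_s,
                                       surr[[1]], surr[[2]], labels = labels)
    timing <- timing_differences(ripples[[1]]$peak_s, ripples[[2]]$peak_s)
  }

  # --- locked analyses ---------------------------------------------------
  locked <- NULL
  if (do_locked) {
    locked <- list()
    combos <- list()
    for (ch in 1:2) {
      if (nrow(ripples[[ch]]) >= 10) {
        combos[[paste0("same_", labels[ch])]] <- list(ev = ch, sig = ch)
      }
    }
    for (ch in 1:2) {
      other <- 3 - ch
      if (nrow(ripples[[ch]]) >= 10) {
        combos[[paste0("cross_", labels[ch], "_ripples_", labels[other], "_signal")]] <-
          list(ev = ch, sig = other)
      }
    }
    for (nm in names(combos)) {
      cb <- combos[[nm]]
      ev <- ripples[[cb$ev]]
      ss <- surr[[cb$ev]]
      erp <- locked_erp(rec$channels[[cb$sig]], fs, ev$peak, ss)
      locked[[nm]] <- list(
        erp = erp,
        erp_spectrum = erp_spectrum(erp),
        power = locked_tf_power(concat[[cb$sig]], ev$peak, ss),
        itpc = locked_itpc(concat[[cb$sig]], ev$peak, ss))
      locked[[nm]]$erp$surrogate_erps <- NULL  # drop bulk after spectra
    }
  }

  report <- structure(list(
    labels = labels, fs = fs, seed = seed,
    trials = trials, clean_minutes = clean_min, n_segments = n_segments,
    spectra = spectra, connectivity = connectivity, pac = pac,
    ripples = ripples, surrogates = surr,
    ripple_summary = ripple_summary,
    cooccurrence = cooccurrence, timing = timing, locked = locked,
    ground_truth = if (!is.null(synth)) synth$ground_truth else NULL,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  ), class = "ripple_report")
  if (!is.null(out_dir)) export_report(report, out_dir)
  report
}

#' @export
print.ripple_report <- function(x, ...) {
  cat(sprintf("ripple pipeline report (seed %d): %.1f clean min, %d 60-s segment(s)\n\n",
              x$seed, x$clean_minutes, x$n_segments))
  cat("Ripple characteristics:\n")
  rs <- x$ripple_summary
  for (i in seq_len(nrow(rs))) {
    cat(sprintf("  %-4s n=%4d  density %.1f/min  duration %.1f +- %.1f ms  freq %.1f +- %.1f Hz  amp %.1f +- %.1f uV\n",
                rs$channel[i], rs$n[i], rs$density_per_min[i],
                rs$duration_ms[i], rs$duration_sd[i],
                rs$main_freq_hz[i], rs$main_freq_sd[i],
                rs$amplitude_uv[i], rs$amplitude_sd[i]))
  }
  if (!is.null(x$cooccurrence)) {
    cat("\nRipple co-occurrence:\n")
    co <- x$cooccurrence
    for (i in seq_len(nrow(co))) {
      cat(sprintf("  %-18s %5d ms  %5.1f%%  %s\n", co$direction[i],
                  co$window_ms[i], co$rate_percent[i], co$p_label[i]))
    }
  }
  invisible(x)
}

#' Export a pipeline report as delimited text files
#'
#' @param report A `ripple_report`.
#' @param out_dir Output directory (created if missing).
#' @export
export_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- sprintf("# seed %d", report$seed)
  for (ch in report$labels) {
    if (nrow(report$ripples[[ch]]) > 0) {
      export_events(report$ripples[[ch]], ch,
                    file.path(out_dir, paste0("ripples_", ch, ".tsv")))
    }
    export_spectrum(report$spectra[[ch]]$psd,
                    file.path(out_dir, paste0("spectrum_", ch, ".tsv")),
                    adjusted = report$spectra[[ch]]$adjusted)
  }
  if (!is.null(report$cooccurrence)) {
    utils::write.table(as.data.frame(report$cooccurrence),
                       file.path(out_dir, "cooccurrence.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  if (!is.null(report$connectivity)) {
    utils::write.table(as.data.frame(report$connectivity),
                       file.path(out_dir, "connectivity.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  if (!is.null(report$pac)) {
    for (nm in names(report$pac)) {
      export_comodulogram(report$pac[[nm]]$grid,
                          file.path(out_dir, paste0("pac_", nm, ".tsv")))
    }
  }
  if (!is.null(report$locked)) {
    for (nm in names(report$locked)) {
      export_clusters(report$locked[[nm]]$power,
                      file.path(out_dir, paste0("clusters_power_", nm, ".tsv")))
      export_clusters(report$locked[[nm]]$itpc,
                      file.path(out_dir, paste0("clusters_itpc_", nm, ".tsv")))
    }
  }
  writeLines(c(hdr, utils::capture.output(print(report))),
             file.path(out_dir, "summary.txt"))
  invisible(out_dir)
}
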