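# File interfaces: EDF signals, plain-text signals, stage annotations,
# synthesis configs, ground-truth sidecars.

pad_field <- function(x, width) {
  s <- substr(as.character(x), 1, width)
  formatC(s, width = width, flag = "-")
}

#' Write a two-channel recording as EDF
#'
#' Minimal EDF (16-bit) writer: one data record per second, physical unit
#' microvolts, physical range taken from the data.
#'
#' @param signals Numeric matrix `n x n_channels`.
#' @param fs Sampling rate in Hz (integer).
#' @param path Output file.
#' @param labels Channel labels (default column names).
#' @export
write_edf <- function(signals, fs, path, labels = colnames(signals)) {
  stopifnot(is.matrix(signals), fs == round(fs))
  ns <- ncol(signals)
  if (is.null(labels)) labels <- paste0("ch", seq_len(ns))
  n_rec <- floor(nrow(signals) / fs)
  signals <- signals[seq_len(n_rec * fs), , drop = FALSE]
  pmin_ <- apply(signals, 2, min)
  pmax_ <- apply(signals, 2, max)
  pmax_[pmax_ == pmin_] <- pmin_[pmax_ == pmin_] + 1
  dmin <- -32768
  dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8), pad_field("X X X X", 80), pad_field("X X X", 80),
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    pad_field(256 * (1 + ns), 8), pad_field("", 44),
    pad_field(n_rec, 8), pad_field(1, 8), pad_field(ns, 4)
  )
  writeChar(hdr, con, eos = NULL)
  fields <- list(
    vapply(labels, pad_field, "", width = 16),
    rep(pad_field("", 80), ns),
    rep(pad_field("uV", 8), ns),
    vapply(sprintf("%.6g", pmin_), pad_field, "", width = 8),
    vapply(sprintf("%.6g", pmax_), pad_field, "", width = 8),
    rep(pad_field(dmin, 8), ns),
    rep(pad_field(dmax, 8), ns),
    rep(pad_field("", 80), ns),
    rep(pad_field(fs, 8), ns),
    rep(pad_field("", 32), ns)
  )
  for (f in fields) writeChar(paste0(f, collapse = ""), con, eos = NULL)

  scale <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1) * fs + 1):(r * fs)
    for (ch in seq_len(ns)) {
      dig <- round((signals[rows, ch] - pmin_[ch]) * scale[ch] + dmin)
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file
#'
#' Reads continuous 16-bit EDF with a common sampling rate across signals.
#'
#' @param path EDF file.
#' @return List with `signals` (matrix `n x n_channels`), `fs`, `labels`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)  # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)
  nsamp <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)
  stopifnot(length(unique(nsamp)) == 1)
  fs <- nsamp[1] / rec_dur
  out <- matrix(0, n_rec * nsamp[1], ns)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", nsamp[ch], size = 2, endian = "little")
      out[((r - 1) * nsamp[ch] + 1):(r * nsamp[ch]), ch] <-
        (dig - dmin[ch]) / (dmax[ch] - dmin[ch]) * (pmax_[ch] - pmin_[ch]) + pmin_[ch]
    }
  }
  colnames(out) <- labels
  list(signals = out, fs = fs, labels = labels)
}

#' Write a recording as delimited text (time, one column per channel)
#'
#' @param signals Numeric matrix `n x n_channels`.
#' @param fs Sampling rate in Hz.
#' @param path Output path (tab-separated).
#' @export
write_signals_text <- function(signals, fs, path) {
  df <- data.frame(time_s = (seq_len(nrow(signals)) - 1) / fs)
  df <- cbind(df, as.data.frame(signals))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read sleep-stage annotations
#'
#' Two-column text: epoch index (1-based, 20-s epochs) and stage label in
#' N1/N2/N3/REM/Wake.
#'
#' @param path Annotation file.
#' @return Character vector of stage labels in epoch order.
#' @export
read_stage_annotations <- function(path) {
  df <- utils::read.table(path, header = FALSE, col.names = c("epoch", "stage"),
                          stringsAsFactors = FALSE)
  df <- df[order(df$epoch), ]
  df$stage
}

#' Read a synthesis configuration file
#'
#' Flat key-value (YAML) file whose keys mirror [synth_config()] argument
#' names exactly.
#'
#' @param path Config file.
#' @return A [synth_config()].
#' @export
read_synth_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(synth_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  do.call(synth_config, vals)
}

#' Write the synthesis ground truth as a JSON sidecar
#'
#' @param ground_truth A `synth_ground_truth`.
#' @param path Output JSON path.
#' @export
write_ground_truth <- function(ground_truth, path) {
  jsonlite::write_json(unclass(ground_truth), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
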