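#' Write a recording to disk
#'
#' Two formats are supported. `"matrix"` writes `<path>.tsv`, a plain
#' tab-separated samples x channels table (header = channel labels,
#' microvolts), plus a `<path>.yaml` sidecar with sampling rate, subject,
#' population, condition and channel order. `"edf"` writes `<path>.edf`,
#' a minimal continuous European Data Format file (16-bit samples, one-second
#' data records) with subject/population/condition packed into the patient
#' identification field; the recording length must be a whole number of
#' seconds. EDF quantises each channel to 16 bits over its physical range.
#'
#' @param rec An [new_recording()] object.
#' @param path Base path (without extension).
#' @param format `"matrix"` or `"edf"`.
#' @return The path of the main file written, invisibly.
#' @export
write_recording <- function(rec, path, format = c("matrix", "edf")) {
  stopifnot(inherits(rec, "eeg_recording"))
  format <- match.arg(format)
  if (format == "matrix") {
    tsv <- paste0(path, ".tsv")
    m <- t(rec$signal)
    colnames(m) <- rec$montage$label
    write.table(m, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    yaml::write_yaml(list(fs = rec$fs,
                          subject_id = rec$meta$subject_id,
                          population = rec$meta$population,
                          condition = rec$meta$condition,
                          unit = "uV",
                          channels = rec$montage$label),
                     paste0(path, ".yaml"))
    invisible(tsv)
  } else {
    invisible(write_edf(rec, paste0(path, ".edf")))
  }
}

#' Read a recording from disk
#'
#' Accepts the two formats of [write_recording()]. Channels are matched by
#' label against the montage and reordered to canonical order; a file with a
#' channel count other than eight, or a sidecar without a sampling rate, is a
#' format error.
#'
#' @param path Path to the `.tsv`, `.yaml` or `.edf` file, or the common base
#'   path.
#' @param format `"matrix"`, `"edf"`, or `NULL` to infer from the extension.
#' @param montage Target montage.
#' @return An `eeg_recording`.
#' @export
read_recording <- function(path, format = NULL, montage = horse_montage()) {
  if (is.null(format)) {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "matrix"
  }
  format <- match.arg(format, c("matrix", "edf"))
  if (format == "edf")
    return(read_edf(path, montage = montage))
  base <- sub("\\.(tsv|yaml)$", "", path)
  tsv <- paste0(base, ".tsv"); side <- paste0(base, ".yaml")
  if (!file.exists(tsv)) stop("matrix file not found: ", tsv)
  if (!file.exists(side)) stop("sidecar not found: ", side)
  meta <- yaml::read_yaml(side)
  if (is.null(meta$fs)) stop("format error: sidecar declares no sampling rate")
  m <- as.matrix(read.table(tsv, header = TRUE, sep = "\t",
                            check.names = FALSE))
  if (ncol(m) != nrow(montage))
    stop(sprintf("format error: expected %d channels, found %d",
                 nrow(montage), ncol(m)))
  labels <- if (!is.null(meta$channels)) unlist(meta$channels) else colnames(m)
  ord <- match(montage$label, labels)
  if (anyNA(ord))
    stop("format error: channel labels do not match the montage")
  new_recording(t(m[, ord, drop = FALSE]), fs = meta$fs,
                subject_id = meta$subject_id %||% "unknown",
                population = meta$population %||% "non-sport",
                condition = meta$condition %||% "home",
                montage = montage)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.pad_ascii <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = width, flag = "-")
}

# Minimal continuous EDF writer: 16-bit little-endian samples, one data
# record per second, physical unit microvolts.
write_edf <- function(rec, path) {
  sig <- rec$signal
  fs <- as.integer(round(rec$fs))
  n <- ncol(sig)
  if (n %% fs != 0L)
    stop("EDF export requires a whole number of seconds of signal")
  n_rec <- n %/% fs
  ns <- nrow(sig)
  pmin <- apply(sig, 1L, min); pmax <- apply(sig, 1L, max)
  flat <- pmax - pmin < 1e-9
  pmin[flat] <- pmin[flat] - 1; pmax[flat] <- pmax[flat] + 1
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  patient <- paste(rec$meta$subject_id, rec$meta$population,
                   rec$meta$condition)
  hdr <- paste0(
    .pad_ascii("0", 8), .pad_ascii(patient, 80),
    .pad_ascii("equiconn EEG", 80),
    .pad_ascii("01.01.26", 8), .pad_ascii("00.00.00", 8),
    .pad_ascii(256L * (1L + ns), 8), .pad_ascii("", 44),
    .pad_ascii(n_rec, 8), .pad_ascii("1", 8), .pad_ascii(ns, 4),
    paste(.pad_ascii(paste("EEG", rec$montage$label), 16), collapse = ""),
    paste(rep(.pad_ascii("", 80), ns), collapse = ""),
    paste(rep(.pad_ascii("uV", 8), ns), collapse = ""),
    paste(.pad_ascii(sprintf("%.2f", pmin), 8), collapse = ""),
    paste(.pad_ascii(sprintf("%.2f", pmax), 8), collapse = ""),
    paste(rep(.pad_ascii(dmin, 8), ns), collapse = ""),
    paste(rep(.pad_ascii(dmax, 8), ns), collapse = ""),
    paste(rep(.pad_ascii("", 80), ns), collapse = ""),
    paste(rep(.pad_ascii(fs, 8), ns), collapse = ""),
    paste(rep(.pad_ascii("", 32), ns), collapse = "")
  )
  writeChar(hdr, con, eos = NULL)
  # written pmin/pmax are rounded to 2 decimals; quantise against those
  pmin <- round(pmin, 2); pmax <- round(pmax, 2)
  scale <- (dmax - dmin) / (pmax - pmin)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    for (ch in seq_len(ns)) {
      d <- round((sig[ch, cols] - pmin[ch]) * scale[ch] + dmin)
      writeBin(as.integer(pmin(pmax(d, dmin), dmax)), con, size = 2L,
               endian = "little")
    }
  }
  path
}

read_edf <- function(path, montage = horse_montage()) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8)                                   # version
  patient <- rd(80); rd(80); rd(8); rd(8)
  rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (ns != nrow(montage))
    stop(sprintf("format error: expected %d channels, found %d",
                 nrow(montage), ns))
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)           # transducer
  for (i in seq_len(ns)) rd(8)            # unit
  pmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  pmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(ns)) rd(80)           # prefilter
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1L)
    stop("format error: per-channel sampling rates differ")
  fs <- spr[1L] / rec_dur
  if (!is.finite(fs) || fs <= 0) stop("format error: missing sampling rate")
  sig <- matrix(0, ns, n_rec * spr[1L])
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * spr[1L] + 1L):(r * spr[1L])
    for (ch in seq_len(ns)) {
      d <- readBin(con, "integer", n = spr[ch], size = 2L, signed = TRUE,
                   endian = "little")
      sig[ch, cols] <- (d - dmin[ch]) / (dmax[ch] - dmin[ch]) *
        (pmax[ch] - pmin[ch]) + pmin[ch]
    }
  }
  labels <- sub("^EEG ", "", labels)
  ord <- match(montage$label, labels)
  if (anyNA(ord))
    stop("format error: channel labels do not match the montage")
  meta <- strsplit(patient, " ")[[1L]]
  new_recording(sig[ord, , drop = FALSE], fs = fs,
                subject_id = if (length(meta) >= 1L) meta[1L] else "unknown",
                population = if (length(meta) >= 2L &&
                                 meta[2L] %in% c("sport", "non-sport"))
                  meta[2L] else "non-sport",
                condition = if (length(meta) >= 3L &&
                                meta[3L] %in% c("home", "guest"))
                  meta[3L] else "home",
                montage = montage)
}
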