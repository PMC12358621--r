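#' Welch estimator configuration for magnitude-squared coherence
#'
#' The study configuration is a 2000-sample Hann window, 100 samples of
#' overlap, a 1000-point transform and fs = 1000 Hz, giving a one-sided
#' frequency grid from 0 to 500 Hz in 1 Hz steps. Because the window is
#' longer than the transform, each tapered segment is wrapped modulo `nfft`
#' and summed ("wrap-and-add") before the FFT, reproducing the reference
#' behaviour of Welch estimators when window length exceeds nfft;
#' `wrap = FALSE` switches to the conventional window-length = nfft mode.
#'
#' @param window_length Taper length in samples (Hann).
#' @param noverlap Overlap between consecutive windows in samples.
#' @param nfft Transform length.
#' @param fs Sampling rate in Hz.
#' @param wrap Wrap tapered segments modulo `nfft` when the window is longer
#'   than the transform.
#' @return A `welch_config` list.
#' @export
welch_config <- function(window_length = 2000L, noverlap = 100L,
                         nfft = 1000L, fs = 1000, wrap = TRUE) {
  stopifnot(window_length >= 1L, nfft >= 1L,
            noverlap >= 0L, noverlap < window_length, fs > 0)
  if (!wrap && window_length > nfft)
    stop("window_length > nfft requires wrap = TRUE")
  structure(list(window_length = as.integer(window_length),
                 noverlap = as.integer(noverlap),
                 nfft = as.integer(nfft), fs = fs, wrap = isTRUE(wrap)),
            class = "welch_config")
}

# MATLAB-convention Hann taper without zero endpoints
.hann <- function(n) 0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1)))

# one-sided FFTs of all demeaned, tapered (and wrapped) segments:
# complex matrix (nfft/2 + 1) x K
.welch_fft <- function(x, cfg) {
  nwin <- cfg$window_length
  hop <- nwin - cfg$noverlap
  n <- length(x)
  if (n < nwin + hop)
    stop(sprintf(
      "degenerate coherence estimate: need >= 2 windows (%d samples), got %d",
      nwin + hop, n))
  starts <- seq(1L, n - nwin + 1L, by = hop)
  w <- .hann(nwin)
  seg <- vapply(starts, function(s) {
    v <- x[s:(s + nwin - 1L)]
    (v - mean(v)) * w
  }, numeric(nwin))
  nfft <- cfg$nfft
  if (nwin > nfft) {
    npad <- ceiling(nwin / nfft) * nfft
    if (npad > nwin)
      seg <- rbind(seg, matrix(0, npad - nwin, ncol(seg)))
    wrapped <- matrix(0, nfft, ncol(seg))
    for (k in seq_len(npad / nfft))
      wrapped <- wrapped + seg[((k - 1L) * nfft + 1L):(k * nfft), , drop = FALSE]
    seg <- wrapped
  } else if (nwin < nfft) {
    seg <- rbind(seg, matrix(0, nfft - nwin, ncol(seg)))
  }
  stats::mvfft(seg)[seq_len(nfft %/% 2L + 1L), , drop = FALSE]
}

.msc_from_fft <- function(X, Y) {
  sxx <- rowSums(Mod(X)^2)
  syy <- rowSums(Mod(Y)^2)
  sxy <- rowSums(X * Conj(Y))
  coh <- Mod(sxy)^2 / (sxx * syy)
  coh[sxx * syy == 0] <- NA_real_
  pmin(pmax(coh, 0), 1)
}

#' Welch magnitude-squared coherence between two series
#'
#' Estimates |S_xy|^2 / (S_xx S_yy) per frequency bin from Welch-averaged
#' cross- and auto-spectra. At least two windows are required: coherence
#' estimated from a single window is identically 1, and this degeneracy is
#' reported as an error rather than returned.
#'
#' @param x,y Equal-length numeric vectors.
#' @param cfg A [welch_config()].
#' @return List with `freq` (Hz, spacing fs/nfft) and `coherence` (same
#'   length, values in `[0, 1]`).
#' @export
msc <- function(x, y, cfg = welch_config()) {
  stopifnot(inherits(cfg, "welch_config"), length(x) == length(y))
  X <- .welch_fft(x, cfg)
  Y <- .welch_fft(y, cfg)
  list(freq = seq(0, cfg$fs / 2, by = cfg$fs / cfg$nfft),
       coherence = .msc_from_fft(X, Y))
}

#' Cross-frequency coherence: delta band of one channel vs raw other channel
#'
#' Compares the delta-filtered series of one electrode with the unfiltered
#' series of another, exposing coupling between slow activity at one site and
#' the full spectrum at the other. Both orientations are computed and
#' returned. Because delta is a lowpass keeping DC, the spectrum read at bins
#' below 4 Hz is also the within-delta coherence of the pair.
#'
#' @param rec An `eeg_recording`.
#' @param pair Length-2 vector of channel indices, or a single pair index
#'   into the canonical pair table.
#' @param cfg A [welch_config()].
#' @param segments Optional segment table; `NULL` uses the whole recording.
#' @return List with `freq`, `ab` (delta of the lower-numbered channel vs raw
#'   higher-numbered) and `ba` (the reverse orientation).
#' @export
cross_frequency_msc <- function(rec, pair, cfg = welch_config(),
                                segments = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (length(pair) == 1L) {
    pt <- build_pair_table(rec$montage)
    stopifnot(pair %in% pt$pair_index)
    pair <- c(pt$channel_a[pair], pt$channel_b[pair])
  }
  a <- min(pair); b <- max(pair)
  stopifnot(a >= 1L, b <= nrow(rec$signal), a != b)
  sig <- extract_segments(rec, segments)
  filt <- design_filter("delta", rec$fs)
  da <- zero_phase_filter(sig[a, ], filt)
  db <- zero_phase_filter(sig[b, ], filt)
  list(freq = seq(0, cfg$fs / 2, by = cfg$fs / cfg$nfft),
       ab = msc(da, sig[b, ], cfg)$coherence,
       ba = msc(db, sig[a, ], cfg)$coherence)
}

#' Coherence cube: frequency x pair x subject
#'
#' Runs the coherence estimator for all 28 pairs of every recording and
#' stacks the spectra into a three-dimensional array (frequency bin, pair,
#' subject). In `"delta-vs-raw"` mode the lower-numbered channel of each pair
#' is delta-filtered and compared with the raw other channel
#' (`orientation = "ba"` reverses this); `"raw-raw"` compares the unfiltered
#' series. A recording whose segments are too short for two windows
#' contributes an all-`NA` slice (absent, not zero) with a warning.
#'
#' @param recordings List of `eeg_recording` objects with a common sampling
#'   rate.
#' @param cfg A [welch_config()].
#' @param band_mode `"delta-vs-raw"` or `"raw-raw"`.
#' @param orientation `"ab"` or `"ba"` (ignored for `"raw-raw"`).
#' @param segments_list Optional list of segment tables, parallel to
#'   `recordings`.
#' @return 3-D numeric array with `dim = c(nfft/2 + 1, 28, n_subjects)`,
#'   dimnames over frequency/pair/subject, and attributes `freq` and
#'   `band_mode`.
#' @export
build_cube <- function(recordings, cfg = welch_config(),
                       band_mode = c("delta-vs-raw", "raw-raw"),
                       orientation = c("ab", "ba"), segments_list = NULL) {
  band_mode <- match.arg(band_mode)
  orientation <- match.arg(orientation)
  stopifnot(length(recordings) >= 1L)
  fs <- unique(vapply(recordings, `[[`, numeric(1), "fs"))
  if (length(fs) != 1L)
    stop("recordings have inconsistent sampling rates")
  if (fs != cfg$fs) stop("welch_config fs does not match the recordings")
  nb <- cfg$nfft %/% 2L + 1L
  pt <- build_pair_table(recordings[[1L]]$montage)
  subjects <- vapply(recordings, function(r) r$meta$subject_id, character(1))
  cube <- array(NA_real_, dim = c(nb, nrow(pt), length(recordings)),
                dimnames = list(NULL, pt$pair_index, subjects))
  filt <- design_filter("delta", fs)
  for (s in seq_along(recordings)) {
    sig <- tryCatch(
      extract_segments(recordings[[s]],
                       if (is.null(segments_list)) NULL else segments_list[[s]]),
      error = function(e) NULL)
    if (is.null(sig) || ncol(sig) < cfg$window_length * 2L - cfg$noverlap) {
      warning("recording ", subjects[s],
              " lacks usable segments; slice left absent")
      next
    }
    raw_fft <- lapply(seq_len(nrow(sig)), function(ch)
      .welch_fft(sig[ch, ], cfg))
    if (band_mode == "delta-vs-raw") {
      delta_fft <- lapply(seq_len(nrow(sig)), function(ch)
        .welch_fft(zero_phase_filter(sig[ch, ], filt), cfg))
    }
    for (p in seq_len(nrow(pt))) {
      a <- pt$channel_a[p]; b <- pt$channel_b[p]
      cube[, p, s] <- if (band_mode == "raw-raw") {
        .msc_from_fft(raw_fft[[a]], raw_fft[[b]])
      } else if (orientation == "ab") {
        .msc_from_fft(delta_fft[[a]], raw_fft[[b]])
      } else {
        .msc_from_fft(delta_fft[[b]], raw_fft[[a]])
      }
    }
  }
  attr(cube, "freq") <- seq(0, fs / 2, by = fs / cfg$nfft)
  attr(cube, "band_mode") <- band_mode
  cube
}

#' Median coherence across subjects and suprathreshold mask
#'
#' `median_coherence` takes the element-wise median along the subject
#' dimension (absent slices ignored); `threshold_mask` marks entries strictly
#' greater than the threshold — a value of exactly 0.8 is *not*
#' suprathreshold for coherence.
#'
#' @param cube Array from [build_cube()].
#' @return Frequency x pair matrix of medians.
#' @export
median_coherence <- function(cube) {
  stopifnot(length(dim(cube)) == 3L)
  out <- apply(cube, c(1L, 2L), median, na.rm = TRUE)
  attr(out, "freq") <- attr(cube, "freq")
  out
}

#' @rdname median_coherence
#' @param m Numeric matrix (or vector) of coherence values.
#' @param threshold Strict threshold, default 0.8.
#' @export
threshold_mask <- function(m, threshold = 0.8) {
  m > threshold
}
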