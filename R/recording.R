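#' Construct a multichannel EEG recording
#'
#' A recording bundles an 8 x n signal matrix (microvolts, rows in canonical
#' montage order), the sampling rate, the montage and per-night metadata.
#' Sample indexing is 0-based half-open throughout the package, matching the
#' segment tables produced by [select_clean_segments()].
#'
#' @param signal Numeric matrix, 8 rows (channels, canonical montage order)
#'   by n columns (samples), in microvolts. All values must be finite.
#' @param fs Sampling rate in samples per second (the acquisition system used
#'   here digitises at 1000/s).
#' @param subject_id Subject identifier string.
#' @param population `"sport"` or `"non-sport"`.
#' @param condition `"home"` (familiar box) or `"guest"` (novel box).
#' @param montage Channel montage, see [horse_montage()].
#' @param annotations Optional data frame of pre-annotated segments with
#'   columns `start`, `end` (0-based half-open sample indices) and `label`.
#' @return An object of class `eeg_recording`.
#' @export
new_recording <- function(signal, fs, subject_id = "unknown",
                          population = c("non-sport", "sport"),
                          condition = c("home", "guest"),
                          montage = horse_montage(), annotations = NULL) {
  validate_montage(montage)
  population <- match.arg(population)
  condition <- match.arg(condition)
  if (!is.matrix(signal) || !is.numeric(signal))
    stop("signal must be a numeric matrix")
  if (nrow(signal) != nrow(montage))
    stop(sprintf("signal must have exactly %d rows (one per montage channel), got %d",
                 nrow(montage), nrow(signal)))
  if (!all(is.finite(signal))) stop("signal contains non-finite samples")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a single positive number")
  if (!is.null(annotations))
    stopifnot(is.data.frame(annotations),
              all(c("start", "end", "label") %in% names(annotations)))
  rownames(signal) <- montage$label
  structure(list(signal = signal, fs = fs, montage = montage,
                 meta = list(subject_id = subject_id, population = population,
                             condition = condition),
                 annotations = annotations),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s (%s, %s box): %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$meta$subject_id, x$meta$population, x$meta$condition,
              nrow(x$signal), ncol(x$signal), x$fs, ncol(x$signal) / x$fs))
  invisible(x)
}

#' Identify artifact-free analysis segments
#'
#' A transparent stand-in for expert artifact rejection: maximal runs of
#' samples during which every channel stays, after removal of its per-channel
#' median, strictly below an absolute amplitude limit, kept only when at
#' least `min_duration` seconds long. Muscle interference and extended line
#' noise in these recordings show up as large-amplitude excursions, which is
#' what the rule excludes. Pre-annotated segments attached to the recording
#' can be passed to the analysis functions instead.
#'
#' @param rec An [new_recording()] object.
#' @param amplitude_limit Absolute amplitude limit in microvolts (> 0).
#' @param min_duration Minimum segment duration in seconds (> 0).
#' @return Data frame with columns `start`, `end` (0-based half-open sample
#'   indices) and `label`; zero rows if nothing qualifies. Segments are
#'   sorted and non-overlapping.
#' @export
select_clean_segments <- function(rec, amplitude_limit = 200, min_duration = 10) {
  stopifnot(inherits(rec, "eeg_recording"),
            amplitude_limit > 0, min_duration > 0)
  centred <- rec$signal - apply(rec$signal, 1L, median)
  ok <- colSums(abs(centred) >= amplitude_limit) == 0L
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths  # 0-based
  keep <- runs$values & runs$lengths >= min_duration * rec$fs
  data.frame(start = starts[keep], end = ends[keep],
             label = rep("clean", sum(keep)), stringsAsFactors = FALSE)
}

#' Concatenate segments of a recording
#'
#' @param rec An `eeg_recording`.
#' @param segments Data frame with `start`/`end` columns (0-based half-open),
#'   or `NULL` to use the whole recording.
#' @return Channels x samples matrix of the concatenated segments.
#' @export
extract_segments <- function(rec, segments = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (is.null(segments))
    return(rec$signal)
  stopifnot(is.data.frame(segments), all(c("start", "end") %in% names(segments)))
  if (nrow(segments) == 0L)
    stop(sprintf("recording %s has no clean segments", rec$meta$subject_id))
  n <- ncol(rec$signal)
  if (any(segments$start < 0) || any(segments$end > n) ||
      any(segments$start >= segments$end))
    stop("segment bounds must satisfy 0 <= start < end <= n_samples")
  idx <- unlist(lapply(seq_len(nrow(segments)), function(i)
    (segments$start[i] + 1L):segments$end[i]))
  rec$signal[, idx, drop = FALSE]
}
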