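#' EEG band definitions
#'
#' The five conventional bands used throughout the pipeline. Delta is a pure
#' lowpass (0-4 Hz, DC kept, as appropriate for full-band DC acquisition);
#' the others are bandpasses.
#'
#' @return Data frame with columns `name`, `low_hz`, `high_hz`, `kind`.
#' @export
band_specs <- function() {
  data.frame(name = c("delta", "theta", "alpha", "beta", "gamma"),
             low_hz = c(0, 4, 8, 13, 30),
             high_hz = c(4, 8, 13, 30, 120),
             kind = c("lowpass", rep("bandpass", 4)),
             stringsAsFactors = FALSE)
}

.get_band <- function(band, specs = band_specs()) {
  if (is.character(band)) {
    i <- match(band, specs$name)
    if (is.na(i)) stop("unknown band: ", band)
    return(specs[i, ])
  }
  stopifnot(is.data.frame(band), nrow(band) == 1L,
            all(c("name", "low_hz", "high_hz", "kind") %in% names(band)))
  band
}

#' Design a third-order Butterworth band filter
#'
#' Cutoffs are normalised as Wn = cutoff / (fs/2), a fraction of the Nyquist
#' frequency; at fs = 1000 the delta lowpass uses Wn = 4/500 = 0.008.
#'
#' @param band Band name (see [band_specs()]) or a one-row band data frame.
#' @param fs Sampling rate in Hz.
#' @param order Filter order (3 throughout this pipeline).
#' @return An object of class `iir_filter` with elements `b`, `a`
#'   (numerator/denominator coefficients), `order`, `wn`, `kind`, `band`,
#'   `fs`.
#' @export
#' @examples
#' design_filter("delta", fs = 1000)$wn  # 0.008
design_filter <- function(band, fs, order = 3L) {
  b <- .get_band(band)
  nyq <- fs / 2
  if (b$high_hz >= nyq)
    stop(sprintf("design error: band edge %g Hz is not below Nyquist %g Hz",
                 b$high_hz, nyq))
  if (b$kind == "lowpass") {
    wn <- b$high_hz / nyq
    flt <- signal::butter(order, wn, type = "low")
  } else {
    if (b$low_hz <= 0) stop("design error: bandpass low edge must be > 0")
    wn <- c(b$low_hz, b$high_hz) / nyq
    flt <- signal::butter(order, wn, type = "pass")
  }
  out <- structure(list(b = flt$b, a = flt$a, order = order, wn = wn,
                        kind = b$kind, band = b$name, fs = fs),
                   class = "iir_filter")
  if (!filter_is_stable(out))
    stop("design error: unstable filter for band ", b$name)
  out
}

#' @rdname design_filter
#' @param filt An `iir_filter`.
#' @export
filter_is_stable <- function(filt) {
  all(Mod(polyroot(rev(filt$a))) < 1)
}

# steady-state delay-line state of the direct-form II transposed filter for
# a unit step, used to start forward/backward passes transient-free
.lfilter_zi <- function(b, a) {
  n <- length(a)
  A <- matrix(0, n - 1L, n - 1L)
  A[1L, ] <- -a[-1L]
  if (n > 2L) A[cbind(2:(n - 1L), 1:(n - 2L))] <- 1
  B <- b[-1L] - a[-1L] * b[1L]
  solve(diag(n - 1L) - t(A), B)
}

#' Zero-phase forward-backward filtering
#'
#' Applies the filter forwards and backwards so the net phase shift is zero
#' and the effective magnitude response is the squared filter response. Edge
#' transients are minimised by odd-reflection padding of 3 x (order + 1)
#' samples at each end together with steady-state initial conditions, the
#' conventional contract for this operation.
#'
#' @param x Numeric vector (one channel).
#' @param filt An `iir_filter` from [design_filter()].
#' @return Filtered vector, same length as `x`.
#' @export
zero_phase_filter <- function(x, filt) {
  stopifnot(inherits(filt, "iir_filter"), is.numeric(x))
  b <- filt$b / filt$a[1L]
  a <- filt$a / filt$a[1L]
  nf <- max(length(a), length(b))
  b <- c(b, rep(0, nf - length(b)))
  a <- c(a, rep(0, nf - length(a)))
  padlen <- 3L * nf
  n <- length(x)
  if (n <= padlen)
    stop(sprintf("signal too short for zero-phase filtering (need > %d samples)",
                 padlen))
  ext <- c(2 * x[1L] - x[(padlen + 1L):2L], x,
           2 * x[n] - x[(n - 1L):(n - padlen)])
  zi <- .lfilter_zi(b, a)
  y <- iir_filter_zi(b, a, ext, zi * ext[1L])
  y <- rev(iir_filter_zi(b, a, rev(y), zi * y[length(y)]))
  y[(padlen + 1L):(padlen + n)]
}

#' Band-filter a signal matrix or recording
#'
#' @param x An `eeg_recording`, or a channels x samples matrix, or a vector.
#' @param band Band name.
#' @param fs Sampling rate (taken from the recording when `x` is one).
#' @return Object of the same shape with every channel band-filtered.
#' @export
band_filter <- function(x, band, fs = NULL) {
  if (inherits(x, "eeg_recording")) {
    x$signal <- band_filter(x$signal, band, x$fs)
    return(x)
  }
  stopifnot(!is.null(fs))
  filt <- design_filter(band, fs)
  if (is.matrix(x))
    t(apply(x, 1L, zero_phase_filter, filt = filt))
  else
    zero_phase_filter(x, filt)
}

#' Optional power-line notch filter
#'
#' A second-order Butterworth band-stop around the line frequency. Off by
#' default in every pipeline function: line-contaminated stretches are
#' excluded as artifacts rather than notched out.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate in Hz.
#' @param freq Line frequency in Hz.
#' @param half_width Half-width of the stop band in Hz.
#' @return Filtered vector.
#' @export
notch_filter <- function(x, fs, freq = 50, half_width = 1) {
  flt <- signal::butter(2, c(freq - half_width, freq + half_width) / (fs / 2),
                        type = "stop")
  filt <- structure(list(b = flt$b, a = flt$a, order = 2L,
                         wn = c(freq - half_width, freq + half_width) / (fs / 2),
                         kind = "bandstop", band = "notch", fs = fs),
                    class = "iir_filter")
  zero_phase_filter(x, filt)
}
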