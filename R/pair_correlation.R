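#' Two-sample rank-biserial correlation
#'
#' The Mann-Whitney effect size r = 2U/(n_x n_y) - 1, where U counts pairs
#' (x_i, y_j) with x_i > y_j, ties counting one half. U is computed through
#' the rank-sum identity (midranks), which is O(n log n) and equivalent to
#' direct counting. The statistic lies in [-1, 1], is +1 when every x exceeds
#' every y, 0 when the two marginal distributions coincide (in particular for
#' x identical to y), and is antisymmetric in its arguments. Note that it is
#' a measure of stochastic dominance between the two *marginal*
#' distributions: it does not respond to joint coupling of two series whose
#' marginals agree.
#'
#' @param x,y Non-empty numeric vectors (lengths may differ).
#' @return Scalar in `[-1, 1]`.
#' @export
#' @examples
#' rank_biserial(c(5, 6, 7), c(1, 2, 3))  # 1
#' rank_biserial(c(1, 3), c(2, 4))        # -0.5
rank_biserial <- function(x, y) {
  nx <- as.numeric(length(x)); ny <- as.numeric(length(y))
  if (nx == 0 || ny == 0) stop("rank_biserial requires non-empty inputs")
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  2 * u / (nx * ny) - 1
}

#' Percentile bootstrap interval for the rank-biserial correlation
#'
#' Resamples time indices with replacement, by default independently for the
#' two series (paired and moving-block schemes are available; the block
#' scheme acknowledges serial dependence of EEG samples but is off by
#' default, matching an exchangeability treatment of the samples). The
#' interval endpoints are the empirical lower/upper percentiles of the
#' resampled statistics, taken as order statistics
#' `sorted[ceiling(n_boot * p)]`.
#'
#' @param x,y Numeric vectors, length >= 2 each.
#' @param n_boot Number of bootstrap resamples (default 3000).
#' @param ci_level Interval coverage (default 0.95, i.e. percentiles 2.5 and
#'   97.5).
#' @param seed Optional integer; same seed and data give the identical
#'   interval.
#' @param scheme `"independent"` (default) or `"paired"` index resampling.
#' @param block_length Optional integer; when given, indices are drawn as
#'   circular moving blocks of this length.
#' @return Named numeric `c(low, high)` with `low <= high`.
#' @export
bootstrap_ci <- function(x, y, n_boot = 3000, ci_level = 0.95, seed = NULL,
                         scheme = c("independent", "paired"),
                         block_length = NULL) {
  scheme <- match.arg(scheme)
  if (n_boot < 1) stop("config error: n_boot must be >= 1")
  if (length(x) < 2L || length(y) < 2L)
    stop("bootstrap_ci requires series of length >= 2")
  if (scheme == "paired" && length(x) != length(y))
    stop("paired resampling requires equal lengths")
  if (!is.null(seed)) set.seed(seed)
  draw <- function(n) {
    if (is.null(block_length)) {
      sample.int(n, n, replace = TRUE)
    } else {
      nb <- ceiling(n / block_length)
      starts <- sample.int(n, nb, replace = TRUE)
      idx <- as.vector(outer(0:(block_length - 1L), starts, `+`)) %% n + 1L
      idx[seq_len(n)]
    }
  }
  stat <- vapply(seq_len(n_boot), function(i) {
    ix <- draw(length(x))
    iy <- if (scheme == "paired") ix else draw(length(y))
    rank_biserial(x[ix], y[iy])
  }, numeric(1))
  s <- sort(stat)
  p_lo <- (1 - ci_level) / 2
  lo <- s[max(1L, ceiling(n_boot * p_lo))]
  hi <- s[max(1L, ceiling(n_boot * (1 - p_lo)))]
  c(low = lo, high = hi)
}

#' Per-band rank-biserial map over all 28 electrode pairs
#'
#' Band-filters every channel, concatenates the clean segments, and computes
#' the rank-biserial statistic for each pair of the canonical pair table.
#'
#' @param rec An `eeg_recording`.
#' @param band Band name.
#' @param segments Optional segment data frame (e.g. from
#'   [select_clean_segments()]); `NULL` uses the whole recording. An empty
#'   segment table is an error naming the recording.
#' @param n_boot Bootstrap resamples for per-pair percentile intervals;
#'   0 (default) skips the bootstrap. The study configuration is 3000.
#' @param ci_level,seed,scheme,block_length Passed to [bootstrap_ci()].
#' @return Object of class `connectivity_map`: list with `band`, `values`
#'   (named length-28 vector, names = pair indices), `ci` (28 x 2 matrix or
#'   `NULL`), `subject_id`, `condition`, `population`.
#' @export
correlation_map <- function(rec, band, segments = NULL, n_boot = 0,
                            ci_level = 0.95, seed = NULL,
                            scheme = "independent", block_length = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  sig <- extract_segments(rec, segments)
  filt <- design_filter(band, rec$fs)
  fsig <- t(apply(sig, 1L, zero_phase_filter, filt = filt))
  pt <- build_pair_table(rec$montage)
  values <- vapply(seq_len(nrow(pt)), function(i)
    rank_biserial(fsig[pt$channel_a[i], ], fsig[pt$channel_b[i], ]),
    numeric(1))
  names(values) <- pt$pair_index
  ci <- NULL
  if (n_boot > 0) {
    ci <- t(vapply(seq_len(nrow(pt)), function(i)
      bootstrap_ci(fsig[pt$channel_a[i], ], fsig[pt$channel_b[i], ],
                   n_boot = n_boot, ci_level = ci_level,
                   seed = if (is.null(seed)) NULL else seed + i,
                   scheme = scheme, block_length = block_length),
      numeric(2)))
    dimnames(ci) <- list(pt$pair_index, c("low", "high"))
  }
  structure(list(band = .get_band(band)$name, values = values, ci = ci,
                 subject_id = rec$meta$subject_id,
                 condition = rec$meta$condition,
                 population = rec$meta$population),
            class = "connectivity_map")
}

#' Median connectivity map across subjects
#'
#' Element-wise median over subjects for one band; an even subject count uses
#' the mean of the two central order statistics.
#'
#' @param maps List of `connectivity_map` objects for one band (typically one
#'   population and condition).
#' @return Named length-28 numeric vector of per-pair medians.
#' @export
median_map <- function(maps) {
  stopifnot(length(maps) >= 1L,
            all(vapply(maps, inherits, logical(1), "connectivity_map")))
  bands <- unique(vapply(maps, `[[`, character(1), "band"))
  if (length(bands) != 1L)
    stop("median_map: maps mix bands: ", paste(bands, collapse = ", "))
  vals <- do.call(rbind, lapply(maps, `[[`, "values"))
  apply(vals, 2L, median)
}

#' Home-minus-guest difference of median maps
#'
#' @param median_home,median_guest Named per-pair vectors over the same pair
#'   domain.
#' @return Named vector of differences (home - guest), with the sign
#'   convention recorded in attribute `"sign"`.
#' @export
condition_difference <- function(median_home, median_guest) {
  if (!identical(names(median_home), names(median_guest)))
    stop("pair domains differ between the two maps")
  structure(median_home - median_guest, sign = "home-guest")
}
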