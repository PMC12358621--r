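#' Normalized cross-correlation at zero delay
#'
#' The Pearson-type coefficient: both series are mean-removed and the value
#' is their inner product divided by the product of their norms. Zero delay
#' is used because the cross-correlation of these recordings peaks at lag
#' zero.
#'
#' @param x,y Equal-length numeric vectors (length >= 2) with nonzero
#'   variance.
#' @return Scalar in `[-1, 1]`.
#' @export
zero_lag_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L)
    stop("zero_lag_correlation requires equal lengths >= 2")
  xc <- x - mean(x); yc <- y - mean(y)
  nx <- sqrt(sum(xc^2)); ny <- sqrt(sum(yc^2))
  if (nx == 0 || ny == 0)
    stop("undefined correlation: zero-variance input")
  max(-1, min(1, sum(xc * yc) / (nx * ny)))
}

#' Normalized suprathreshold pair counts per electrode group
#'
#' Band-filters the recording, computes the zero-lag correlation of every
#' pair, and reports for each of the seven groups the fraction of member
#' pairs at or above the threshold (normalization basis: the maximum number
#' of pairs in the group, so V3 with both member pairs >= 0.8 scores 1).
#' A correlation of exactly the threshold counts; negative correlations never
#' count.
#'
#' @param rec An `eeg_recording`.
#' @param band Band name. Delta is accepted but excluded from the downstream
#'   contrasts, since broadly coupled slow activity saturates every group.
#' @param threshold Suprathreshold rule `>= threshold` (default 0.8).
#' @param segments Optional segment table.
#' @return Data frame with one row per group: `subject_id`, `population`,
#'   `condition`, `band`, `group`, `count` (fraction in `[0, 1]`).
#' @export
group_counts <- function(rec, band, threshold = 0.8, segments = NULL) {
  stopifnot(inherits(rec, "eeg_recording"), threshold > 0, threshold < 1)
  sig <- extract_segments(rec, segments)
  filt <- design_filter(band, rec$fs)
  fsig <- t(apply(sig, 1L, zero_phase_filter, filt = filt))
  sc <- group_scheme(rec$montage)
  corr <- vapply(seq_len(nrow(sc)), function(i)
    zero_lag_correlation(fsig[sc$channel_a[i], ], fsig[sc$channel_b[i], ]),
    numeric(1))
  supra <- corr >= threshold
  groups <- c("H1", "H2", "H3", "H4", "V1", "V2", "V3")
  counts <- vapply(groups, function(g) mean(supra[sc$group == g]), numeric(1))
  data.frame(subject_id = rec$meta$subject_id,
             population = rec$meta$population,
             condition = rec$meta$condition,
             band = .get_band(band)$name,
             group = groups, count = unname(counts),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Group counts for a whole cohort
#'
#' @param recordings List of `eeg_recording` objects.
#' @param bands Bands to analyse; delta is excluded by default.
#' @param threshold Passed to [group_counts()].
#' @param segments_list Optional list of segment tables parallel to
#'   `recordings`.
#' @return Long data frame of per-subject, per-condition, per-band group
#'   counts (the content of a group-count boxplot).
#' @export
cohort_group_counts <- function(recordings,
                                bands = c("theta", "alpha", "beta", "gamma"),
                                threshold = 0.8, segments_list = NULL) {
  out <- lapply(seq_along(recordings), function(i) {
    segs <- if (is.null(segments_list)) NULL else segments_list[[i]]
    do.call(rbind, lapply(bands, function(b)
      group_counts(recordings[[i]], b, threshold, segs)))
  })
  do.call(rbind, out)
}

#' Home-minus-guest difference of group counts
#'
#' For counts of one subject and band as two [group_counts()] frames, or for
#' a whole cohort table, computes home - guest per group. Subjects missing
#' one of the two conditions are dropped with a warning.
#'
#' @param home,guest [group_counts()] data frames for the same subject and
#'   band.
#' @return Named numeric vector over the seven groups (for the pair form).
#' @export
condition_difference_counts <- function(home, guest) {
  stopifnot(is.data.frame(home), is.data.frame(guest))
  if (!identical(home$subject_id[1L], guest$subject_id[1L]))
    stop("subject mismatch between home and guest counts")
  if (!identical(home$band[1L], guest$band[1L]))
    stop("band mismatch between home and guest counts")
  g <- home$group
  out <- home$count - guest$count[match(g, guest$group)]
  names(out) <- g
  out
}

#' @rdname condition_difference_counts
#' @param counts A [cohort_group_counts()] table containing both conditions.
#' @export
count_differences <- function(counts) {
  stopifnot(is.data.frame(counts))
  key <- interaction(counts$subject_id, counts$band, drop = TRUE)
  rows <- split(seq_len(nrow(counts)), key)
  out <- lapply(rows, function(i) {
    sub <- counts[i, ]
    home <- sub[sub$condition == "home", ]
    guest <- sub[sub$condition == "guest", ]
    if (nrow(home) == 0L || nrow(guest) == 0L ||
        !setequal(home$group, guest$group)) {
      warning("subject ", sub$subject_id[1L],
              " lacks one condition for band ", sub$band[1L], "; dropped")
      return(NULL)
    }
    data.frame(subject_id = sub$subject_id[1L],
               population = sub$population[1L], band = sub$band[1L],
               group = home$group,
               difference = home$count -
                 guest$count[match(home$group, guest$group)],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out[!vapply(out, is.null, logical(1))],
                   list(make.row.names = FALSE)))
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact null distribution when both samples have at most 10 values and no
#' ties are present; otherwise the normal approximation with tie and
#' continuity correction. `h = 1` reports rejection at level `alpha`.
#'
#' @param a,b Non-empty numeric samples.
#' @param alpha Significance level (default 0.05).
#' @return List with `h` (0/1), `p`, `statistic` (Mann-Whitney U of `a`) and
#'   `method`.
#' @export
#' @examples
#' ranksum_test(c(4, 5, 6), c(1, 2, 3))$p  # 0.1
ranksum_test <- function(a, b, alpha = 0.05) {
  if (length(a) == 0L || length(b) == 0L)
    stop("ranksum_test requires non-empty samples")
  if (length(unique(c(a, b))) == 1L) {
    # every observation ties: the rank-sum statistic is degenerate and the
    # two distributions are trivially identical
    return(list(h = 0L, p = 1, statistic = length(a) * length(b) / 2,
                method = "degenerate-ties"))
  }
  exact <- length(a) <= 10L && length(b) <= 10L && !anyDuplicated(c(a, b))
  wt <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = TRUE))
  p <- min(1, wt$p.value)
  list(h = as.integer(p < alpha), p = p, statistic = unname(wt$statistic),
       method = if (exact) "exact" else "normal-approximation")
}

.contrast_groups <- c("H1", "H2", "H3", "H4", "V1", "V2", "V3")

#' Population contrast of home-guest count differences
#'
#' For every band x group cell, tests whether the per-subject home - guest
#' differences of the normalized counts have the same distribution in the
#' sport and non-sport populations (two-sided rank-sum). Delta is excluded.
#' No multiple-testing correction is applied by default;
#' `adjust = "BH"` switches on a Benjamini-Hochberg adjustment of the 28
#' p-values.
#'
#' @param differences A [count_differences()] table containing both
#'   populations.
#' @param bands Bands to test (default theta-gamma: 4 bands x 7 groups = 28
#'   tests).
#' @param alpha Significance level.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Data frame with columns `band`, `group`, `h`, `p`,
#'   `contrast_kind = "population-difference"`.
#' @export
population_contrast <- function(differences,
                                bands = c("theta", "alpha", "beta", "gamma"),
                                alpha = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(is.data.frame(differences))
  cells <- expand.grid(band = bands, group = .contrast_groups,
                       stringsAsFactors = FALSE)
  cells <- cells[order(match(cells$band, bands), cells$group), ]
  res <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- differences$band == cells$band[i] &
      differences$group == cells$group[i]
    a <- differences$difference[sel & differences$population == "sport"]
    b <- differences$difference[sel & differences$population == "non-sport"]
    ranksum_test(a, b, alpha)
  })
  p <- vapply(res, `[[`, numeric(1), "p")
  if (adjust == "BH") p <- stats::p.adjust(p, "BH")
  data.frame(band = cells$band, group = cells$group,
             h = as.integer(p < alpha), p = p,
             contrast_kind = "population-difference",
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Condition contrast within one population
#'
#' Rank-sum comparison of the distribution of normalized group counts
#' between the home and guest conditions, per band x group, within one
#' population.
#'
#' @param counts A [cohort_group_counts()] table.
#' @param population `"sport"` or `"non-sport"`.
#' @inheritParams population_contrast
#' @return Data frame with `band`, `group`, `h`, `p`,
#'   `contrast_kind = "condition-within-population"`.
#' @export
condition_contrast <- function(counts, population,
                               bands = c("theta", "alpha", "beta", "gamma"),
                               alpha = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(is.data.frame(counts), population %in% counts$population)
  counts <- counts[counts$population == population, ]
  cells <- expand.grid(band = bands, group = .contrast_groups,
                       stringsAsFactors = FALSE)
  cells <- cells[order(match(cells$band, bands), cells$group), ]
  res <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- counts$band == cells$band[i] & counts$group == cells$group[i]
    h <- counts$count[sel & counts$condition == "home"]
    g <- counts$count[sel & counts$condition == "guest"]
    ranksum_test(h, g, alpha)
  })
  p <- vapply(res, `[[`, numeric(1), "p")
  if (adjust == "BH") p <- stats::p.adjust(p, "BH")
  data.frame(band = cells$band, group = cells$group,
             h = as.integer(p < alpha), p = p,
             contrast_kind = "condition-within-population",
             stringsAsFactors = FALSE, row.names = NULL)
}
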