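test_that("zero-lag correlation is the mean-removed normalized inner product", {
  set.seed(51)
  x <- rnorm(100)
  expect_equal(zero_lag_correlation(x, x), 1)
  expect_equal(zero_lag_correlation(x, -x), -1)
  expect_equal(zero_lag_correlation(c(1, 2, 3, 4), c(2, 4, 6, 8)), 1)
  # direct formula oracle
  y <- rnorm(100)
  xc <- x - mean(x); yc <- y - mean(y)
  expect_equal(zero_lag_correlation(x, y),
               sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2)))
  expect_error(zero_lag_correlation(rep(1, 10), rnorm(10)),
               "zero-variance")
  expect_error(zero_lag_correlation(rnorm(5), rnorm(6)), "equal lengths")
})

test_that("group counts are normalized by group size with a >= threshold", {
  fs <- 1000
  set.seed(52)
  sig <- matrix(rnorm(8 * 10 * fs, sd = 10), 8, 10 * fs)
  # duplicate the V3 partners: fr/or (1,4) and ol/fl (5,8)
  sig[4, ] <- sig[1, ]
  sig[8, ] <- sig[5, ]
  gc <- group_counts(mk_recording(sig), "alpha")
  expect_equal(gc$count[gc$group == "V3"], 1)     # both of 2 pairs
  expect_true(all(gc$count >= 0 & gc$count <= 1))
  # 2 of the 4 H1 pairs suprathreshold -> 0.5
  sig2 <- matrix(rnorm(8 * 10 * fs, sd = 10), 8, 10 * fs)
  sig2[7, ] <- sig2[2, ]   # tr/tl
  sig2[6, ] <- sig2[3, ]   # pr/pl
  gc2 <- group_counts(mk_recording(sig2), "alpha")
  expect_equal(gc2$count[gc2$group == "H1"], 0.5)
  expect_equal(sum(gc2$count[gc2$group != "H1"]), 0)
  # independent channels: all groups zero
  gc0 <- group_counts(mk_recording(matrix(rnorm(8 * 10 * fs), 8, 10 * fs)),
                      "alpha")
  expect_equal(gc0$count, rep(0, 7))
})

test_that("group counts are monotone non-increasing in the threshold", {
  spec <- cohort_spec(presets = list("non-sport.guest" = list(
    source_spec(c(2, 7), coupling = 0.75, band = "alpha", amplitude = 10),
    source_spec(c(1, 4), coupling = 0.9, band = "beta", amplitude = 10))),
    n_subjects = 1, duration = 10, seed = 53, jitter = 0)
  rec <- generate_recording(spec, 1, "non-sport", "guest")
  for (band in c("alpha", "beta")) {
    c1 <- group_counts(rec, band, threshold = 0.5)$count
    c2 <- group_counts(rec, band, threshold = 0.7)$count
    c3 <- group_counts(rec, band, threshold = 0.9)$count
    expect_true(all(c2 <= c1) && all(c3 <= c2))
  }
})

test_that("broad slow coupling saturates every group in the delta band", {
  # the rationale for excluding delta from the grouped analysis: a shared
  # slow source across the whole montage pushes all 28 pairs past threshold
  spec <- cohort_spec(presets = list("non-sport.guest" = list(
    source_spec(1:8, coupling = 0.95, band = "delta", amplitude = 15))),
    n_subjects = 1, duration = 20, seed = 54, jitter = 0)
  rec <- generate_recording(spec, 1, "non-sport", "guest")
  gc <- group_counts(rec, "delta")
  expect_equal(gc$count, rep(1, 7))
})

test_that("count differences follow home - guest and detect mismatches", {
  sigs <- function(seed) {
    set.seed(seed); matrix(rnorm(8 * 10000), 8, 10000)
  }
  home <- group_counts(mk_recording(sigs(1), condition = "home"), "alpha")
  guest <- group_counts(mk_recording(sigs(2), condition = "guest"), "alpha")
  d <- condition_difference_counts(home, guest)
  expect_equal(unname(d), home$count - guest$count)
  expect_equal(unname(d["V3"]), 0)
  home$count[home$group == "V3"] <- 1
  d2 <- condition_difference_counts(home, guest)
  expect_equal(unname(d2["V3"]), 1)
  home$count[home$group == "H1"] <- 0.25
  guest$count[guest$group == "H1"] <- 0.75
  expect_equal(unname(condition_difference_counts(home, guest)["H1"]), -0.5)
  other <- home; other$subject_id <- "someone-else"
  expect_error(condition_difference_counts(other, guest), "subject mismatch")
  theta <- home; theta$band <- "theta"
  expect_error(condition_difference_counts(theta, guest), "band mismatch")
  # cohort form drops subjects missing a condition, with a warning
  tbl <- rbind(home, guest)
  lone <- group_counts(mk_recording(sigs(3), subject = "t99",
                                    condition = "home"), "alpha")
  expect_warning(dd <- count_differences(rbind(tbl, lone)), "lacks one condition")
  expect_equal(nrow(dd), 7)
})

test_that("ranksum_test matches exact enumeration and its approximation", {
  r <- ranksum_test(c(4, 5, 6), c(1, 2, 3))
  expect_equal(r$p, 0.1)  # most extreme of C(6,3)=20 arrangements, two-sided
  expect_equal(r$p, ranksum_enum_p(c(4, 5, 6), c(1, 2, 3)))
  expect_equal(r$method, "exact")
  expect_equal(r$h, 0L)
  # identical multisets: approximation path, p = 1, no rejection
  r2 <- ranksum_test(c(1, 2, 2), c(1, 2, 2))
  expect_equal(r2$p, 1)
  expect_equal(r2$h, 0L)
  # clearly shifted large samples are detected
  set.seed(55)
  r3 <- ranksum_test(rnorm(50) + 10, rnorm(50))
  expect_equal(r3$h, 1L)
  expect_error(ranksum_test(numeric(0), 1:3), "non-empty")
  # enumeration oracle on random small samples
  for (i in 1:10) {
    a <- rnorm(4); b <- rnorm(5)
    expect_equal(ranksum_test(a, b)$p, ranksum_enum_p(a, b))
  }
  # exact and normal-approximation paths agree closely at n = 10
  set.seed(56)
  for (i in 1:10) {
    a <- rnorm(10); b <- rnorm(10)
    p_exact <- ranksum_test(a, b)$p
    p_approx <- suppressWarnings(
      wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
    expect_lt(abs(p_exact - p_approx), 0.02)
  }
})

test_that("contrasts emit one test per band x group and detect planted effects", {
  groups <- c("H1", "H2", "H3", "H4", "V1", "V2", "V3")
  mk_counts <- function(subject, population, condition, value_by_group) {
    do.call(rbind, lapply(c("theta", "alpha", "beta", "gamma"), function(b)
      data.frame(subject_id = subject, population = population,
                 condition = condition, band = b, group = groups,
                 count = value_by_group, stringsAsFactors = FALSE)))
  }
  counts <- do.call(rbind, c(
    lapply(1:6, function(s) mk_counts(sprintf("ns%02d", s), "non-sport",
                                      "home", rep(0, 7))),
    lapply(1:6, function(s) mk_counts(sprintf("ns%02d", s), "non-sport",
                                      "guest", c(0.5, 0, 0, 1, 0, 0, 0))),
    lapply(1:6, function(s) mk_counts(sprintf("sp%02d", s), "sport",
                                      "home", rep(0, 7))),
    lapply(1:6, function(s) mk_counts(sprintf("sp%02d", s), "sport",
                                      "guest", rep(0, 7)))))
  diffs <- count_differences(counts)
  pc <- population_contrast(diffs)
  expect_equal(nrow(pc), 28)  # 4 bands x 7 groups, delta excluded
  expect_true(all(pc$p > 0 & pc$p <= 1))
  # the planted guest-only effect in the non-sport cohort rejects in H1/H4
  expect_equal(sort(unique(pc$group[pc$h == 1])), c("H1", "H4"))
  # identical populations: nothing rejects
  even <- diffs; even$difference <- 0
  expect_equal(sum(population_contrast(even)$h), 0)
  # invariant to subject ordering
  set.seed(57)
  perm <- diffs[sample(nrow(diffs)), ]
  expect_equal(population_contrast(perm), pc)
  cc <- condition_contrast(counts, "non-sport")
  expect_equal(nrow(cc), 28)
  expect_equal(sort(unique(cc$group[cc$h == 1])), c("H1", "H4"))
  expect_equal(sum(condition_contrast(counts, "sport")$h), 0)
})
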