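test_that("source and cohort specifications validate their inputs", {
  expect_error(source_spec(c(4, 4), coupling = 0.5, band = "delta"),
               "config error")
  expect_error(source_spec(c(4, 9), coupling = 0.5, band = "delta"),
               "config error")
  expect_error(source_spec(c(4, 5), coupling = 1.2, band = "delta"),
               "config error")
  expect_error(source_spec(c(4, 5), coupling = 0.5), "need a band")
  expect_error(source_spec(c(4, 5), coupling = 0.5, waveform = "sinusoid"),
               "need a frequency")
  expect_error(source_spec(c(4, 5), waveform = "dc", offsets = 1),
               "one offset per channel")
  src <- source_spec(c(4, 5), coupling = 0.5, band = "delta")
  expect_error(cohort_spec(list("non-sport.home" = list(src)), duration = 2),
               "Welch windows")
  expect_error(cohort_spec(list("non-sport.home" = list(src)), fs = 200,
                           duration = 60), "twice the highest band edge")
  spec <- cohort_spec(list("non-sport.home" = list(src)))
  expect_error(generate_recording(spec, 1, "sport", "home"), "no preset")
})

test_that("generation is deterministic and respects the recording contract", {
  spec <- cohort_spec(presets = list(
    "non-sport.home" = list(),
    "non-sport.guest" = list(
      source_spec(c(4, 5), coupling = 0.8, band = "delta", amplitude = 15),
      source_spec(c(2, 4), coupling = 0.9, waveform = "sinusoid", freq = 1,
                  amplitude = 8))),
    n_subjects = 2, duration = 10, seed = 61)
  r1 <- generate_recording(spec, 1, "non-sport", "guest")
  r2 <- generate_recording(spec, 1, "non-sport", "guest")
  expect_identical(r1$signal, r2$signal)  # byte-identical replay
  r3 <- generate_recording(spec, 2, "non-sport", "guest")
  expect_false(identical(r1$signal, r3$signal))
  expect_s3_class(r1, "eeg_recording")
  expect_true(all(is.finite(r1$signal)))
  expect_equal(dim(r1$signal), c(8L, 10000L))
  expect_equal(r1$meta$subject_id, "non-sport-01")
  cohort <- generate_cohort(spec)
  expect_length(cohort, 4)  # 2 presets x 2 subjects
})

test_that("injected coupling appears as band-limited correlation; zero coupling does not", {
  # closed form: with unit-variance shared and private parts, the expected
  # band correlation is c attenuated only by the (small) in-band background
  couplings <- c(0.25, 0.9)
  for (cpl in couplings) {
    spec <- cohort_spec(presets = list("non-sport.guest" = list(
      source_spec(c(4, 5), coupling = cpl, band = "delta", amplitude = 15))),
      n_subjects = 5, duration = 30, seed = 62, jitter = 0)
    gt <- ground_truth(spec, "non-sport", "guest")
    expected <- gt$expected_correlation[gt$band == "delta" & gt$pair_index == 19]
    est <- vapply(1:5, function(s) {
      r <- generate_recording(spec, s, "non-sport", "guest")
      f <- band_filter(r$signal, "delta", r$fs)
      zero_lag_correlation(f[4, ], f[5, ])
    }, numeric(1))
    se <- sd(est) / sqrt(length(est))
    expect_lt(abs(mean(est) - expected), 3 * se + 0.005)
    expect_lt(abs(expected - cpl), 0.02)  # background dilution stays small
  }
  spec0 <- cohort_spec(presets = list("non-sport.guest" = list(
    source_spec(c(4, 5), coupling = 0, band = "delta", amplitude = 15))),
    n_subjects = 5, duration = 30, seed = 63, jitter = 0)
  est0 <- vapply(1:5, function(s) {
    r <- generate_recording(spec0, s, "non-sport", "guest")
    f <- band_filter(r$signal, "delta", r$fs)
    zero_lag_correlation(f[4, ], f[5, ])
  }, numeric(1))
  expect_lt(max(abs(est0)), 0.3)
})

test_that("ground truth matches a Monte-Carlo oracle, including overlapping sources", {
  # two sources sharing channel 4: variances add, covariances stay separate
  spec <- cohort_spec(presets = list("non-sport.guest" = list(
    source_spec(c(4, 5), coupling = 0.8, band = "delta", amplitude = 15),
    source_spec(c(2, 4), coupling = 0.6, band = "delta", amplitude = 10))),
    n_subjects = 1, duration = 240, seed = 64, jitter = 0)
  gt <- ground_truth(spec, "non-sport", "guest",
                     bands = c("delta", "theta"))
  r <- generate_recording(spec, 1, "non-sport", "guest")
  f <- band_filter(r$signal, "delta", r$fs)
  for (p in c(19, 9, 10)) {  # (4,5), (2,4) and the induced-zero (2,5)
    pt <- build_pair_table()
    a <- pt$channel_a[p]; b <- pt$channel_b[p]
    emp <- zero_lag_correlation(f[a, ], f[b, ])
    exp_p <- gt$expected_correlation[gt$band == "delta" & gt$pair_index == p]
    expect_lt(abs(emp - exp_p), 0.05)
  }
  # disjoint sources leave unrelated pairs near zero
  expect_lt(abs(gt$expected_correlation[gt$band == "delta" &
                                          gt$pair_index == 10]), 1e-9)
  # the dc mechanism only reaches the DC-preserving delta band
  spec_dc <- cohort_spec(presets = list("non-sport.guest" = list(
    source_spec(c(4, 5), waveform = "dc", offsets = c(25, -25)))),
    n_subjects = 1, duration = 30, seed = 65, jitter = 0)
  gtd <- ground_truth(spec_dc, "non-sport", "guest")
  rb_delta <- gtd$expected_rank_biserial[gtd$band == "delta" &
                                           gtd$pair_index == 19]
  rb_alpha <- gtd$expected_rank_biserial[gtd$band == "alpha" &
                                           gtd$pair_index == 19]
  expect_gt(rb_delta, 0.9)
  expect_lt(abs(rb_alpha), 0.05)
  rd <- generate_recording(spec_dc, 1, "non-sport", "guest")
  fd <- band_filter(rd$signal, "delta", rd$fs)
  expect_lt(abs(rank_biserial(fd[4, ], fd[5, ]) - rb_delta), 0.05)
})

test_that("a shared sinusoid produces suprathreshold coherence in its own bins", {
  spec <- cohort_spec(presets = list("non-sport.guest" = list(
    source_spec(c(2, 4), coupling = 0.95, waveform = "sinusoid", freq = 1,
                amplitude = 10))),
    n_subjects = 1, duration = 60, seed = 66, jitter = 0)
  r <- generate_recording(spec, 1, "non-sport", "guest")
  cf <- cross_frequency_msc(r, 9)
  expect_equal(cf$freq[which.max(cf$ab)], 1)
  supra <- which(threshold_mask(cf$ab))
  expect_true(length(supra) >= 1)
  expect_true(all(cf$freq[supra] <= 4))
})
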