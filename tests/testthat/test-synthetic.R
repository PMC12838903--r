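test_that("zero shift yields the canonical subject and generation is deterministic", {
  s0 <- make_subject(0, shift_scale = 0, seed = 7)
  expect_equal(unname(s0$channel_gains), rep(1, 4))
  expect_equal(unname(s0$freq_jitter_hz), rep(0, 4))
  expect_equal(s0$asymmetry_gain, 1)

  a <- make_subject(0, shift_scale = 0.5, seed = 7)
  b <- make_subject(0, shift_scale = 0.5, seed = 7)
  expect_identical(a, b)
  c <- make_subject(0, shift_scale = 0.5, seed = 8)
  expect_false(all(a$channel_gains == c$channel_gains))

  expect_error(make_subject(0, shift_scale = -1), "nonnegative")
})

test_that("subject shift deviations scale linearly with shift_scale", {
  s1 <- make_subject(3, shift_scale = 0.5, seed = 11)
  s2 <- make_subject(3, shift_scale = 1.0, seed = 11)
  expect_equal(2 * (s1$channel_gains - 1), s2$channel_gains - 1)
  expect_equal(2 * s1$freq_jitter_hz, s2$freq_jitter_hz)
  expect_equal(2 * (s1$asymmetry_gain - 1), s2$asymmetry_gain - 1)
})

test_that("trial simulation is deterministic and validates its inputs", {
  subj <- make_subject(1, 0.5, seed = 3)
  r <- emotion_rating(7, 3)
  t1 <- simulate_trial(subj, r, 5, 1, 100, seed = 9)
  t2 <- simulate_trial(subj, r, 5, 1, 100, seed = 9)
  expect_identical(t1$data, t2$data)
  expect_equal(dim(t1$data), c(4, 500))
  expect_equal(t1$baseline_s, 1)

  expect_error(emotion_rating(0.5, 5), "\\[1, 9\\]")
  expect_error(emotion_rating(5, 9.5), "\\[1, 9\\]")
  expect_error(simulate_trial(subj, r, 5, 1, 60), "aliasing")
  expect_error(simulate_trial(subj, r, 1, 2, 100), "duration_s")
})

test_that("frontal alpha asymmetry follows valence sign and vanishes at the midpoint", {
  subj <- make_subject(0, shift_scale = 0, seed = 5, noise_sd = 0,
                       pink_noise_scale = 0)
  stat <- function(valence) {
    tr <- simulate_trial(subj, emotion_rating(valence, 5), 6, 0, 128,
                         seed = 17)
    oracle_band_power(tr$data["F4", ], 128, 8, 13) -
      oracle_band_power(tr$data["F3", ], 128, 8, 13)
  }
  expect_gt(stat(8), 0)
  expect_lt(stat(2), 0)
  # at valence 5 the class term is exactly zero: noiseless F3 and F4 carry
  # identical amplitude per band, so band powers match
  expect_equal(stat(5), 0, tolerance = 1e-10)
})

test_that("at least 95% of generated spectral power lies inside 1-45 Hz", {
  subj <- make_subject(2, 0.5, seed = 21)
  tr <- simulate_trial(subj, emotion_rating(7, 7), 8, 1, 128, seed = 4)
  for (ch in rownames(tr$data)) {
    x <- tr$data[ch, ]
    total <- oracle_band_power(x - mean(x), 128, 0, 64)
    inband <- oracle_band_power(x - mean(x), 128, 1, 45)
    expect_gt(inband / total, 0.95)
  }
})

test_that("class separation of the alpha-asymmetry oracle increases with effect size", {
  # heavy noise and 1 s trials keep the statistic away from its ceiling so
  # the ordering across effect sizes is informative
  subj <- make_subject(0, shift_scale = 0, seed = 5, noise_sd = 3,
                       pink_noise_scale = 1)
  n <- 40
  set.seed(99)
  vals <- c(runif(n / 2, 1, 4.5), runif(n / 2, 5.5, 9))
  is_high <- vals >= 5
  auc_at <- function(effect) {
    stat <- vapply(seq_len(n), function(i) {
      tr <- simulate_trial(subj, emotion_rating(vals[i], 5), 1, 0, 128,
                           seed = 1000 + i, effect_size = effect)
      oracle_band_power(tr$data["F4", ], 128, 8, 13) -
        oracle_band_power(tr$data["F3", ], 128, 8, 13)
    }, numeric(1))
    oracle_auc(stat, is_high)
  }
  aucs <- vapply(c(0.1, 0.3, 1), auc_at, numeric(1))
  expect_true(all(diff(aucs) > 0))
  expect_gt(aucs[3], 0.9)
})

test_that("dataset generation has the right geometry, balance and determinism", {
  trials <- tiny_trials()
  expect_length(trials, 12)
  expect_s3_class(trials[[1]], "raw_trial")
  expect_length(attr(trials, "subjects"), 3)

  # fixed seed -> identical rating sequences
  again <- simulate_dataset(3, 4, duration_s = 9, baseline_s = 1,
                            rate_hz = 100, shift_scale = 0.5,
                            effect_size = 1, seed = 42)
  expect_identical(vapply(trials, function(t) t$rating$valence, numeric(1)),
                   vapply(again, function(t) t$rating$valence, numeric(1)))
  expect_identical(trials[[5]]$data, again[[5]]$data)

  # ratings cover both halves of both scales, avoiding the threshold gap
  v <- vapply(trials, function(t) t$rating$valence, numeric(1))
  a <- vapply(trials, function(t) t$rating$arousal, numeric(1))
  expect_true(all(v < 4.5 + 1e-9 | v > 5.5 - 1e-9))
  for (sid in 0:2) {
    sel <- vapply(trials, function(t) t$subject_id, integer(1)) == sid
    expect_equal(sum(v[sel] >= 5), 2)
    expect_equal(sum(a[sel] >= 5), 2)
  }

  # generating one subject reproduces its slice of the full dataset
  solo <- simulate_dataset(3, 4, duration_s = 9, baseline_s = 1,
                           rate_hz = 100, shift_scale = 0.5,
                           effect_size = 1, seed = 42, subject_ids = 1L)
  full_s1 <- Filter(function(t) t$subject_id == 1L, trials)
  expect_identical(solo[[2]]$data, full_s1[[2]]$data)
})

test_that("a bandpower-threshold classifier sits at chance when the effect is absent", {
  subj <- make_subject(0, shift_scale = 0, seed = 5)
  n <- 200
  set.seed(7)
  vals <- c(runif(n / 2, 1, 4.5), runif(n / 2, 5.5, 9))[sample.int(n)]
  stat <- vapply(seq_len(n), function(i) {
    tr <- simulate_trial(subj, emotion_rating(vals[i], 5), 1, 0, 128,
                         seed = 5000 + i, effect_size = 0)
    oracle_band_power(tr$data["F4", ], 128, 8, 13) -
      oracle_band_power(tr$data["F3", ], 128, 8, 13)
  }, numeric(1))
  acc <- mean((stat > stats::median(stat)) == (vals >= 5))
  se3 <- 3 * sqrt(0.25 / n)
  expect_lt(abs(acc - 0.5), se3)
})
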