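mk_trial <- function(data, rate, baseline = 0, valence = 7, arousal = 3) {
  raw_trial(subject_id = 1, trial_id = 1, data = data,
            sampling_rate_hz = rate, baseline_s = baseline,
            rating = emotion_rating(valence, arousal))
}

sine_trial <- function(freq, rate, dur, baseline = 0, channels = c("FP1", "FP2", "F3", "F4")) {
  t <- (seq_len(round(dur * rate)) - 1) / rate
  data <- matrix(rep(sin(2 * pi * freq * t), length(channels)),
                 nrow = length(channels), byrow = TRUE,
                 dimnames = list(channels, NULL))
  mk_trial(data, rate, baseline)
}

test_that("baseline removal keeps the tail and the arithmetic of the two geometries", {
  tr <- sine_trial(10, 128, 63, baseline = 3)
  out <- drop_baseline(tr)
  expect_equal(ncol(out$data), 7680)           # (63 - 3) * 128
  expect_equal(out$baseline_s, 0)
  expect_identical(out$data, tr$data[, 385:8064])

  tr2 <- sine_trial(10, 100, 70, baseline = 10)
  expect_equal(ncol(drop_baseline(tr2)$data), 6000)  # (70 - 10) * 100

  tr3 <- sine_trial(10, 100, 5, baseline = 0)
  expect_identical(drop_baseline(tr3), tr3)
})

test_that("resampling gives exact counts, preserves tone frequency, and refuses upsampling", {
  tr <- sine_trial(10, 512, 60)
  out <- resample_trial(tr, 128)
  expect_equal(ncol(out$data), 7680)
  expect_equal(out$sampling_rate_hz, 128)
  # dominant periodogram peak stays at 10 Hz
  x <- out$data[1, ]
  p <- Mod(stats::fft(x))^2
  f <- (seq_along(x) - 1) * 128 / length(x)
  peak <- f[f <= 64][which.max(p[f <= 64][-1]) + 1]
  expect_equal(peak, 10, tolerance = 0.05)

  expect_identical(resample_trial(tr, 512), tr)
  expect_error(resample_trial(tr, 1024), "upsampling")

  # non-integer ratio (128 -> 100)
  tr3 <- sine_trial(10, 128, 10)
  expect_equal(ncol(resample_trial(tr3, 100)$data), 1000)
})

test_that("band-pass filtering attenuates stop bands and passes the analysis band", {
  stop_tr <- sine_trial(1, 128, 20)
  out <- bandpass_trial(stop_tr)
  expect_lt(sd(out$data[1, ]) / sd(stop_tr$data[1, ]), 0.10)

  pass_tr <- sine_trial(10, 128, 20)
  out2 <- bandpass_trial(pass_tr)
  expect_equal(sd(out2$data[1, ]) / sd(pass_tr$data[1, ]), 1,
               tolerance = 0.10)

  zero_tr <- mk_trial(matrix(0, 4, 1000,
                             dimnames = list(c("FP1", "FP2", "F3", "F4"),
                                             NULL)), 128)
  expect_true(all(bandpass_trial(zero_tr)$data == 0))

  expect_error(bandpass_trial(sine_trial(10, 80, 5), 4, 45), "Nyquist")
})

test_that("channel selection reorders, subsets, and reports unknown labels", {
  chans <- c("CZ", "F4", "FP1", "F3", "PZ", "FP2")
  data <- matrix(seq_len(6 * 50), nrow = 6, dimnames = list(chans, NULL))
  tr <- mk_trial(data, 100)
  out <- select_channels(tr)
  expect_equal(rownames(out$data), c("FP1", "FP2", "F3", "F4"))
  expect_equal(out$data["F3", ], data["F3", ])

  expect_identical(select_channels(tr, chans), tr)
  expect_error(select_channels(tr, c("FP1", "OZ")), "OZ")
  expect_match(tryCatch(select_channels(tr, "OZ"),
                        error = conditionMessage), "available")
})

test_that("windowing respects counts, overlap, and short trials", {
  tr <- sine_trial(10, 128, 60)
  w <- window_trial(tr, 1)
  expect_length(w, 60)
  expect_equal(dim(w[[1]]), c(4, 128))
  expect_identical(w[[2]], tr$data[, 129:256])

  tr100 <- sine_trial(10, 100, 60)
  w100 <- window_trial(tr100, 1)
  expect_length(w100, 60)
  expect_equal(dim(w100[[1]]), c(4, 100))

  expect_length(window_trial(sine_trial(10, 128, 0.5), 1), 0)
  expect_length(window_trial(tr, 1, overlap_s = 0.5), 119)
  expect_error(window_trial(tr, 1, overlap_s = 1), "overlap")
})

test_that("per-channel min-max normalization hits its bounds and handles degenerate input", {
  expect_equal(normalize_window(matrix(c(2, 4, 6), 1)),
               matrix(c(0, 0.5, 1), 1))
  expect_equal(normalize_window(matrix(3, 1, 3)), matrix(0, 1, 3))

  set.seed(31)
  w <- matrix(rnorm(4 * 128), 4)
  nw <- normalize_window(w)
  expect_true(all(nw >= 0 & nw <= 1))
  expect_equal(unname(apply(nw, 1, min)), rep(0, 4))
  expect_equal(unname(apply(nw, 1, max)), rep(1, 4))
  # idempotence on an already-normalized window
  expect_equal(normalize_window(nw), nw)
})

test_that("label derivation follows the threshold and quadrant conventions", {
  sch_v <- label_scheme("binary_valence")
  sch_q <- label_scheme("quadrant")
  expect_equal(label_rating(emotion_rating(3.2, 7), sch_v), 1L)  # low
  expect_equal(label_rating(emotion_rating(6.1, 2), sch_v), 2L)  # high
  # threshold itself is high, matching the quadrant >= 5 rule
  expect_equal(label_rating(emotion_rating(5, 5), sch_v), 2L)
  expect_equal(sch_q$class_names[label_rating(emotion_rating(5, 5), sch_q)],
               "HVHA")
  expect_equal(sch_q$class_names[label_rating(emotion_rating(7, 2), sch_q)],
               "HVLA")
  expect_equal(sch_q$class_names[label_rating(emotion_rating(2, 7), sch_q)],
               "LVHA")
  expect_equal(sch_q$class_names[label_rating(emotion_rating(1, 1), sch_q)],
               "LVLA")
  expect_error(label_rating(list(valence = 0, arousal = 5), sch_v),
               "\\[1, 9\\]")
})

test_that("the pipeline conserves window counts, stays in bounds, and is deterministic", {
  ds <- tiny_ds()
  # 3 subjects x 4 trials x floor((9 - 1)/1) windows
  expect_equal(dim(ds$X), c(96, 4, 100))
  expect_equal(as.vector(table(ds$subject_ids)), rep(32L, 3))
  expect_true(all(ds$X >= 0 & ds$X <= 1))
  expect_true(all(ds$labels %in% 1:2))
  expect_equal(ds$labels, ifelse(ds$valence >= 5, 2L, 1L))

  again <- preprocess_trials(tiny_trials(),
                             profile = list(target_rate_hz = 100),
                             scheme = label_scheme("binary_valence"))
  expect_identical(ds$X, again$X)
  expect_identical(ds$labels, again$labels)

  # stage errors are annotated with the trial id
  bad <- tiny_trials()[1]
  bad[[1]]$channel_names <- rownames(bad[[1]]$data) <- c("A", "B", "C", "D")
  expect_error(preprocess_trials(bad, list(target_rate_hz = 100),
                                 label_scheme("binary_valence")),
               "trial 1")
})
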