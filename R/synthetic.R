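#' Dataset geometry profiles
#'
#' Canonical acquisition geometries for the two supported study layouts:
#' `"deap_like"` (40 trials of 63 s with a 3 s leading baseline at 128 Hz)
#' and `"eppvr_like"` (14 trials of 70 s with a 10 s baseline at 100 Hz).
#'
#' @param name `"deap_like"` or `"eppvr_like"`.
#' @return A list with `n_trials`, `duration_s`, `baseline_s`, `rate_hz`
#'   (acquisition rate) and `target_rate_hz` (analysis rate).
#' @export
dataset_profile <- function(name = c("deap_like", "eppvr_like")) {
  name <- match.arg(name)
  switch(name,
    deap_like = list(name = "deap_like", n_trials = 40L, duration_s = 63,
                     baseline_s = 3, rate_hz = 128, target_rate_hz = 128),
    eppvr_like = list(name = "eppvr_like", n_trials = 14L, duration_s = 70,
                      baseline_s = 10, rate_hz = 100, target_rate_hz = 100)
  )
}

# Band centers (Hz) of the oscillatory content: theta, alpha, beta, gamma.
# All inside the 4-45 Hz analysis band so the band-pass retains class signal.
.band_centers <- c(theta = 6, alpha = 10, beta = 20, gamma = 35)
.band_amps   <- c(theta = 0.8, alpha = 1.0, beta = 0.7, gamma = 0.5)

#' Emotion rating
#'
#' A valence/arousal self-assessment pair on the usual 1-9 scale.
#'
#' @param valence,arousal Reals in `[1, 9]`.
#' @return An object of class `emotion_rating`.
#' @export
emotion_rating <- function(valence, arousal) {
  check_rating_range(valence, "valence")
  check_rating_range(arousal, "arousal")
  structure(list(valence = valence, arousal = arousal),
            class = "emotion_rating")
}

#' Build a subject specification
#'
#' Draws the per-subject parameters that generate inter-subject distribution
#' shift: per-channel gains, per-band center-frequency jitter, and a scalar
#' gain on the class-conditional frontal alpha asymmetry. All deviations from
#' the canonical subject scale linearly with `shift_scale`; `shift_scale = 0`
#' gives unit gains, zero jitter and unit asymmetry gain. The asymmetry gain
#' is deliberately unclamped: with larger shifts, some subjects express the
#' valence effect weakly or with inverted sign, mimicking the individual
#' variability in frontal alpha asymmetry that makes cross-subject valence
#' decoding hard.
#'
#' @param subject_id Integer identifier.
#' @param shift_scale Nonnegative scalar controlling inter-subject shift.
#' @param seed Integer base seed; the subject's own stream is derived from
#'   `(seed, subject_id)` so subjects are mutually independent.
#' @param noise_sd Additive white-noise standard deviation (signal units).
#' @param pink_noise_scale Standard deviation of the 1/f background.
#' @param channel_names Ordered electrode labels.
#' @return An object of class `subject_spec`.
#' @export
make_subject <- function(subject_id, shift_scale = 0.5, seed = 42,
                         noise_sd = 0.2, pink_noise_scale = 0.25,
                         channel_names = c("FP1", "FP2", "F3", "F4")) {
  stop_if_not(is.numeric(shift_scale) && length(shift_scale) == 1 &&
                shift_scale >= 0, "shift_scale must be a nonnegative scalar")
  stop_if_not(noise_sd >= 0, "noise_sd must be nonnegative")
  nc <- length(channel_names)
  sseed <- mix_seed(seed, subject_id)
  draws <- with_seed(sseed, list(
    gain_dev = rnorm(nc, 0, 0.2),
    freq_jit = rnorm(length(.band_centers), 0, 1),
    asym_dev = rnorm(1, 0, 0.75)
  ))
  structure(list(
    subject_id = as.integer(subject_id),
    channel_gains = stats::setNames(
      pmax(1 + shift_scale * draws$gain_dev, 0.05), channel_names),
    freq_jitter_hz = stats::setNames(
      shift_scale * draws$freq_jit, names(.band_centers)),
    # unclamped: at larger shifts some subjects have weak or sign-inverted
    # frontal asymmetry, the main realistic obstacle to cross-subject
    # transfer of a valence decoder
    asymmetry_gain = 1 + shift_scale * draws$asym_dev,
    noise_sd = noise_sd,
    pink_noise_scale = pink_noise_scale,
    channel_names = channel_names,
    shift_scale = shift_scale,
    rng_seed = sseed
  ), class = "subject_spec")
}

# 1/f background, band-limited to [1, 45] Hz by spectral shaping, unit sd
# before scaling (zero if scale is zero).
pink_noise <- function(n, rate_hz, scale) {
  if (scale <= 0) return(numeric(n))
  s <- stats::fft(stats::rnorm(n))
  f <- (seq_len(n) - 1) * rate_hz / n
  f_fold <- pmin(f, rate_hz - f)
  amp <- ifelse(f_fold >= 1 & f_fold <= 45, 1 / sqrt(f_fold), 0)
  x <- Re(stats::fft(s * amp, inverse = TRUE)) / n
  sdx <- stats::sd(x)
  if (sdx == 0) return(numeric(n))
  x / sdx * scale
}

#' Simulate one EEG trial
#'
#' Each channel is a sum of band-limited sinusoids at (jittered) theta /
#' alpha / beta / gamma center frequencies with random phases, a 1/f
#' background and white noise, scaled by the subject's channel gain. The
#' class signal is encoded as in the frontal-asymmetry literature: the
#' alpha-band amplitude difference between F4 and F3 is a monotone, odd
#' function of `valence - 5` (scaled by the subject's asymmetry gain), and
#' total beta+gamma amplitude grows monotonically with `arousal - 5`. The
#' leading baseline segment carries no class-conditional effect.
#'
#' @param subject A [make_subject()] specification.
#' @param rating An [emotion_rating()].
#' @param duration_s Total trial length in seconds (including baseline).
#' @param baseline_s Leading baseline length in seconds.
#' @param rate_hz Sampling rate; must exceed twice the highest band frequency.
#' @param seed Integer seed for phases and noise.
#' @param effect_size Nonnegative multiplier on both class-conditional
#'   effects; `0` removes all class information.
#' @return An object of class `raw_trial` with a `channels x samples` data
#'   matrix.
#' @export
simulate_trial <- function(subject, rating, duration_s, baseline_s, rate_hz,
                           seed = 1, effect_size = 1) {
  stopifnot(inherits(subject, "subject_spec"))
  if (!inherits(rating, "emotion_rating"))
    rating <- emotion_rating(rating[[1]], rating[[2]])
  stop_if_not(duration_s > baseline_s && baseline_s >= 0,
              "need duration_s > baseline_s >= 0")
  centers <- .band_centers + subject$freq_jitter_hz
  stop_if_not(rate_hz > 2 * max(centers),
              "sampling rate %.1f Hz too low for band content up to %.1f Hz (aliasing)",
              rate_hz, max(centers))
  n <- round(duration_s * rate_hz)
  n_base <- round(baseline_s * rate_hz)
  t <- (seq_len(n) - 1) / rate_hz
  chans <- subject$channel_names
  nc <- length(chans)

  # Class-conditional amplitude modulation, zero at the rating midpoint 5.
  e_val <- tanh((rating$valence - 5) / 2) * 0.6 * subject$asymmetry_gain *
    effect_size
  e_val <- max(min(e_val, 0.95), -0.95)
  e_aro <- max(min(tanh((rating$arousal - 5) / 2) * 0.5 * effect_size,
                   0.95), -0.95)

  # Per-channel alpha asymmetry weights: full effect on F3/F4, half on
  # FP1/FP2, sign +1 on right-hemisphere (even-numbered) electrodes.
  asym_w <- vapply(chans, function(ch) {
    side <- if (grepl("2|4|6|8", ch)) 1 else -1
    mag <- if (ch %in% c("F3", "F4")) 1 else 0.5
    side * mag
  }, numeric(1))

  data <- with_seed(seed, {
    out <- matrix(0, nrow = nc, ncol = n, dimnames = list(chans, NULL))
    for (ci in seq_len(nc)) {
      x <- numeric(n)
      for (bi in seq_along(centers)) {
        band <- names(centers)[bi]
        a_base <- .band_amps[bi]
        a_mod <- a_base
        if (band == "alpha") a_mod <- a_base * (1 + e_val * asym_w[ci])
        if (band %in% c("beta", "gamma")) a_mod <- a_base * (1 + e_aro)
        amp <- c(rep(a_base, n_base), rep(a_mod, n - n_base))
        phase <- runif(1, 0, 2 * pi)
        x <- x + amp * sin(2 * pi * centers[bi] * t + phase)
      }
      x <- x + pink_noise(n, rate_hz, subject$pink_noise_scale)
      if (subject$noise_sd > 0) x <- x + rnorm(n, 0, subject$noise_sd)
      out[ci, ] <- x * subject$channel_gains[ci]
    }
    out
  })

  raw_trial(subject_id = subject$subject_id, trial_id = NA_integer_,
            data = data, sampling_rate_hz = rate_hz,
            baseline_s = baseline_s, rating = rating)
}

#' Raw trial container
#'
#' One trial's continuous multi-channel EEG plus its acquisition metadata
#' and valence/arousal rating.
#'
#' @param subject_id,trial_id Integer identifiers.
#' @param data `channels x samples` numeric matrix; row names are the
#'   channel labels.
#' @param sampling_rate_hz Positive sampling rate.
#' @param baseline_s Seconds of leading baseline contained in `data`.
#' @param rating An [emotion_rating()].
#' @return An object of class `raw_trial`.
#' @export
raw_trial <- function(subject_id, trial_id, data, sampling_rate_hz,
                      baseline_s, rating) {
  stop_if_not(is.matrix(data) && !is.null(rownames(data)),
              "data must be a channels x samples matrix with channel row names")
  stop_if_not(sampling_rate_hz > 0, "sampling_rate_hz must be positive")
  dur <- ncol(data) / sampling_rate_hz
  stop_if_not(baseline_s >= 0 && baseline_s < dur,
              "baseline_s must be in [0, duration)")
  structure(list(subject_id = as.integer(subject_id),
                 trial_id = as.integer(trial_id),
                 data = data,
                 sampling_rate_hz = sampling_rate_hz,
                 channel_names = rownames(data),
                 baseline_s = baseline_s,
                 rating = rating),
            class = "raw_trial")
}

#' @export
print.raw_trial <- function(x, ...) {
  cat(sprintf(
    "<raw_trial> subject %s trial %s: %d ch x %d samples @ %g Hz (%.1f s, %.1f s baseline), valence %.2f arousal %.2f\n",
    x$subject_id, x$trial_id, nrow(x$data), ncol(x$data),
    x$sampling_rate_hz, ncol(x$data) / x$sampling_rate_hz, x$baseline_s,
    x$rating$valence, x$rating$arousal))
  invisible(x)
}

trial_duration <- function(trial) ncol(trial$data) / trial$sampling_rate_hz

#' Simulate a multi-subject EEG dataset
#'
#' Draws one [make_subject()] specification per subject and one trial per
#' `(subject, trial)` pair, with per-trial seeds derived deterministically
#' from `(seed, subject_id, trial_id)`. Ratings are drawn so that low/high
#' halves of both scales are balanced within each subject; by default they
#' avoid the ambiguous neighborhood of the class threshold 5 by sampling
#' from `[1, 4.5]` and `[5.5, 9]`.
#'
#' @param n_subjects,n_trials Positive counts.
#' @param duration_s,baseline_s,rate_hz Trial geometry (see
#'   [dataset_profile()] for the two canonical layouts).
#' @param shift_scale Inter-subject shift magnitude passed to
#'   [make_subject()].
#' @param effect_size Class-effect multiplier passed to [simulate_trial()].
#' @param seed Integer base seed; the dataset is a pure function of the seed
#'   and the arguments.
#' @param boundary_gap If `TRUE` (default) ratings avoid `(4.5, 5.5)`;
#'   if `FALSE` they are uniform on `[1, 9]`.
#' @param noise_sd,pink_noise_scale Noise levels passed to [make_subject()].
#' @param subject_ids Which subject ids to generate (default `0:(n_subjects
#'   - 1)`). Because every per-subject and per-trial stream is derived from
#'   `(seed, subject_id, trial_id)`, generating a subset yields exactly the
#'   corresponding slice of the full dataset, which lets large datasets be
#'   produced one subject at a time.
#' @return A list of `raw_trial` objects with attribute `subjects` (the
#'   subject specifications).
#' @export
simulate_dataset <- function(n_subjects, n_trials, duration_s = 63,
                             baseline_s = 3, rate_hz = 128,
                             shift_scale = 0.5, effect_size = 1, seed = 42,
                             boundary_gap = TRUE, noise_sd = 0.2,
                             pink_noise_scale = 0.25,
                             subject_ids = seq_len(n_subjects) - 1L) {
  stop_if_not(n_subjects >= 1 && n_trials >= 1, "counts must be positive")
  subjects <- lapply(subject_ids, make_subject,
                     shift_scale = shift_scale, seed = seed,
                     noise_sd = noise_sd,
                     pink_noise_scale = pink_noise_scale)
  trials <- vector("list", length(subjects) * n_trials)
  k <- 1L
  for (subj in subjects) {
    sid <- subj$subject_id
    ratings <- with_seed(mix_seed(seed, sid, 999999L), {
      draw_dim <- function() {
        if (boundary_gap) {
          low <- sample(rep(c(TRUE, FALSE), length.out = n_trials))
          ifelse(low, runif(n_trials, 1, 4.5), runif(n_trials, 5.5, 9))
        } else {
          runif(n_trials, 1, 9)
        }
      }
      list(valence = draw_dim(), arousal = draw_dim())
    })
    for (tid in seq_len(n_trials)) {
      tr <- simulate_trial(
        subj, emotion_rating(ratings$valence[tid], ratings$arousal[tid]),
        duration_s = duration_s, baseline_s = baseline_s, rate_hz = rate_hz,
        seed = mix_seed(seed, sid, tid), effect_size = effect_size)
      tr$trial_id <- tid
      trials[[k]] <- tr
      k <- k + 1L
    }
  }
  attr(trials, "subjects") <- subjects
  trials
}

#' Periodogram band power
#'
#' Mean power of `x` inside `[low_hz, high_hz]`, computed from the raw
#' periodogram. Used as the spectral oracle throughout the package (e.g. to
#' verify where generated power lives and to read out alpha asymmetry).
#'
#' @param x Numeric vector.
#' @param rate_hz Sampling rate of `x`.
#' @param low_hz,high_hz Band edges in Hz.
#' @return Total periodogram power in the band (one-sided).
#' @export
band_power <- function(x, rate_hz, low_hz, high_hz) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2 / n^2
  f <- (seq_len(n) - 1) * rate_hz / n
  half <- f <= rate_hz / 2
  sel <- half & f >= low_hz & f <= high_hz
  2 * sum(p[sel])
}
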