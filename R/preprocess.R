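#' Label scheme
#'
#' Mapping from continuous valence/arousal ratings to class indices.
#' Binary modes threshold one dimension at `threshold` (ratings at or above
#' the threshold are "high"; the quadrant definitions use `>= 5`, and the
#' same rule is applied everywhere for consistency). Quadrant mode yields
#' four classes in the fixed order LVLA, LVHA, HVLA, HVHA.
#'
#' @param mode One of `"binary_valence"`, `"binary_arousal"`, `"quadrant"`.
#' @param threshold Class threshold on the 1-9 scale (default 5).
#' @return An object of class `label_scheme` with `mode`, `threshold`,
#'   `n_classes` and `class_names`.
#' @export
label_scheme <- function(mode = c("binary_valence", "binary_arousal",
                                  "quadrant"),
                         threshold = 5) {
  mode <- match.arg(mode)
  cls <- switch(mode,
    binary_valence = c("low", "high"),
    binary_arousal = c("low", "high"),
    quadrant = c("LVLA", "LVHA", "HVLA", "HVHA"))
  structure(list(mode = mode, threshold = threshold,
                 n_classes = length(cls), class_names = cls),
            class = "label_scheme")
}

#' Derive a class label from a rating
#'
#' @param rating An [emotion_rating()] (or list with `valence`, `arousal`).
#' @param scheme A [label_scheme()].
#' @return Integer class index in `1..n_classes` (order as in the scheme's
#'   `class_names`).
#' @export
label_rating <- function(rating, scheme) {
  check_rating_range(rating$valence, "valence")
  check_rating_range(rating$arousal, "arousal")
  th <- scheme$threshold
  hv <- rating$valence >= th
  ha <- rating$arousal >= th
  switch(scheme$mode,
    binary_valence = ifelse(hv, 2L, 1L),
    binary_arousal = ifelse(ha, 2L, 1L),
    # order: LVLA, LVHA, HVLA, HVHA
    quadrant = 1L + 2L * as.integer(hv) + as.integer(ha))
}

#' Remove the leading baseline segment
#'
#' Drops the first `baseline_s` seconds of the trial, keeping the tail;
#' the returned trial has `baseline_s = 0`.
#'
#' @param trial A [raw_trial()].
#' @return The trial without its baseline segment.
#' @export
drop_baseline <- function(trial) {
  stopifnot(inherits(trial, "raw_trial"))
  if (trial$baseline_s == 0) return(trial)
  n_base <- round(trial$baseline_s * trial$sampling_rate_hz)
  stop_if_not(n_base < ncol(trial$data),
              "baseline (%g s) must be shorter than the trial", trial$baseline_s)
  trial$data <- trial$data[, (n_base + 1L):ncol(trial$data), drop = FALSE]
  trial$baseline_s <- 0
  trial
}

#' Resample a trial
#'
#' Anti-aliased polyphase resampling to `target_rate_hz`. Only
#' downsampling (or the identity) is allowed by default, since the
#' supported pipelines never increase the rate.
#'
#' @param trial A [raw_trial()].
#' @param target_rate_hz Positive target rate.
#' @param allow_upsample Permit `target_rate_hz` above the source rate.
#' @return The resampled trial; the sample count becomes
#'   `round(duration_s * target_rate_hz)`.
#' @export
resample_trial <- function(trial, target_rate_hz, allow_upsample = FALSE) {
  stopifnot(inherits(trial, "raw_trial"))
  stop_if_not(target_rate_hz > 0, "target_rate_hz must be positive")
  src <- trial$sampling_rate_hz
  if (isTRUE(all.equal(src, target_rate_hz))) return(trial)
  stop_if_not(allow_upsample || target_rate_hz < src,
              "upsampling (%g -> %g Hz) is disabled", src, target_rate_hz)
  # rational rate ratio p/q (rates are expected to be near-integers)
  scale <- 1000
  p <- round(target_rate_hz * scale)
  q <- round(src * scale)
  g <- gcd_int(p, q)
  p <- p / g; q <- q / g
  dur <- ncol(trial$data) / src
  n_out <- round(dur * target_rate_hz)
  out <- t(apply(trial$data, 1, function(x) {
    y <- signal::resample(x, p, q)
    length(y) <- n_out   # trim/pad the polyphase tail to the exact count
    y[is.na(y)] <- 0
    y
  }))
  rownames(out) <- trial$channel_names
  trial$data <- out
  trial$sampling_rate_hz <- target_rate_hz
  trial
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Band-pass filter a trial
#'
#' Fourth-order Butterworth band-pass (default 4-45 Hz) applied
#' forward-backward (zero phase) to every channel.
#'
#' @param trial A [raw_trial()].
#' @param low_hz,high_hz Pass-band edges in Hz.
#' @param order Butterworth order of the one-way design.
#' @return The filtered trial.
#' @export
bandpass_trial <- function(trial, low_hz = 4, high_hz = 45, order = 4) {
  stopifnot(inherits(trial, "raw_trial"))
  nyq <- trial$sampling_rate_hz / 2
  stop_if_not(low_hz > 0 && low_hz < high_hz && high_hz < nyq,
              "need 0 < low_hz < high_hz < Nyquist (%g Hz)", nyq)
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  out <- t(apply(trial$data, 1, function(x) signal::filtfilt(bf, x)))
  rownames(out) <- trial$channel_names
  trial$data <- out
  trial
}

#' Select and reorder channels
#'
#' @param trial A [raw_trial()].
#' @param names Ordered channel labels to keep (default: the four
#'   prefrontal electrodes FP1, FP2, F3, F4).
#' @return The trial restricted to `names`, in that order.
#' @export
select_channels <- function(trial, names = c("FP1", "FP2", "F3", "F4")) {
  stopifnot(inherits(trial, "raw_trial"))
  missing <- setdiff(names, trial$channel_names)
  stop_if_not(length(missing) == 0,
              "channel(s) %s not present; available: %s",
              paste(missing, collapse = ", "),
              paste(trial$channel_names, collapse = ", "))
  trial$data <- trial$data[names, , drop = FALSE]
  trial$channel_names <- names
  trial
}

#' Segment a trial into fixed-length windows
#'
#' Non-overlapping by default; incomplete trailing samples are discarded.
#'
#' @param trial A [raw_trial()].
#' @param window_s Window length in seconds.
#' @param overlap_s Overlap between consecutive windows in seconds.
#' @return A list of `channels x samples` matrices (possibly empty).
#' @export
window_trial <- function(trial, window_s = 1, overlap_s = 0) {
  stopifnot(inherits(trial, "raw_trial"))
  stop_if_not(window_s > 0 && overlap_s >= 0 && overlap_s < window_s,
              "need window_s > 0 and 0 <= overlap_s < window_s")
  f <- round(window_s * trial$sampling_rate_hz)
  step <- round((window_s - overlap_s) * trial$sampling_rate_hz)
  n <- ncol(trial$data)
  if (n < f) return(list())
  starts <- seq(1L, n - f + 1L, by = step)
  lapply(starts, function(s) trial$data[, s:(s + f - 1L), drop = FALSE])
}

#' Min-max normalize one window
#'
#' Per channel, maps values affinely onto `[0, 1]`; a constant channel maps
#' to all zeros so the output stays bounded and deterministic.
#'
#' @param w A `channels x samples` matrix.
#' @return The normalized matrix.
#' @export
normalize_window <- function(w) {
  mins <- apply(w, 1, min)
  maxs <- apply(w, 1, max)
  rng <- maxs - mins
  rng[rng == 0] <- 1          # constant channel: (x - min)/1 = 0 everywhere
  (w - mins) / rng
}

#' Windowed dataset container
#'
#' @param X `n x channels x samples` array of normalized windows.
#' @param valence,arousal Numeric vectors of per-window ratings.
#' @param labels Integer class indices consistent with `scheme`.
#' @param subject_ids Integer vector of per-window subject ids.
#' @param window_s,sampling_rate_hz Window geometry.
#' @param scheme The [label_scheme()] used to derive `labels`.
#' @param channel_names Ordered channel labels.
#' @return An object of class `windowed_dataset`.
#' @export
windowed_dataset <- function(X, valence, arousal, labels, subject_ids,
                             window_s, sampling_rate_hz, scheme,
                             channel_names) {
  n <- dim(X)[1]
  stop_if_not(length(labels) == n && length(subject_ids) == n &&
                length(valence) == n && length(arousal) == n,
              "metadata length must match dim(X)[1]")
  structure(list(X = X, valence = valence, arousal = arousal,
                 labels = as.integer(labels),
                 subject_ids = as.integer(subject_ids),
                 window_s = window_s, sampling_rate_hz = sampling_rate_hz,
                 scheme = scheme, channel_names = channel_names),
            class = "windowed_dataset")
}

#' @export
print.windowed_dataset <- function(x, ...) {
  d <- dim(x$X)
  cat(sprintf(
    "<windowed_dataset> %d windows of %d ch x %d samples @ %g Hz; %d subject(s); scheme %s (%d classes)\n",
    d[1], d[2], d[3], x$sampling_rate_hz, length(unique(x$subject_ids)),
    x$scheme$mode, x$scheme$n_classes))
  invisible(x)
}

#' Subset a windowed dataset
#'
#' Selects windows by index or logical mask, keeping all metadata aligned.
#'
#' @param ds A [windowed_dataset()].
#' @param idx Integer indices or logical mask over windows.
#' @return The subsetted [windowed_dataset()].
#' @export
subset_windows <- function(ds, idx) {
  windowed_dataset(ds$X[idx, , , drop = FALSE], ds$valence[idx],
                   ds$arousal[idx], ds$labels[idx], ds$subject_ids[idx],
                   ds$window_s, ds$sampling_rate_hz, ds$scheme,
                   ds$channel_names)
}

#' Run the full preprocessing pipeline
#'
#' Stage order: resample to the profile's analysis rate, drop the leading
#' baseline, 4-45 Hz Butterworth band-pass, select the four prefrontal
#' channels, segment into non-overlapping 1 s windows, min-max normalize
#' each window per channel, and derive class labels.
#'
#' @param trials List of [raw_trial()] objects.
#' @param profile `"deap_like"`, `"eppvr_like"`, or a list as returned by
#'   [dataset_profile()].
#' @param scheme A [label_scheme()].
#' @param channels Channels to keep, in order.
#' @param window_s Window length in seconds.
#' @param low_hz,high_hz Band-pass edges.
#' @return A [windowed_dataset()].
#' @export
preprocess_trials <- function(trials, profile = "deap_like",
                              scheme = label_scheme("binary_valence"),
                              channels = c("FP1", "FP2", "F3", "F4"),
                              window_s = 1, low_hz = 4, high_hz = 45) {
  stop_if_not(length(trials) > 0, "no trials supplied")
  if (is.character(profile)) profile <- dataset_profile(profile)
  Xs <- list(); val <- list(); aro <- list(); lab <- list(); sid <- list()
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    wins <- tryCatch({
      tr <- resample_trial(tr, profile$target_rate_hz)
      tr <- drop_baseline(tr)
      tr <- bandpass_trial(tr, low_hz, high_hz)
      tr <- select_channels(tr, channels)
      lapply(window_trial(tr, window_s), normalize_window)
    }, error = function(e) {
      stop(sprintf("trial %s (subject %s): %s", trials[[i]]$trial_id,
                   trials[[i]]$subject_id, conditionMessage(e)),
           call. = FALSE)
    })
    if (length(wins) == 0) next
    lb <- label_rating(tr$rating, scheme)
    Xs[[length(Xs) + 1L]] <- wins
    val[[length(val) + 1L]] <- rep(tr$rating$valence, length(wins))
    aro[[length(aro) + 1L]] <- rep(tr$rating$arousal, length(wins))
    lab[[length(lab) + 1L]] <- rep(lb, length(wins))
    sid[[length(sid) + 1L]] <- rep(tr$subject_id, length(wins))
  }
  wins <- unlist(Xs, recursive = FALSE)
  n <- length(wins)
  stop_if_not(n > 0, "preprocessing produced no windows")
  c_dim <- nrow(wins[[1]]); f_dim <- ncol(wins[[1]])
  X <- array(0, dim = c(n, c_dim, f_dim))
  for (i in seq_len(n)) X[i, , ] <- wins[[i]]
  windowed_dataset(X, unlist(val), unlist(aro), unlist(lab), unlist(sid),
                   window_s, profile$target_rate_hz, scheme, channels)
}
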