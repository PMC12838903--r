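# Shared fixtures, built once per test run and memoized. All sizes are
# deliberately small: 100 Hz trials of a few seconds keep every band of the
# generator below Nyquist while holding network passes to desk scale.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- build()
  .fixtures[[key]]
}

# 3 subjects x 4 trials of 9 s (1 s baseline) at 100 Hz -> 32 windows/subject
tiny_trials <- function() {
  memo("tiny_trials", function() {
    simulate_dataset(3, 4, duration_s = 9, baseline_s = 1, rate_hz = 100,
                     shift_scale = 0.5, effect_size = 1, seed = 42)
  })
}

tiny_ds <- function() {
  memo("tiny_ds", function() {
    preprocess_trials(tiny_trials(), profile = list(target_rate_hz = 100),
                      scheme = label_scheme("binary_valence"))
  })
}

# a small trained model over subjects != 0 of the tiny dataset
tiny_teacher <- function() {
  memo("tiny_teacher", function() {
    ds <- tiny_ds()
    src <- eeglwf:::subset_windows(ds, ds$subject_ids != 0)
    pretrain(src, tiny_cfg(),
             train_config(batch_size = 32, pretrain_epochs = 2, seed = 42))
  })
}

tiny_cfg <- function() model_config(c = 4, f = 100)

# reduced-width config for cheap gradient / shape work
slim_cfg <- function() {
  model_config(c = 4, f = 100, temporal_filters = 8, spatial_filters = 5,
               ffl_channels = c(5L, 6L, 7L, 8L), dcl_hidden = c(10L, 6L),
               dropout = 0)
}

# total periodogram power of a vector inside a band, computed directly
# (independent of band_power) for use as a spectral oracle
oracle_band_power <- function(x, rate, lo, hi) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2 / n^2
  f <- (seq_len(n) - 1) * rate / n
  sel <- f <= rate / 2 & f >= lo & f <= hi
  2 * sum(p[sel])
}

# brute-force ranking AUC of a statistic separating two classes
oracle_auc <- function(stat, is_high) {
  hi <- stat[is_high]
  lo <- stat[!is_high]
  pairs <- outer(hi, lo, ">") + 0.5 * outer(hi, lo, "==")
  mean(pairs)
}
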