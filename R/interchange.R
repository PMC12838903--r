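# On-disk interchange format: one directory per subject holding a
# `trials.csv` metadata table and one plain-text array file per trial
# (channels x samples; one CSV row per channel, full %.17g precision so
# the round trip is bit-exact).

fmt_num <- function(x) sprintf("%.17g", x)

write_matrix_csv <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(m))) {
    writeLines(paste(fmt_num(m[i, ]), collapse = ","), con)
  }
  invisible(path)
}

read_matrix_csv <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = ",")
  m <- as.matrix(dt)
  dimnames(m) <- NULL
  m
}

#' Write raw trials in the interchange format
#'
#' Creates one `subject_<id>` directory per subject under `root`, each
#' containing `trials.csv` (subject_id, trial_id, valence, arousal,
#' sampling_rate_hz, baseline_s, n_channels, channels, file) and one
#' channels-x-samples CSV per trial.
#'
#' @param trials List of [raw_trial()] objects.
#' @param root Output directory (created if missing).
#' @return `root`, invisibly.
#' @export
write_interchange <- function(trials, root) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  by_subj <- split(trials, vapply(trials, function(t) t$subject_id,
                                  integer(1)))
  for (sid in names(by_subj)) {
    sdir <- file.path(root, sprintf("subject_%03d", as.integer(sid)))
    dir.create(sdir, showWarnings = FALSE)
    meta <- list()
    for (tr in by_subj[[sid]]) {
      fname <- sprintf("trial_%04d.csv", tr$trial_id)
      write_matrix_csv(tr$data, file.path(sdir, fname))
      meta[[length(meta) + 1L]] <- data.frame(
        subject_id = tr$subject_id, trial_id = tr$trial_id,
        valence = fmt_num(tr$rating$valence),
        arousal = fmt_num(tr$rating$arousal),
        sampling_rate_hz = fmt_num(tr$sampling_rate_hz),
        baseline_s = fmt_num(tr$baseline_s),
        n_channels = length(tr$channel_names),
        channels = paste(tr$channel_names, collapse = ";"),
        file = fname)
    }
    data.table::fwrite(do.call(rbind, meta), file.path(sdir, "trials.csv"))
  }
  invisible(root)
}

#' Read raw trials from the interchange format
#'
#' @param root Directory written by [write_interchange()].
#' @return A list of [raw_trial()] objects, ordered by subject then trial.
#' @export
read_interchange <- function(root) {
  sdirs <- sort(list.dirs(root, recursive = FALSE))
  stop_if_not(length(sdirs) > 0, "no subject directories under %s", root)
  trials <- list()
  for (sdir in sdirs) {
    meta <- data.table::fread(file.path(sdir, "trials.csv"),
                              colClasses = list(character = c(
                                "valence", "arousal", "sampling_rate_hz",
                                "baseline_s")))
    stop_if_not(nrow(meta) == length(list.files(sdir, pattern = "^trial_")),
                "metadata rows and trial files disagree in %s", sdir)
    for (i in seq_len(nrow(meta))) {
      m <- read_matrix_csv(file.path(sdir, meta$file[i]))
      ch <- strsplit(meta$channels[i], ";")[[1]]
      stop_if_not(nrow(m) == meta$n_channels[i] &&
                    length(ch) == meta$n_channels[i],
                  "channel count mismatch in %s", meta$file[i])
      rownames(m) <- ch
      trials[[length(trials) + 1L]] <- raw_trial(
        subject_id = meta$subject_id[i], trial_id = meta$trial_id[i],
        data = m,
        sampling_rate_hz = as.numeric(meta$sampling_rate_hz[i]),
        baseline_s = as.numeric(meta$baseline_s[i]),
        rating = emotion_rating(as.numeric(meta$valence[i]),
                                as.numeric(meta$arousal[i])))
    }
  }
  trials
}

#' Write / read a windowed dataset
#'
#' Stores the window stack as a wide CSV (one row per window: subject id,
#' ratings, label, then the flattened `c x f` values) plus a JSON sidecar
#' with the window geometry, channel order and label scheme.
#'
#' @param ds A [windowed_dataset()].
#' @param path Output directory.
#' @return `path` invisibly (`write`); the dataset (`read`).
#' @export
write_windowed <- function(ds, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  d <- dim(ds$X)
  jsonlite::write_json(list(
    n = d[1], c = d[2], f = d[3], window_s = ds$window_s,
    sampling_rate_hz = ds$sampling_rate_hz,
    channel_names = ds$channel_names,
    scheme = list(mode = ds$scheme$mode, threshold = ds$scheme$threshold)),
    file.path(path, "meta.json"), auto_unbox = TRUE, digits = NA)
  con <- file(file.path(path, "windows.csv"), "w")
  on.exit(close(con))
  for (i in seq_len(d[1])) {
    writeLines(paste(c(ds$subject_ids[i], fmt_num(ds$valence[i]),
                       fmt_num(ds$arousal[i]), ds$labels[i],
                       fmt_num(as.vector(ds$X[i, , ]))), collapse = ","),
               con)
  }
  invisible(path)
}

#' @rdname write_windowed
#' @export
read_windowed <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  dt <- as.matrix(data.table::fread(file.path(path, "windows.csv"),
                                    header = FALSE, sep = ","))
  n <- meta$n; cdim <- meta$c; fdim <- meta$f
  stop_if_not(nrow(dt) == n && ncol(dt) == 4 + cdim * fdim,
              "windows.csv does not match meta.json")
  X <- array(0, c(n, cdim, fdim))
  for (i in seq_len(n)) X[i, , ] <- matrix(dt[i, -(1:4)], cdim, fdim)
  windowed_dataset(X, valence = dt[, 2], arousal = dt[, 3],
                   labels = as.integer(dt[, 4]),
                   subject_ids = as.integer(dt[, 1]),
                   window_s = meta$window_s,
                   sampling_rate_hz = meta$sampling_rate_hz,
                   scheme = label_scheme(meta$scheme$mode,
                                         meta$scheme$threshold),
                   channel_names = meta$channel_names)
}
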