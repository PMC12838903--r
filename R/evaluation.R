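#' Classification accuracy
#'
#' @param pred,truth Equal-length integer label vectors.
#' @return Fraction of exact matches.
#' @export
accuracy_score <- function(pred, truth) {
  stop_if_not(length(pred) == length(truth) && length(pred) >= 1,
              "pred and truth must have equal positive length")
  mean(pred == truth)
}

#' Confusion matrix
#'
#' Rows are actual classes, columns are predicted classes.
#'
#' @param pred,truth Integer labels in `1..K`.
#' @param K Number of classes.
#' @return A `K x K` integer matrix whose entries sum to `length(truth)`.
#' @export
confusion_matrix <- function(pred, truth, K) {
  stop_if_not(length(pred) == length(truth), "length mismatch")
  m <- matrix(0L, K, K)
  for (i in seq_along(truth)) {
    m[truth[i], pred[i]] <- m[truth[i], pred[i]] + 1L
  }
  m
}

# binary F-score with `positive` as the positive class:
# TP / (TP + (FP + FN)/2)
.f_binary <- function(pred, truth, positive) {
  tp <- sum(pred == positive & truth == positive)
  fp <- sum(pred == positive & truth != positive)
  fn <- sum(pred != positive & truth == positive)
  if (tp + fp + fn == 0) return(NA_real_)
  tp / (tp + (fp + fn) / 2)
}

#' F-score
#'
#' Binary (`K = 2`): `TP / (TP + (FP + FN)/2)` with class 2 ("high") as
#' positive. Multiclass: macro average of one-vs-rest binary scores, with
#' classes absent from both prediction and truth contributing 0.
#'
#' @param pred,truth Integer labels in `1..K`.
#' @param K Number of classes (default: inferred).
#' @return F-score in `[0, 1]`; 0 with a warning if undefined everywhere.
#' @export
f_score <- function(pred, truth, K = max(pred, truth)) {
  stop_if_not(length(pred) == length(truth) && length(pred) >= 1,
              "pred and truth must have equal positive length")
  if (K == 2) {
    f <- .f_binary(pred, truth, positive = 2L)
    if (is.na(f)) {
      warning("F-score undefined (no positives in prediction or truth); returning 0")
      return(0)
    }
    return(f)
  }
  fs <- vapply(seq_len(K), function(k) .f_binary(pred, truth, k), numeric(1))
  if (all(is.na(fs))) {
    warning("F-score undefined for every class; returning 0")
    return(0)
  }
  fs[is.na(fs)] <- 0
  mean(fs)
}

#' Metrics bundle for one evaluation fold
#'
#' @param pred,truth Integer labels.
#' @param K Number of classes.
#' @return A list with `accuracy`, `f_score`, `confusion`, and (for
#'   `K = 2`) the `tp`, `tn`, `fp`, `fn` counts.
#' @export
fold_metrics <- function(pred, truth, K) {
  cm <- confusion_matrix(pred, truth, K)
  out <- list(accuracy = accuracy_score(pred, truth),
              f_score = suppressWarnings(f_score(pred, truth, K)),
              confusion = cm, n = length(truth))
  if (K == 2) {
    out$tp <- cm[2, 2]; out$tn <- cm[1, 1]
    out$fp <- cm[1, 2]; out$fn <- cm[2, 1]
  }
  out
}

#' Two-tailed paired t-test on per-subject accuracies
#'
#' @param acc_a,acc_b Equal-length numeric vectors (one entry per subject).
#' @return A list with `t`, `p` and `df`.
#' @export
paired_t_test <- function(acc_a, acc_b) {
  stop_if_not(length(acc_a) == length(acc_b) && length(acc_a) >= 2,
              "need equal lengths >= 2")
  d <- acc_a - acc_b
  if (stats::sd(d) == 0) {
    if (all(d == 0)) return(list(t = 0, p = 1, df = length(d) - 1))
    stop("paired differences have zero variance; t statistic is degenerate",
         call. = FALSE)
  }
  ht <- stats::t.test(acc_a, acc_b, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter))
}

# run one fold: pretrain on source, adapt on the target's split, test on
# the remainder. Returns metrics plus the teacher's pre-adaptation
# accuracy on the same test windows.
run_fold <- function(source, target, cfg, tc, lwf, fraction = 0.02,
                     use_lwf = TRUE, seed = tc$seed) {
  tc_run <- tc
  tc_run$seed <- as.integer(seed)
  teacher <- pretrain(source, cfg, tc_run)
  pair <- init_student(teacher, seed = seed, lwf = lwf)
  split <- select_incremental(target, fraction,
                              seed = mix_seed(seed, target$subject_ids[1]))
  student <- if (use_lwf) finetune_lwf(pair, split, tc_run)
             else finetune_plain(pair, split, tc_run)
  pred <- model_predict(student, split$test$X)$labels
  pre_pred <- model_predict(teacher, split$test$X)$labels
  met <- fold_metrics(pred, split$test$labels, cfg$n_classes)
  list(metrics = met, n_test = length(split$test_idx),
       pre_accuracy = accuracy_score(pre_pred, split$test$labels),
       teacher = teacher, student = student, split = split)
}

#' Leave-one-subject-out evaluation
#'
#' For each subject in turn: pre-train on the remaining subjects, adapt on
#' the target's incremental split, test on its held-out remainder.
#' Repeated `repeats` times with seeds `base_seed + repeat - 1` (the split
#' additionally mixes in the subject id), re-drawing both the split and
#' the initialization.
#'
#' @param dataset A multi-subject [windowed_dataset()].
#' @param cfg A [model_config()].
#' @param tc A [train_config()] (its `seed` is the base seed).
#' @param lwf A [lwf_config()].
#' @param fraction Incremental fraction of the target data.
#' @param repeats Number of repeats per subject.
#' @param use_lwf `FALSE` runs the plain fine-tuning arm.
#' @return An object of class `loso_result`: list with `folds`
#'   (data frame: subject, repeat, accuracy, f_score, pre_accuracy,
#'   n_test), `confusions`, and `summary` (pooled and per-axis mean/sd).
#' @export
loso <- function(dataset, cfg, tc = train_config(), lwf = lwf_config(),
                 fraction = 0.02, repeats = 5L, use_lwf = TRUE) {
  stopifnot(inherits(dataset, "windowed_dataset"))
  subjects <- sort(unique(dataset$subject_ids))
  stop_if_not(length(subjects) >= 2, "need at least 2 subjects")
  rows <- list(); confs <- list()
  for (s in subjects) {
    tgt <- subset_windows(dataset, dataset$subject_ids == s)
    src <- subset_windows(dataset, dataset$subject_ids != s)
    for (r in seq_len(repeats)) {
      fr <- run_fold(src, tgt, cfg, tc, lwf, fraction, use_lwf,
                     seed = tc$seed + (r - 1L))
      rows[[length(rows) + 1L]] <- data.frame(
        subject = s, rep = r, accuracy = fr$metrics$accuracy,
        f_score = fr$metrics$f_score, pre_accuracy = fr$pre_accuracy,
        n_test = fr$n_test)
      confs[[sprintf("s%d_r%d", s, r)]] <- fr$metrics$confusion
    }
  }
  folds <- do.call(rbind, rows)
  per_subject <- stats::aggregate(cbind(accuracy, f_score) ~ subject,
                                  folds, mean)
  summary <- list(
    accuracy_mean = mean(folds$accuracy), accuracy_sd = stats::sd(folds$accuracy),
    f_score_mean = mean(folds$f_score), f_score_sd = stats::sd(folds$f_score),
    accuracy_by_subject = per_subject,
    n_folds = nrow(folds))
  structure(list(folds = folds, confusions = confs, summary = summary),
            class = "loso_result")
}

#' @export
print.loso_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<loso_result> %d folds | accuracy %.4f +/- %.4f | F-score %.4f +/- %.4f\n",
    s$n_folds, s$accuracy_mean, s$accuracy_sd, s$f_score_mean,
    s$f_score_sd))
  invisible(x)
}

#' Ablation suite
#'
#' Runs [loso()] for the full model and each requested variant:
#' `"temporal"`, `"spatial"`, `"fusion"` drop one network stage;
#' `"no_lwf"` replaces adaptation with plain fine-tuning.
#'
#' @param dataset A multi-subject [windowed_dataset()].
#' @param cfg,tc,lwf,fraction,repeats As in [loso()].
#' @param variants Character vector of ablation tags.
#' @return A list with `table` (variant x mean/sd accuracy and F-score)
#'   and `results` (named `loso_result`s, including `"full"`).
#' @export
ablation_suite <- function(dataset, cfg, tc = train_config(),
                           lwf = lwf_config(), fraction = 0.02,
                           repeats = 1L,
                           variants = c("temporal", "spatial", "fusion",
                                        "no_lwf")) {
  runs <- list(full = loso(dataset, cfg, tc, lwf, fraction, repeats))
  for (v in variants) {
    if (v == "no_lwf") {
      runs[[v]] <- loso(dataset, cfg, tc, lwf, fraction, repeats,
                        use_lwf = FALSE)
    } else {
      runs[[v]] <- loso(dataset, make_variant(cfg, v), tc, lwf, fraction,
                        repeats)
    }
  }
  tab <- do.call(rbind, lapply(names(runs), function(nm) {
    s <- runs[[nm]]$summary
    data.frame(variant = nm, accuracy_mean = s$accuracy_mean,
               accuracy_sd = s$accuracy_sd, f_score_mean = s$f_score_mean,
               f_score_sd = s$f_score_sd)
  }))
  list(table = tab, results = runs)
}

#' Incremental-size sweep
#'
#' Pre-trains once per (subject, repeat) and re-runs the adapt+test arm at
#' each incremental fraction, then compares every fraction against the
#' smallest one with a paired t-test over per-subject accuracies.
#'
#' @param dataset A multi-subject [windowed_dataset()].
#' @param cfg,tc,lwf,repeats As in [loso()].
#' @param fractions Ascending fractions in `(0, 1)`.
#' @return A list with `table` (fraction, n_inc, mean/sd accuracy, paired
#'   t and p against the baseline fraction) and `folds`.
#' @export
sweep_incremental <- function(dataset, cfg, tc = train_config(),
                              lwf = lwf_config(),
                              fractions = c(0.005, 0.01, 0.02, 0.03, 0.05),
                              repeats = 1L) {
  stop_if_not(all(fractions > 0 & fractions < 1) &&
                !is.unsorted(fractions, strictly = TRUE),
              "fractions must be strictly ascending within (0, 1)")
  subjects <- sort(unique(dataset$subject_ids))
  stop_if_not(length(subjects) >= 2, "need at least 2 subjects")
  rows <- list()
  for (s in subjects) {
    tgt <- subset_windows(dataset, dataset$subject_ids == s)
    src <- subset_windows(dataset, dataset$subject_ids != s)
    for (r in seq_len(repeats)) {
      seed_r <- tc$seed + (r - 1L)
      tc_run <- tc; tc_run$seed <- as.integer(seed_r)
      teacher <- pretrain(src, cfg, tc_run)
      for (fr in fractions) {
        pair <- init_student(teacher, seed = seed_r, lwf = lwf)
        split <- select_incremental(tgt, fr, seed = mix_seed(seed_r, s))
        student <- finetune_lwf(pair, split, tc_run)
        pred <- model_predict(student, split$test$X)$labels
        rows[[length(rows) + 1L]] <- data.frame(
          fraction = fr, subject = s, rep = r, n_inc = split$n_inc,
          accuracy = accuracy_score(pred, split$test$labels))
      }
    }
  }
  folds <- do.call(rbind, rows)
  base <- fractions[1]
  per_subj <- function(fr) {
    sub <- folds[folds$fraction == fr, ]
    stats::aggregate(accuracy ~ subject, sub, mean)$accuracy
  }
  base_acc <- per_subj(base)
  tab <- do.call(rbind, lapply(fractions, function(fr) {
    sub <- folds[folds$fraction == fr, ]
    tt <- if (fr == base) list(t = NA_real_, p = NA_real_)
          else tryCatch(paired_t_test(per_subj(fr), base_acc),
                        error = function(e) list(t = NA_real_, p = NA_real_))
    data.frame(fraction = fr, n_inc = sub$n_inc[1],
               accuracy_mean = mean(sub$accuracy),
               accuracy_sd = stats::sd(sub$accuracy),
               t_vs_baseline = tt$t, p_vs_baseline = tt$p)
  }))
  list(table = tab, folds = folds)
}
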