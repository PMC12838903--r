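#' Training configuration
#'
#' Optimization hyperparameters shared by the pre-training and
#' incremental-adaptation phases: mini-batch Adam with batch size 128 and
#' initial learning rate 1e-3; 100 pre-training epochs and 15 incremental
#' epochs by default; base seed 42.
#'
#' @param batch_size Mini-batch size.
#' @param learning_rate Adam step size.
#' @param pretrain_epochs Epochs of source-domain pre-training.
#' @param incremental_epochs Epochs of target-domain adaptation.
#' @param seed Integer base seed controlling initialization, shuffling,
#'   dropout and split sampling.
#' @return An object of class `train_config`.
#' @export
train_config <- function(batch_size = 128L, learning_rate = 1e-3,
                         pretrain_epochs = 100L, incremental_epochs = 15L,
                         seed = 42L) {
  stop_if_not(batch_size >= 1 && pretrain_epochs >= 1 &&
                incremental_epochs >= 1, "epochs and batch size must be >= 1")
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 pretrain_epochs = as.integer(pretrain_epochs),
                 incremental_epochs = as.integer(incremental_epochs),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Learning-without-Forgetting configuration
#'
#' @param lambda_relax Weight of the distillation loss (relaxation
#'   parameter); 0 reduces adaptation to plain fine-tuning.
#' @param temperature Distillation temperature `T > 0`; probability rows
#'   are raised to `1/T` and renormalized before the teacher/student
#'   comparison.
#' @return An object of class `lwf_config`.
#' @export
lwf_config <- function(lambda_relax = 0.1, temperature = 2) {
  stop_if_not(lambda_relax >= 0, "lambda_relax must be >= 0")
  stop_if_not(temperature > 0, "temperature must be > 0")
  structure(list(lambda_relax = lambda_relax, temperature = temperature),
            class = "lwf_config")
}

# mean cross-entropy of probability rows vs integer labels
cross_entropy <- function(probs, labels, eps = 1e-12) {
  -mean(log(pmax(probs[cbind(seq_along(labels), labels)], eps)))
}

#' Pre-train the network on source-domain data
#'
#' Mini-batch Adam on the mean cross-entropy, for `pretrain_epochs` epochs.
#' The seed fully determines initialization, shuffling and dropout, so the
#' returned parameters are a pure function of `(source, cfg, tc)`.
#'
#' @param source A [windowed_dataset()] containing at least two classes.
#' @param cfg A [model_config()]; its `n_classes` must match the scheme.
#' @param tc A [train_config()].
#' @return A `tscl_model` with attribute `history` (per-epoch loss and
#'   training accuracy).
#' @export
pretrain <- function(source, cfg, tc = train_config()) {
  stopifnot(inherits(source, "windowed_dataset"))
  stop_if_not(length(unique(source$labels)) >= 2,
              "source data must contain at least two classes")
  model <- model_init(cfg, seed = tc$seed)
  n <- dim(source$X)[1]
  xfull <- input_array(source$X)
  loss_hist <- acc_hist <- numeric(tc$pretrain_epochs)
  model <- with_seed(mix_seed(tc$seed, 777L), {
    st <- adam_init(model$params)
    for (ep in seq_len(tc$pretrain_epochs)) {
      idx <- sample.int(n)
      ep_loss <- 0; ep_hit <- 0
      for (start in seq(1L, n, by = tc$batch_size)) {
        bi <- idx[start:min(start + tc$batch_size - 1L, n)]
        xb <- xfull[, , , bi, drop = FALSE]
        yb <- source$labels[bi]
        fw <- tscl_forward(model, xb, training = TRUE)
        model$params <- fw$params
        B <- length(bi)
        onehot <- matrix(0, cfg$n_classes, B)
        onehot[cbind(yb, seq_len(B))] <- 1
        dlogits <- (t(fw$probs) - onehot) / B
        grads <- tscl_backward(model, fw$cache, dlogits)
        ad <- adam_step(model$params, grads, st, lr = tc$learning_rate)
        model$params <- ad$params
        st <- ad$state
        ep_loss <- ep_loss + cross_entropy(fw$probs, yb) * B
        ep_hit <- ep_hit + sum(max.col(fw$probs, ties.method = "first") == yb)
      }
      loss_hist[ep] <- ep_loss / n
      acc_hist[ep] <- ep_hit / n
    }
    model
  })
  # eval-mode normalization reflects the final parameters, not the few
  # training batches seen along the way
  model <- calibrate_bn(model, source$X)
  attr(model, "history") <- data.frame(epoch = seq_len(tc$pretrain_epochs),
                                       loss = loss_hist,
                                       accuracy = acc_hist)
  model
}

#' Initialize a teacher/student pair
#'
#' The student inherits every feature-extractor parameter of the (frozen)
#' teacher bit-for-bit and gets a freshly initialized classifier head.
#'
#' @param teacher A pre-trained `tscl_model`.
#' @param seed Integer seed for the new head.
#' @param lwf A [lwf_config()].
#' @return An object of class `teacher_student` with elements `teacher`,
#'   `student` and `lwf`.
#' @export
init_student <- function(teacher, seed = 42, lwf = lwf_config()) {
  stopifnot(inherits(teacher, "tscl_model"))
  cfg <- teacher$config
  sh <- model_shapes(cfg)
  student <- teacher
  student$params$classifier <- with_seed(mix_seed(seed, 555L), {
    h <- cfg$dcl_hidden
    list(fc1 = list(W = init_mat(h[1], sh$dcl_in, sh$dcl_in),
                    b = init_vec(h[1], sh$dcl_in)),
         bn1 = init_bn(h[1]),
         fc2 = list(W = init_mat(h[2], h[1], h[1]),
                    b = init_vec(h[2], h[1])),
         bn2 = init_bn(h[2]),
         fc3 = list(W = init_mat(cfg$n_classes, h[2], h[2]),
                    b = init_vec(cfg$n_classes, h[2])))
  })
  structure(list(teacher = teacher, student = student, lwf = lwf,
                 seed = as.integer(seed)),
            class = "teacher_student")
}

#' Select the labeled incremental subset of a target subject
#'
#' Samples `ceiling(fraction * n)` windows uniformly without replacement;
#' the remainder is the held-out test set. The ceiling rule reproduces the
#' canonical sizes 48 (2% of 2400) and 17 (2% of 840).
#'
#' @param target A [windowed_dataset()] of one subject.
#' @param fraction Fraction in `(0, 1)`.
#' @param seed Integer seed for the draw.
#' @return An object of class `incremental_split` with `inc`, `test`
#'   (windowed datasets), `inc_idx`, `test_idx` and `n_inc`.
#' @export
select_incremental <- function(target, fraction = 0.02, seed = 42) {
  stopifnot(inherits(target, "windowed_dataset"))
  stop_if_not(fraction > 0 && fraction < 1, "fraction must be in (0, 1)")
  n <- dim(target$X)[1]
  n_inc <- ceiling(fraction * n)
  stop_if_not(n_inc >= 1 && n_inc < n,
              "incremental split of %d leaves no training or no test data",
              n_inc)
  inc_idx <- sort(with_seed(mix_seed(seed, 31L), sample.int(n, n_inc)))
  test_idx <- setdiff(seq_len(n), inc_idx)
  structure(list(inc = subset_windows(target, inc_idx),
                 test = subset_windows(target, test_idx),
                 inc_idx = inc_idx, test_idx = test_idx,
                 n_inc = n_inc, seed = as.integer(seed)),
            class = "incremental_split")
}

#' Temperature rescaling of probability rows
#'
#' Raises each probability to the power `1/T` and renormalizes per row;
#' `T = 1` is the identity and the uniform row is a fixed point for any
#' `T`.
#'
#' @param p Probability vector or matrix (rows are distributions).
#' @param T Temperature, `> 0`.
#' @return Rescaled probabilities with the same shape.
#' @export
temperature_rescale <- function(p, T) {
  stop_if_not(T > 0, "temperature must be > 0")
  vec <- is.null(dim(p))
  if (vec) p <- matrix(p, nrow = 1)
  stop_if_not(all(p >= 0), "probabilities must be nonnegative")
  q <- p^(1 / T)
  z <- rowSums(q)
  stop_if_not(all(z > 0), "a probability row sums to zero")
  out <- q / z
  if (vec) out <- drop(out)
  out
}

#' Learning-without-Forgetting loss
#'
#' `total = L_new + lambda * L_old`, where `L_new` is the mean
#' cross-entropy of the student probabilities against the true labels and
#' `L_old` is the mean cross-entropy between the temperature-rescaled
#' teacher and student rows (the distillation term).
#'
#' @param y_n Student probability rows (n x K).
#' @param y_o Teacher probability rows (n x K).
#' @param y_true Integer labels in `1..K`.
#' @param lwf A [lwf_config()].
#' @param eps Clamp inside logarithms.
#' @return A list with `total`, `new` and `old`; `total == new +
#'   lambda * old` exactly.
#' @export
lwf_loss <- function(y_n, y_o, y_true, lwf = lwf_config(), eps = 1e-12) {
  stopifnot(all(dim(y_n) == dim(y_o)), nrow(y_n) == length(y_true))
  l_new <- cross_entropy(y_n, y_true, eps)
  q <- temperature_rescale(y_o, lwf$temperature)
  s <- temperature_rescale(y_n, lwf$temperature)
  l_old <- -mean(rowSums(q * log(pmax(s, eps))))
  list(total = l_new + lwf$lambda_relax * l_old, new = l_new, old = l_old)
}

# Shared adaptation loop. If teacher_probs is NULL the distillation term is
# skipped entirely (plain fine-tuning); otherwise the gradient through the
# student logits is (p - y)/B + lambda/(T B) * (s - q), with s and q the
# temperature-rescaled student and teacher rows.
.adapt_loop <- function(student, split, tc, lambda, temperature,
                        teacher_probs) {
  cfg <- student$config
  inc <- split$inc
  n <- dim(inc$X)[1]
  stop_if_not(n >= 1, "empty incremental set")
  xfull <- input_array(inc$X)
  bs <- min(tc$batch_size, n)
  hist <- matrix(0, tc$incremental_epochs, 3,
                 dimnames = list(NULL, c("total", "new", "old")))
  student <- with_seed(mix_seed(tc$seed, 333L), {
    st <- adam_init(student$params)
    for (ep in seq_len(tc$incremental_epochs)) {
      idx <- sample.int(n)
      ep_tot <- ep_new <- ep_old <- 0
      for (start in seq(1L, n, by = bs)) {
        bi <- idx[start:min(start + bs - 1L, n)]
        B <- length(bi)
        xb <- xfull[, , , bi, drop = FALSE]
        yb <- inc$labels[bi]
        fw <- tscl_forward(student, xb, training = TRUE)
        student$params <- fw$params
        p <- t(fw$probs)                      # K x B
        onehot <- matrix(0, cfg$n_classes, B)
        onehot[cbind(yb, seq_len(B))] <- 1
        dlogits <- (p - onehot) / B
        l_new <- cross_entropy(fw$probs, yb)
        l_old <- 0
        if (!is.null(teacher_probs)) {
          q <- t(temperature_rescale(teacher_probs[bi, , drop = FALSE],
                                     temperature))
          s <- t(temperature_rescale(fw$probs, temperature))
          dlogits <- dlogits + lambda / (temperature * B) * (s - q)
          l_old <- -mean(colSums(q * log(pmax(s, 1e-12))))
        }
        grads <- tscl_backward(student, fw$cache, dlogits)
        ad <- adam_step(student$params, grads, st, lr = tc$learning_rate)
        student$params <- ad$params
        st <- ad$state
        ep_new <- ep_new + l_new * B
        ep_old <- ep_old + l_old * B
        ep_tot <- ep_tot + (l_new + lambda * l_old) * B
      }
      hist[ep, ] <- c(ep_tot, ep_new, ep_old) / n
    }
    student
  })
  # normalization statistics re-estimated on the adaptation windows (the
  # only target-domain data available to the student)
  student <- calibrate_bn(student, inc$X)
  attr(student, "history") <- as.data.frame(cbind(
    epoch = seq_len(tc$incremental_epochs), hist))
  student
}

#' Adapt the student with Learning without Forgetting
#'
#' Runs `incremental_epochs` of Adam on the LwF loss over the incremental
#' subset. The frozen teacher supplies eval-mode soft targets once; its
#' parameters are never touched.
#'
#' @param pair A [init_student()] teacher/student pair.
#' @param split A [select_incremental()] split of the target subject.
#' @param tc A [train_config()].
#' @return The adapted student `tscl_model` with a per-epoch loss
#'   `history` attribute (columns `total`, `new`, `old`).
#' @export
finetune_lwf <- function(pair, split, tc = train_config()) {
  stopifnot(inherits(pair, "teacher_student"),
            inherits(split, "incremental_split"))
  teacher_probs <- tscl_forward(pair$teacher, split$inc$X,
                                training = FALSE)$probs
  .adapt_loop(pair$student, split, tc, pair$lwf$lambda_relax,
              pair$lwf$temperature, teacher_probs)
}

#' Plain fine-tuning (the "without LwF" arm)
#'
#' Identical loop to [finetune_lwf()] with the distillation term removed;
#' with `lambda_relax = 0` the two produce bit-identical trajectories
#' under the same seed.
#'
#' @inheritParams finetune_lwf
#' @return The fine-tuned student model with a `history` attribute.
#' @export
finetune_plain <- function(pair, split, tc = train_config()) {
  stopifnot(inherits(pair, "teacher_student"),
            inherits(split, "incremental_split"))
  .adapt_loop(pair$student, split, tc, 0, pair$lwf$temperature, NULL)
}
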