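test_that("temperature rescaling matches direct arithmetic and its fixed points", {
  # sqrt(0.9)/(sqrt(0.9) + sqrt(0.1)) = 3/4 exactly
  expect_equal(temperature_rescale(c(0.9, 0.1), 2), c(0.75, 0.25))
  expect_equal(temperature_rescale(c(0.5, 0.5), 7), c(0.5, 0.5))
  expect_equal(temperature_rescale(c(0.9, 0.1), 1), c(0.9, 0.1))
  m <- matrix(c(0.9, 0.2, 0.1, 0.8), 2)
  r <- temperature_rescale(m, 2)
  expect_equal(rowSums(r), c(1, 1))
  expect_equal(r[1, ], c(0.75, 0.25))
  expect_error(temperature_rescale(c(0, 0), 2), "zero")
  expect_error(temperature_rescale(c(0.5, 0.5), 0), "temperature")
})

test_that("the LwF loss reproduces worked values and the Gibbs inequality", {
  # perfect one-hot student, lambda 0 -> zero loss
  y_n <- matrix(c(1, 0, 0, 1), 2, byrow = TRUE)
  l <- lwf_loss(y_n, y_n, c(1L, 2L), lwf_config(lambda_relax = 0))
  expect_equal(l$total, 0, tolerance = 1e-9)

  # uniform teacher and student over 2 classes: total = 1.1 * ln 2
  u <- matrix(0.5, 3, 2)
  l2 <- lwf_loss(u, u, c(1L, 2L, 1L), lwf_config(lambda_relax = 0.1, temperature = 2))
  expect_equal(l2$new, log(2))
  expect_equal(l2$old, log(2))
  expect_equal(l2$total, 1.1 * log(2), tolerance = 1e-12)

  # decomposition holds exactly for random rows
  set.seed(5)
  a <- matrix(stats::runif(8), 4); a <- a / rowSums(a)
  b <- matrix(stats::runif(8), 4); b <- b / rowSums(b)
  lw <- lwf_config(lambda_relax = 0.37, temperature = 3)
  l3 <- lwf_loss(a, b, c(1L, 2L, 1L, 2L), lw)
  expect_equal(l3$total, l3$new + 0.37 * l3$old, tolerance = 1e-10)

  # Gibbs: distillation term >= entropy of the rescaled teacher row, with
  # equality when student equals teacher
  q <- temperature_rescale(b, 3)
  entropy <- -mean(rowSums(q * log(q)))
  expect_gte(l3$old, entropy - 1e-12)
  l4 <- lwf_loss(b, b, c(1L, 2L, 1L, 2L), lw)
  expect_equal(l4$old, entropy, tolerance = 1e-12)
})

test_that("incremental selection pins the ceiling rule and is reproducible", {
  fake_ds <- function(n) windowed_dataset(
    array(0, c(n, 4, 2)), rep(5, n), rep(5, n), rep(1L, n), rep(0L, n),
    1, 100, label_scheme("binary_valence"), c("FP1", "FP2", "F3", "F4"))
  s1 <- select_incremental(fake_ds(2400), 0.02, seed = 42)
  expect_equal(s1$n_inc, 48)
  expect_equal(length(s1$test_idx), 2352)
  s2 <- select_incremental(fake_ds(840), 0.02, seed = 42)
  expect_equal(s2$n_inc, 17)

  s3 <- select_incremental(fake_ds(2400), 0.02, seed = 42)
  expect_identical(s1$inc_idx, s3$inc_idx)
  s4 <- select_incremental(fake_ds(2400), 0.02, seed = 43)
  expect_false(identical(s1$inc_idx, s4$inc_idx))
  expect_length(intersect(s1$inc_idx, s1$test_idx), 0)
  expect_setequal(c(s1$inc_idx, s1$test_idx), seq_len(2400))

  expect_error(select_incremental(fake_ds(10), 0.999), "no training or no test")
  expect_error(select_incremental(fake_ds(10), 0), "fraction")
})

test_that("pretraining is seed-deterministic and rejects single-class sources", {
  ds <- tiny_ds()
  src <- eeglwf:::subset_windows(ds, ds$subject_ids == 1)
  cfg <- tiny_cfg()
  tc <- train_config(batch_size = 16, pretrain_epochs = 1, seed = 42)
  m1 <- pretrain(src, cfg, tc)
  m2 <- pretrain(src, cfg, tc)
  expect_identical(m1$params, m2$params)
  h <- attr(m1, "history")
  expect_equal(nrow(h), 1)
  expect_true(all(is.finite(h$loss)))

  mono <- eeglwf:::subset_windows(src, src$labels == 1L)
  expect_error(pretrain(mono, cfg, tc), "two classes")
})

test_that("student initialization copies the feature extractor and redraws the head", {
  teacher <- tiny_teacher()
  pair <- init_student(teacher, seed = 7)
  expect_identical(pair$student$params$temporal, teacher$params$temporal)
  expect_identical(pair$student$params$spatial, teacher$params$spatial)
  expect_identical(pair$student$params$fusion, teacher$params$fusion)
  expect_false(identical(pair$student$params$classifier$fc1$W,
                         teacher$params$classifier$fc1$W))
  pair2 <- init_student(teacher, seed = 7)
  expect_identical(pair$student$params, pair2$student$params)
})

test_that("adaptation leaves the teacher bit-identical and is reproducible", {
  teacher <- tiny_teacher()
  ds <- tiny_ds()
  tgt <- eeglwf:::subset_windows(ds, ds$subject_ids == 0)
  tc <- train_config(batch_size = 16, pretrain_epochs = 2,
                     incremental_epochs = 3, seed = 42)
  pair <- init_student(teacher, seed = 42)
  split <- select_incremental(tgt, 0.25, seed = 42)
  before <- pair$teacher$params
  s1 <- finetune_lwf(pair, split, tc)
  expect_identical(pair$teacher$params, before)
  s2 <- finetune_lwf(pair, split, tc)
  expect_identical(s1$params, s2$params)
  h <- attr(s1, "history")
  expect_equal(colnames(h), c("epoch", "total", "new", "old"))
  expect_true(all(is.finite(h$total)))
})

test_that("a zero relaxation weight reduces LwF adaptation to plain fine-tuning", {
  teacher <- tiny_teacher()
  ds <- tiny_ds()
  tgt <- eeglwf:::subset_windows(ds, ds$subject_ids == 0)
  tc <- train_config(batch_size = 16, incremental_epochs = 3, seed = 42)
  pair0 <- init_student(teacher, seed = 42,
                        lwf = lwf_config(lambda_relax = 0))
  split <- select_incremental(tgt, 0.25, seed = 42)
  s_lwf0 <- finetune_lwf(pair0, split, tc)
  s_plain <- finetune_plain(pair0, split, tc)
  expect_identical(s_lwf0$params, s_plain$params)

  # and a nonzero weight produces a genuinely different trajectory
  pair1 <- init_student(teacher, seed = 42,
                        lwf = lwf_config(lambda_relax = 0.5))
  s_lwf1 <- finetune_lwf(pair1, split, tc)
  expect_false(identical(s_lwf1$params, s_plain$params))
})
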