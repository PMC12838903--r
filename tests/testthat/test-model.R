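test_that("the multi-scale kernel rule reproduces the canonical widths", {
  expect_equal(temporal_kernel_widths(128, 0.5, 3), c(64L, 32L, 16L))
  expect_equal(temporal_kernel_widths(100, 0.5, 3), c(50L, 25L, 12L))
  expect_equal(temporal_kernel_widths(2, 0.5, 1), 1L)
  expect_error(temporal_kernel_widths(4, 0.5, 3), "width below 1")
})

test_that("analytic shape functions match executed forward traces on a config grid", {
  for (cc in c(2L, 4L)) for (ff in c(64L, 100L, 128L)) {
    cfg <- model_config(c = cc, f = ff)
    sh <- model_shapes(cfg)
    m <- model_init(cfg, seed = 1)
    X <- array(stats::runif(3 * cc * ff), c(3, cc, ff))
    fw <- tscl_forward(m, X)
    expect_equal(fw$stages$temporal[1:3], unname(sh$temporal))
    expect_equal(fw$stages$spatial[1:3], unname(sh$spatial))
    expect_equal(fw$stages$dcl_in, sh$dcl_in)
    expect_equal(ncol(fw$probs), cfg$n_classes)
  }
  # the canonical DEAP-like geometry: temporal length 34 = 8 + 12 + 14,
  # spatial 15 x 4 x 17, classifier input 128 * 13
  sh <- model_shapes(model_config(c = 4, f = 128))
  expect_equal(sh$branch_len, c(8L, 12L, 14L))
  expect_equal(sh$temporal_len, 34L)
  expect_equal(unname(sh$spatial), c(15, 4, 17))
  expect_equal(sh$fusion$lens, c(120, 59, 28, 13))
  expect_equal(sh$dcl_in, 1664L)
})

test_that("predictions are probability rows, deterministic in eval mode, batch-equivariant", {
  cfg <- slim_cfg()
  m <- model_init(cfg, seed = 4)
  set.seed(8)
  X <- array(stats::runif(6 * 4 * 100), c(6, 4, 100))
  p1 <- tscl_forward(m, X)$probs
  p2 <- tscl_forward(m, X)$probs
  expect_equal(dim(p1), c(6, 2))
  expect_equal(rowSums(p1), rep(1, 6), tolerance = 1e-6)
  expect_true(all(p1 >= 0))
  expect_identical(p1, p2)

  perm <- c(3, 1, 6, 2, 5, 4)
  p3 <- tscl_forward(m, X[perm, , , drop = FALSE])$probs
  expect_equal(p3, p1[perm, ], tolerance = 1e-12)
})

test_that("a zeroed classifier output layer yields uniform class probabilities", {
  cfg <- slim_cfg()
  m <- model_init(cfg, seed = 4)
  m$params$classifier$fc3$W[] <- 0
  m$params$classifier$fc3$b[] <- 0
  X <- array(stats::runif(3 * 4 * 100), c(3, 4, 100))
  expect_equal(tscl_forward(m, X)$probs,
               matrix(0.5, 3, 2), tolerance = 1e-12)
})

test_that("analytic gradients agree with central finite differences at every stage", {
  cfg <- slim_cfg()
  m <- model_init(cfg, seed = 2)
  set.seed(3)
  X <- array(stats::rnorm(3 * 4 * 100), c(3, 4, 100))
  y <- c(1L, 2L, 1L)
  loss_fn <- function(params) {
    m2 <- m
    m2$params <- params
    fw <- tscl_forward(m2, X, training = TRUE)
    -mean(log(fw$probs[cbind(1:3, y)]))
  }
  fw <- tscl_forward(m, X, training = TRUE)
  onehot <- matrix(0, 2, 3); onehot[cbind(y, 1:3)] <- 1
  dlogits <- (t(fw$probs) - onehot) / 3
  m$params <- fw$params
  g <- eeglwf:::tscl_backward(m, fw$cache, dlogits)
  setl <- function(pp, path, val) {
    if (length(path) == 1) pp[[path[[1]]]] <- val
    else pp[[path[[1]]]] <- setl(pp[[path[[1]]]], path[-1], val)
    pp
  }
  paths <- list(list("temporal", "branch1", "W"),
                list("temporal", "bn", "gamma"),
                list("spatial", "local", "W"),
                list("spatial", "global", "b"),
                list("fusion", "b1", "dw", "W"),
                list("fusion", "b3", "pw", "W"),
                list("classifier", "fc1", "W"),
                list("classifier", "bn2", "beta"))
  rel_errs <- c()
  set.seed(11)
  for (path in paths) {
    arr <- Reduce(`[[`, path, m$params)
    ga <- Reduce(`[[`, path, g)
    for (i in sample(length(arr), min(3, length(arr)))) {
      eps <- 1e-5
      up <- arr; up[i] <- arr[i] + eps
      dn <- arr; dn[i] <- arr[i] - eps
      num <- (loss_fn(setl(m$params, path, up)) -
                loss_fn(setl(m$params, path, dn))) / (2 * eps)
      rel_errs <- c(rel_errs, abs(ga[i] - num) / max(1e-6, abs(num)))
    }
  }
  # a few entries sit near rectifier/pool kinks where central differences
  # are inexact; the bulk must agree tightly
  expect_lt(stats::median(rel_errs), 1e-6)
  expect_lt(max(rel_errs), 1e-2)
})

test_that("ablation variants recompute shapes as specified", {
  cfg <- model_config(c = 4, f = 128)
  v_t <- make_variant(cfg, "temporal")
  expect_equal(v_t$n_temporal_scales, 1L)
  # single largest kernel: floor((128 - 64 + 1)/8) = 8 time steps
  expect_equal(model_shapes(v_t)$temporal_len, 8L)

  v_s <- make_variant(cfg, "spatial")
  expect_equal(sum(model_shapes(v_s)$spatial_rows), 1L)

  v_f <- make_variant(cfg, "fusion")
  expect_equal(model_shapes(v_f)$dcl_in, 15L * 4L * 17L)  # 1020
  m <- model_init(v_f, seed = 1)
  X <- array(stats::runif(2 * 4 * 128), c(2, 4, 128))
  expect_equal(tscl_forward(m, X)$stages$dcl_in, 1020L)

  expect_identical(make_variant(cfg, "none"), cfg)
  expect_error(make_variant(cfg, "bogus"))
})

test_that("checkpoints round-trip bit-exactly with their manifest", {
  cfg <- slim_cfg()
  m <- model_init(cfg, seed = 9)
  dir <- withr::local_tempdir()
  save_model(m, dir, phase = "pretrained")
  m2 <- load_model(dir)
  expect_identical(m2$params, m$params)
  expect_equal(attr(m2, "phase"), "pretrained")
  expect_equal(m2$config$f, cfg$f)
  X <- array(stats::runif(2 * 4 * 100), c(2, 4, 100))
  expect_identical(tscl_forward(m, X)$probs, tscl_forward(m2, X)$probs)
})
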