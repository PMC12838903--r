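#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif approx fft sd t.test var
#' @importFrom utils head tail
#' @importFrom Rcpp evalCpp
#' @useDynLib eeglwf, .registration = TRUE
NULL

# Deterministic sub-seed derivation. Mixes a base seed with up to two index
# arguments so that per-subject / per-trial streams are independent and
# reproducible, while staying inside the 32-bit integer range.
mix_seed <- function(seed, a = 0L, b = 0L) {
  s <- (as.double(seed) %% 2147483647) * 48271 + as.double(a) * 1000003 +
    as.double(b) * 10007 + 12345
  as.integer(s %% 2147483629)
}

# Run expr with a temporary RNG state seeded from `seed`.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

stop_if_not <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_rating_range <- function(x, what = "rating") {
  stop_if_not(is.numeric(x) && all(is.finite(x)) && all(x >= 1) && all(x <= 9),
              "%s must lie in [1, 9]", what)
  invisible(x)
}
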