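#' @importFrom rlang abort warn %||% .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom stats cor predict quantile rnorm runif sd setNames var pnorm median
#' @importFrom utils head tail
NULL

# polynomial rolling hash over non-negative integer sequences, exact in doubles
# (values stay below 2^53); used for fingerprint bit assignment so results are
# platform-independent
hash_ints <- function(x, mod = 2147483647) {
  h <- 17
  for (v in x) h <- (h * 1000003 + (v %% mod)) %% mod
  h
}

hash_string <- function(s, mod = 2147483647) {
  hash_ints(utf8ToInt(s), mod)
}

# round half away from zero, the convention of the screening literature's
# reported tables (base round() is banker's rounding)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# all seeded randomness goes through this so the caller's RNG state is never
# disturbed
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

# derive a stage seed from a root seed; kept below 2^31
derive_seed <- function(seed, stage) {
  as.integer((as.double(seed) * 48271 + hash_string(stage, 2147483423L)) %% 2147483423)
}

check_fraction <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must be in [0, 1].", name))
  }
  invisible(x)
}
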