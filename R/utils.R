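# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Set the RNG state from an optional seed
#'
#' Used by all stochastic entry points: if `seed` is `NULL` the current global
#' RNG stream is used unchanged, otherwise the stream is seeded so repeated
#' calls reproduce the same draws.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    set.seed(as.integer(seed))
  }
  expr
}

#' Derive a per-unit seed from a master seed, staying inside 32-bit range
#' @noRd
derive_seed <- function(master_seed, index) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L)
  as.integer((as.double(master_seed) + 104729 * as.double(index)) %% 2147483629)
}

stop_input <- function(...) stop(..., call. = FALSE)

assert_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max)
    stop_input(sprintf("`%s` must be a single number in [%s, %s]", name, min, max))
  invisible(x)
}
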