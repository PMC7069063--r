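# Internal helpers: error conditions, seed handling, small validators.

condition_stop <- function(subclass, msg, ...) {
  stop(structure(
    list(message = sprintf(msg, ...), call = sys.call(-2)),
    class = c(subclass, "asntopo_error", "error", "condition")
  ))
}

stop_param <- function(msg, ...) {
  condition_stop("asntopo_parameter_error", msg, ...)
}

stop_format <- function(msg, ...) {
  condition_stop("asntopo_format_error", msg, ...)
}

stop_metric <- function(msg, ...) {
  condition_stop("asntopo_metric_error", msg, ...)
}

assert_scalar_num <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_param("`%s` must be a single finite number", name)
  }
  invisible(x)
}

#' Derive a child seed from a master seed and a counter
#'
#' Deterministic counter-based derivation so that every network in an
#' ensemble has its own reproducible seed while the whole ensemble is
#' reproducible from one master seed. The result always fits in a 32-bit
#' integer.
#'
#' @param master integer master seed.
#' @param counter non-negative integer index (0, 1, 2, ...).
#' @return An integer seed in `[0, 2147483628]`.
#' @export
derive_seed <- function(master, counter) {
  assert_scalar_num(master, "master")
  assert_scalar_num(counter, "counter")
  p <- 2147483629 # prime < 2^31
  as.integer((((as.numeric(master) %% p) * 48271) %% p + 12820163 * counter) %% p)
}

# Run `code` under a temporary RNG state when `seed` is given; leave the
# caller's RNG untouched either way.
local_seed_eval <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

clamp01 <- function(x) pmin(1, pmax(0, x))
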