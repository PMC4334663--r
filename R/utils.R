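# Internal helpers: argument checking and seeded evaluation.

stop_config <- function(...) abort(paste0(...), class = "megmyelin_config_error")
stop_geometry <- function(...) abort(paste0(...), class = "megmyelin_geometry_error")
stop_input <- function(...) abort(paste0(...), class = "megmyelin_input_error")
stop_numeric <- function(...) abort(paste0(...), class = "megmyelin_numeric_error")

check_scalar <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x))) {
    stop_config(name, " must be a single finite number")
  }
  invisible(x)
}

check_vec3 <- function(x, name) {
  if (!is.numeric(x) || length(x) != 3L || any(!is.finite(x))) {
    stop_config(name, " must be a finite numeric 3-vector")
  }
  invisible(as.numeric(x))
}

# Evaluate `expr` under a deterministic RNG state without disturbing the
# caller's .Random.seed. All stochastic operations in the package go through
# this, keyed by an explicit integer seed.
with_seed_ <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop_config("seed must be a single integer")
  }
  withr::with_seed(as.integer(seed), expr)
}

# Deterministic sub-seed derivation (kept well below 2^31).
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(offset) %% 1009L
}

vnorm <- function(x) sqrt(sum(x^2))

`%||%` <- function(a, b) if (is.null(a)) b else a
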