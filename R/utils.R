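#' @keywords internal
"_PACKAGE"

# Validation helper: stop with the offending argument named, so callers can
# tell which config field was rejected.
check_that <- function(ok, field, msg) {
  if (!isTRUE(ok)) {
    stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
  }
  invisible(TRUE)
}

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x >= 0 && x == floor(x)
}

is_fraction <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x >= 0 && x <= 1
}

# Deterministic sub-stream seeds: each unit (feature column, CV fold,
# permutation, pipeline stage) draws from its own seed derived from the
# master seed, so enlarging one dimension never perturbs another.
# Kept strictly below 2^31 - 1 (R integers are 32-bit).
substream_seed <- function(seed, index) {
  (as.numeric(seed) * 48271 + 7919 * as.numeric(index)) %% 2147483629
}

# Evaluate `expr` under a temporary RNG state; restores the caller's state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483629))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
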