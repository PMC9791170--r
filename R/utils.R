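# Internal helpers: seeded RNG scoping and structured conditions.

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so library calls never perturb user randomness.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop_detchar("`seed` must be a single finite integer", "bad_seed")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Error with a subclass so callers can condition on failure modes
# (e.g. "detchar_saturated", "detchar_band_unavailable").
stop_detchar <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(paste0("detchar_", class), "detchar_error", "error", "condition"),
    list(message = msg, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  ))
}

warn_detchar <- function(msg, class) {
  warning(structure(
    class = c(paste0("detchar_", class), "detchar_warning", "warning", "condition"),
    list(message = msg, call = NULL)
  ))
}

check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_detchar(sprintf("`%s` must be a single finite number", name), "bad_arg")
  }
  if (positive && x <= 0) {
    stop_detchar(sprintf("`%s` must be > 0", name), "bad_arg")
  }
  if (nonneg && x < 0) {
    stop_detchar(sprintf("`%s` must be >= 0", name), "bad_arg")
  }
  invisible(x)
}
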