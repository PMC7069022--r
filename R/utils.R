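# Error helpers: every user-facing failure is classed so callers (and the
# test-suite) can distinguish malformed files, bad data and bad configuration.

abort_format <- function(msg, ...) {
  rlang::abort(msg, class = "mycnfunnel_format_error", ...)
}

abort_data <- function(msg, ...) {
  rlang::abort(msg, class = "mycnfunnel_data_error", ...)
}

abort_config <- function(msg, ...) {
  rlang::abort(msg, class = "mycnfunnel_config_error", ...)
}

# Run an expression under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort_config("`seed` must be a single integer.")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

check_fraction <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
    abort_config(sprintf("`%s` must be a single number in [%g, %g].", name, lo, hi))
  }
  invisible(x)
}
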