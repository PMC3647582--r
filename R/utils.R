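## Shared argument validation. Errors name the offending argument so
## failures in analysis scripts point at the input, not the internals.

check_fraction <- function(x, name, open_lower = TRUE, closed_upper = FALSE) {
  if (!is.numeric(x) || anyNA(x))
    stop(name, " must be numeric and non-missing", call. = FALSE)
  lo_bad <- if (open_lower) x <= 0 else x < 0
  hi_bad <- if (closed_upper) x > 1 else x >= 1
  if (any(lo_bad | hi_bad)) {
    rng <- paste0(if (open_lower) "(" else "[", "0, 1",
                  if (closed_upper) "]" else ")")
    stop(name, " must lie in ", rng, call. = FALSE)
  }
  invisible(x)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x <= 0))
    stop(name, " must be positive", call. = FALSE)
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      abs(x - round(x)) > 1e-8 || x < min)
    stop(name, " must be a single integer >= ", min, call. = FALSE)
  invisible(as.integer(round(x)))
}

## Evaluate `expr` with a temporary RNG state seeded by `seed`, restoring
## the caller's .Random.seed afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
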