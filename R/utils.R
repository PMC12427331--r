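# Internal helpers shared across modules.

# Round half away from zero (R's round() is banker's rounding; exact-count
# arithmetic for masking and imputation needs deterministic half-up).
round_half_up <- function(x) floor(x + 0.5)

# Derive a child seed from a user seed and a stream label, staying within
# 32-bit integer range so set.seed() accepts it.
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  s <- 0
  for (p in parts) s <- (s * 69069 + as.double(p) + 1) %% 2147483647
  as.integer(s)
}

with_seed <- function(seed, code) {
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
  })
  set.seed(seed)
  force(code)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         integerish = FALSE, closed_lower = TRUE,
                         closed_upper = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number", name))
  }
  lo_ok <- if (closed_lower) x >= lower else x > lower
  hi_ok <- if (closed_upper) x <= upper else x < upper
  if (!lo_ok || !hi_ok) {
    abort(sprintf("`%s` = %g is outside its allowed range", name, x))
  }
  if (integerish && x != floor(x)) {
    abort(sprintf("`%s` must be an integer", name))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
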