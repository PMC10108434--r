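# internal helpers: seeded RNG without touching global state, input checks

# Evaluate `code` under a private RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All generators route their randomness here
# so identical (seed, parameters) give byte-identical output regardless of the
# surrounding session.
with_local_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    abort(sprintf(
      "`%s` must be in %s%g, %g%s (got %g).", name,
      if (strict_lower) "(" else "[", lower, upper,
      if (strict_upper) ")" else "]", x
    ))
  }
  invisible(x)
}

check_numeric_vec <- function(x, name, lower = -Inf, min_len = 1,
                              strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) < min_len || anyNA(x) || any(!is.finite(x))) {
    abort(sprintf("`%s` must be a finite numeric vector of length >= %d.",
                  name, min_len))
  }
  bad <- if (strict_lower) any(x <= lower) else any(x < lower)
  if (bad) {
    abort(sprintf("`%s` must be %s %g.", name,
                  if (strict_lower) "strictly greater than" else "at least", lower))
  }
  invisible(x)
}

# 95% normal CI half-width of the mean
ci95_halfwidth <- function(x) {
  n <- length(x)
  if (n < 2) return(NA_real_)
  qnorm(0.975) * stats::sd(x) / sqrt(n)
}
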