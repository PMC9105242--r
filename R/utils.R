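# Internal numeric helpers shared across modules.

# Trapezoidal integral of y(x) over the full grid.
trapz <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (y[-length(y)] + y[-1L]) / 2)
}

# Cumulative trapezoidal integral, same length as x (starts at 0).
cumtrapz <- function(x, y) {
  if (length(x) < 2L) return(rep(0, length(x)))
  c(0, cumsum(diff(x) * (y[-length(y)] + y[-1L]) / 2))
}

# Centered moving average with window k (odd); the window shrinks near the
# edges so the output has the same length and no phase shift.
moving_average <- function(x, k = 5L) {
  n <- length(x)
  if (k <= 1L || n < 3L) return(x)
  half <- k %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    out[i] <- mean(x[lo:hi])
  }
  out
}

# Evaluate expr with a locally seeded RNG, restoring the caller's RNG state.
# All synthetic generators route their randomness through this so they are
# pure functions of (params, seed).
with_seed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) stop("a seed is mandatory", call. = FALSE)
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
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  }
  invisible(x)
}

# greatest common divisor (non-negative integers)
gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b != 0) {
    t <- b
    b <- a %% b
    a <- t
  }
  a
}
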