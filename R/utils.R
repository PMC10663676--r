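# Small internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. `seed = NULL` leaves the current stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Round half away from zero at `digits` decimals (base round() uses
# round-half-even, which would print 2.3/7.3 = 0.315 as 0.31, not the 0.32
# convention used for reported stoichiometry ratios).
round_away <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Trapezoidal integral of y over (possibly non-uniform) x.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

# Centered moving average with window w (odd); edges use shrunken windows.
moving_average <- function(y, w) {
  if (w <= 1) return(y)
  n <- length(y)
  half <- (w - 1) %/% 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- max(1, i - half):min(n, i + half)
    out[i] <- mean(y[j])
  }
  out
}

# Moving average whose edge windows use a local linear fit instead of a
# shrunken mean, so linear trends are reproduced exactly everywhere (a
# plain one-sided mean biases a sloped baseline at the trace ends).
moving_average_linear <- function(x, y, w) {
  if (w <= 1) return(y)
  n <- length(y)
  half <- (w - 1) %/% 2
  out <- moving_average(y, w)
  fit_at <- function(i, j) {
    xb <- mean(x[j]); yb <- mean(y[j])
    vx <- sum((x[j] - xb)^2)
    b <- if (vx > 0) sum((x[j] - xb) * (y[j] - yb)) / vx else 0
    yb + b * (x[i] - xb)
  }
  for (i in seq_len(min(half, n))) out[i] <- fit_at(i, 1:min(n, i + half))
  for (i in seq(max(1, n - half + 1), n)) {
    out[i] <- fit_at(i, max(1, i - half):n)
  }
  out
}

stop_if_not_number <- function(x, what, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", what), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be > 0", what), call. = FALSE)
  }
  invisible(x)
}
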