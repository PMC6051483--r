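# Internal helpers shared across modules.

## Evaluate `expr` under a fixed RNG seed without disturbing the caller's
## RNG state. All stochastic entry points funnel through this.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Acausal FIR filtering: y(t) = sum_a coef[a] * x(t - lags[a]), with x
## zero-extended outside its support. `lags` are integer sample shifts
## (negative = future samples).
acausalFilter <- function(x, coef, lags) {
  stopifnot(length(coef) == length(lags))
  n <- length(x)
  y <- numeric(n)
  for (a in seq_along(lags)) {
    k <- lags[a]
    if (coef[a] == 0) next
    if (k >= 0) {
      src <- seq_len(n - k)
      y[src + k] <- y[src + k] + coef[a] * x[src]
    } else {
      src <- seq.int(1L - k, n)
      y[src + k] <- y[src + k] + coef[a] * x[src]
    }
  }
  y
}

## Shift a vector by k samples (positive = delay), zero filling.
shiftVec <- function(x, k) {
  n <- length(x)
  y <- numeric(n)
  if (k >= 0) y[seq.int(k + 1L, n)] <- x[seq_len(n - k)]
  else y[seq_len(n + k)] <- x[seq.int(1L - k, n)]
  y
}

## Wrap angles into (-pi, pi].
wrapAngle <- function(a) {
  w <- (a + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

## Circular mean of angles.
circularMean <- function(a) atan2(mean(sin(a)), mean(cos(a)))

## Pearson correlation that tolerates zero variance (returns NA).
safeCor <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

## Assert a scalar in a range, with a readable error.
checkScalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (x < lower || x > upper)
    stop(sprintf("'%s' must be in [%g, %g]", name, lower, upper),
         call. = FALSE)
  invisible(x)
}
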