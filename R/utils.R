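## internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

## scalar validators; name is used in the error message
check_number <- function(x, name, min = -Inf, max = Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
  if (strict_min && x <= min) stopf("'%s' must be > %g", name, min)
  if (!strict_min && x < min) stopf("'%s' must be >= %g", name, min)
  if (x > max) stopf("'%s' must be <= %g", name, max)
  invisible(x)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stopf("'%s' must be TRUE or FALSE", name)
  invisible(x)
}

## Evaluate `expr` under a temporary RNG state seeded with `seed`,
## restoring the caller's RNG afterwards. All stochastic steps in the
## package go through this, which is what makes seeded runs reproducible
## without clobbering the user's random stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

## Derive a stream of child seeds from a parent seed (kept < 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

## OLS slope + r^2 on (t, y); slope per unit of t
ols_line <- function(t, y) {
  tb <- mean(t); yb <- mean(y)
  sxx <- sum((t - tb)^2)
  if (sxx == 0) stopf("degenerate fit window: no spread in time")
  slope <- sum((t - tb) * (y - yb)) / sxx
  yhat <- yb + slope * (t - tb)
  sst <- sum((y - yb)^2)
  r2 <- if (sst == 0) 1 else 1 - sum((y - yhat)^2) / sst
  list(slope = slope, intercept = yb - slope * tb, r2 = max(0, min(1, r2)))
}
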