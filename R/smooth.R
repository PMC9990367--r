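## Temporal smoothing: centered moving average with shrinking edge windows.

#' Centered moving-average smoothing
#'
#' At each index the mean is taken over a window of `window` frames centered
#' on that index; near the edges the window shrinks symmetrically so that no
#' padding values are invented. `window = 1` is the identity. The defaults
#' used by the pipeline are 11 frames for lactate (Laconic) traces and 5
#' frames for glucose (FLII) traces.
#'
#' @param x Numeric vector (a ratio trace or per-pixel series).
#' @param window Odd window length, `1 <= window <= length(x)`.
#' @return Smoothed vector of the same length.
#' @export
#' @examples
#' temporal_smooth(c(0, 0, 0, 1, 0, 0, 0), 3)
temporal_smooth <- function(x, window) {
  if (!is.numeric(x) || length(x) < 1L) stopf("'x' must be a numeric vector")
  check_number(window, "window", min = 1)
  if (window %% 2 == 0) stopf("'window' must be odd")
  n <- length(x)
  if (window > n) stopf("'window' (%d) exceeds series length (%d)", window, n)
  if (window == 1) return(x)
  half <- (window - 1L) / 2L
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  k <- pmin(half, i - 1L, n - i)        # symmetric shrink at the edges
  (cs[i + k + 1L] - cs[i - k]) / (2L * k + 1L)
}
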