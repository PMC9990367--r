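## Masked ratiometric trace extraction.

#' Construct a ratio trace
#'
#' @param t Time base, s (uniform at 1/frame_rate).
#' @param r Ratio per frame (finite, > 0).
#' @param frame_rate Frames per second.
#' @param window Smoothing window used, frames.
#' @param metadata Provenance list (mask fraction, drift summary, protocol).
#' @return A `ratio_trace` data.frame with columns `t`, `ratio`.
#' @export
ratio_trace <- function(t, r, frame_rate, window = 1L, metadata = list()) {
  if (length(t) != length(r)) stopf("'t' and 'r' must have equal length")
  if (any(!is.finite(r)) || any(r <= 0)) stopf("ratios must be finite and > 0")
  structure(data.frame(t = t, ratio = r),
            class = c("ratio_trace", "data.frame"),
            frame_rate = frame_rate, window = window, metadata = metadata)
}

#' Extract the whole-frame ratio trace from a masked movie
#'
#' Per frame, the ratio is the mean numerator intensity over the mask divided
#' by the mean denominator intensity over the mask (ratio of means, which
#' suppresses noise amplification from dim pixels). Fill pixels marked
#' invalid by registration, and pixels with zero denominator, are excluded
#' from both means. The trace is then smoothed with [temporal_smooth()]
#' (sensor-appropriate default: 11 frames for lactate, 5 for glucose).
#'
#' @param movie A [movie_stack()].
#' @param mask A [build_mask()] result (or logical matrix).
#' @param window Odd smoothing window in frames.
#' @return A [ratio_trace()].
#' @export
extract_ratio_trace <- function(movie, mask, window = 11L) {
  if (!inherits(movie, "movie_stack")) stopf("'movie' must be a movie_stack")
  m <- if (inherits(mask, "tissue_mask")) mask$mask else mask
  if (!is.matrix(m) || !is.logical(m) ||
      !identical(dim(m), dim(movie$num)[2:3]))
    stopf("'mask' must be a logical matrix matching the frame shape")
  if (!any(m)) stopf("mask is empty")
  check_number(window, "window", min = 1)
  if (window %% 2 == 0) stopf("'window' must be odd")

  nt <- n_frames(movie)
  r <- numeric(nt)
  n_used <- integer(nt)
  for (f in seq_len(nt)) {
    sel <- m
    if (!is.null(movie$valid)) sel <- sel & movie$valid[f, , ]
    den <- movie$den[f, , ][sel]
    num <- movie$num[f, , ][sel]
    keep <- den > 0
    if (!any(keep))
      stopf("all masked denominator pixels are zero in frame %d", f)
    r[f] <- mean(num[keep]) / mean(den[keep])
    n_used[f] <- sum(keep)
  }
  t <- (seq_len(nt) - 1L) / movie$frame_rate
  md <- list(protocol = movie$metadata$protocol,
             sensor = movie$metadata$sensor,
             mask_fraction = if (inherits(mask, "tissue_mask")) mask$fraction else mean(m),
             n_masked_pixels = n_used)
  ratio_trace(t, temporal_smooth(r, window), movie$frame_rate,
              window = window, metadata = md)
}
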