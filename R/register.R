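## Drift registration by frequency-domain cross-correlation.

#' Estimate the xy offset between a frame and a reference
#'
#' Finds the integer shift `(dy, dx)` that maximizes the circular
#' cross-correlation of the (zero-mean) frame against the reference, computed
#' with 2-D FFTs. The returned offset is the shift that maps the reference
#' onto the frame; the score is the normalized correlation coefficient at the
#' peak. Ties are broken toward the smallest Euclidean offset, then row-major
#' order.
#'
#' @param frame,reference Numeric matrices of equal shape.
#' @param score_floor Peak-correlation value below which the result is
#'   flagged low-confidence.
#' @return List `dy`, `dx`, `score`, `low_confidence`.
#' @export
estimate_drift <- function(frame, reference, score_floor = 0.3) {
  if (!is.matrix(frame) || !is.matrix(reference) ||
      !identical(dim(frame), dim(reference)))
    stopf("'frame' and 'reference' must be matrices of equal shape")
  f0 <- frame - mean(frame)
  r0 <- reference - mean(reference)
  ssf <- sum(f0^2); ssr <- sum(r0^2)
  if (ssr == 0 || ssf == 0) stopf("no structure to register: constant image")

  ## cross-correlation of frame with reference over all circular shifts
  cc <- Re(fft(fft(f0) * Conj(fft(r0)), inverse = TRUE)) / length(f0)
  score_map <- cc / sqrt(ssf * ssr)
  pk <- max(score_map)

  h <- nrow(cc); w <- ncol(cc)
  idx <- which(score_map >= pk - 1e-12)
  dy <- (idx - 1L) %% h
  dx <- (idx - 1L) %/% h
  dy <- ifelse(dy > h / 2, dy - h, dy)   # wrap to signed offsets
  dx <- ifelse(dx > w / 2, dx - w, dx)
  ord <- order(dy^2 + dx^2, dy, dx)      # tie-break: smallest shift, row-major
  best <- ord[1]
  list(dy = as.integer(dy[best]), dx = as.integer(dx[best]),
       score = score_map[idx[best]],
       low_confidence = score_map[idx[best]] < score_floor)
}

#' Register a movie stack against a reference frame
#'
#' Offsets are estimated on the channel-sum image of each frame against the
#' channel-sum reference (first frame by default) and the same shift is
#' applied to both channels. Out-of-frame pixels exposed by the shift are
#' filled with the frame's background estimate (per-frame median) and marked
#' invalid, so later masked statistics exclude them.
#'
#' @param movie A [movie_stack()] with at least 2 frames.
#' @param reference `"first"` or `"mean"` (time-average) reference policy.
#' @param score_floor Passed to [estimate_drift()].
#' @return List with the registered `movie` (valid-pixel mask attached) and
#'   `drift` (data.frame `frame, dy, dx, score, low_confidence`).
#' @export
register_stack <- function(movie, reference = c("first", "mean"),
                           score_floor = 0.3) {
  if (!inherits(movie, "movie_stack")) stopf("'movie' must be a movie_stack")
  reference <- match.arg(reference)
  nt <- n_frames(movie)
  if (nt < 2L) stopf("registration undefined for a single-frame movie")

  sum_frame <- function(f) movie$num[f, , ] + movie$den[f, , ]
  ref <- if (reference == "first") sum_frame(1L) else
    apply(movie$num + movie$den, c(2, 3), mean)

  d <- dim(movie$num)
  num <- movie$num; den <- movie$den
  valid <- if (is.null(movie$valid)) array(TRUE, d) else movie$valid
  drift <- data.frame(frame = seq_len(nt), dy = 0L, dx = 0L,
                      score = 1, low_confidence = FALSE)

  for (f in seq_len(nt)) {
    est <- estimate_drift(sum_frame(f), ref, score_floor = score_floor)
    drift$dy[f] <- est$dy; drift$dx[f] <- est$dx
    drift$score[f] <- est$score; drift$low_confidence[f] <- est$low_confidence
    if (est$dy != 0 || est$dx != 0) {
      ## undo the drift: shift content back by -offset
      num[f, , ] <- shift_image(movie$num[f, , ], -est$dy, -est$dx,
                                fill = median(movie$num[f, , ]))
      den[f, , ] <- shift_image(movie$den[f, , ], -est$dy, -est$dx,
                                fill = median(movie$den[f, , ]))
      vmask <- shift_image(matrix(1, d[2], d[3]), -est$dy, -est$dx, fill = 0)
      valid[f, , ] <- valid[f, , ] & (vmask > 0)
    }
  }

  out <- movie_stack(num, den, movie$frame_rate, metadata = movie$metadata,
                     valid = valid)
  out$metadata$registered <- TRUE
  list(movie = out, drift = drift)
}
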