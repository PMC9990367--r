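## Rendering: concentration series -> two-channel movie stack.

#' Construct a two-channel movie stack
#'
#' @param num,den Numeric arrays `(time, height, width)`: numerator and
#'   denominator channel intensities (>= 0, same shape).
#' @param frame_rate Frames per second.
#' @param metadata Named list (protocol/group/mouse/slice ids, drift truth,
#'   seed, ...).
#' @param valid Optional logical array marking real (non-fill) pixels;
#'   `NULL` means all pixels are valid.
#' @return A `movie_stack` object.
#' @export
movie_stack <- function(num, den, frame_rate, metadata = list(), valid = NULL) {
  if (!is.array(num) || !is.array(den) || length(dim(num)) != 3L)
    stopf("channels must be 3-D arrays (time, height, width)")
  if (!identical(dim(num), dim(den)))
    stopf("both channels must have the same shape")
  if (min(num) < 0 || min(den) < 0) stopf("intensities must be >= 0")
  check_number(frame_rate, "frame_rate", min = 0, strict_min = TRUE)
  if (!is.null(valid) && !identical(dim(valid), dim(num)))
    stopf("'valid' must match the channel shape")
  structure(list(num = num, den = den, frame_rate = frame_rate,
                 metadata = metadata, valid = valid),
            class = "movie_stack")
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$num)
  cat(sprintf("<movie_stack> %d frames of %dx%d at %g Hz (%s)\n",
              d[1], d[2], d[3], x$frame_rate,
              x$metadata$protocol %||% "no protocol"))
  invisible(x)
}

n_frames <- function(movie) dim(movie$num)[1]

## shift a matrix by integer (dy, dx): content moves down/right for positive
## offsets; exposed pixels are filled with `fill`.
shift_image <- function(mat, dy, dx, fill = 0) {
  h <- nrow(mat); w <- ncol(mat)
  out <- matrix(fill, h, w)
  ys <- max(1, 1 + dy):min(h, h + dy)   # destination rows
  xs <- max(1, 1 + dx):min(w, w + dx)
  if (length(ys) > 0 && length(xs) > 0)
    out[ys, xs] <- mat[ys - dy, xs - dx]
  out
}

#' Render a synthetic two-channel FRET movie
#'
#' For each frame, every cell's analyte concentration (from `series`, or
#' `control_series` for non-knockout cells in a mosaic) is mapped through the
#' sensor model to a ratio; the denominator channel carries the cell's
#' intensity scale and the numerator carries intensity times ratio, so the
#' masked channel-mean ratio reproduces the sensor ratio exactly in the
#' noiseless case. Bleaching, xy drift (integer pixels, recorded as truth in
#' the metadata), Poisson shot noise and Gaussian read noise are applied
#' after signal synthesis. Identical seeds give bit-identical stacks.
#'
#' @param series `concentration_series` for knockout cells (or all cells if
#'   `control_series` is `NULL`).
#' @param sensor A [sensor_model()]; its `analyte` selects the lactate or
#'   glucose column of the series.
#' @param scene A [scene_phantom()].
#' @param noise A [noise_model()].
#' @param frame_rate Frames per second (acquisition default 5.94 Hz).
#' @param control_series Optional series for wild-type cells in mosaic scenes.
#' @param duration Movie duration in seconds; defaults to the series extent
#'   and must not exceed it.
#' @return A [movie_stack()] with `metadata$drift_truth` (data.frame
#'   `frame, dy, dx`) and `metadata$scene`.
#' @export
render_movie <- function(series, sensor, scene, noise = noise_model(),
                         frame_rate = 5.94, control_series = NULL,
                         duration = NULL) {
  if (!inherits(series, "concentration_series"))
    stopf("'series' must be a concentration_series")
  if (!inherits(scene, "scene_phantom")) stopf("'scene' must be a scene_phantom")
  if (!inherits(noise, "noise_model")) stopf("'noise' must be a noise_model")
  check_number(frame_rate, "frame_rate", min = 0, strict_min = TRUE)

  col <- if (sensor$analyte == "lactate") "lac_in" else "glc_in"
  duration <- duration %||% max(series$t)
  if (duration > max(series$t) + 1e-9)
    stopf("series does not cover the movie duration")
  nt <- floor(duration * frame_rate) + 1L
  t_f <- (seq_len(nt) - 1L) / frame_rate
  conc_at <- function(ser) approx(ser$t, ser[[col]], xout = t_f, rule = 2)$y
  c_ko <- conc_at(series)
  c_wt <- if (is.null(control_series)) c_ko else {
    if (!inherits(control_series, "concentration_series"))
      stopf("'control_series' must be a concentration_series")
    if (max(control_series$t) < max(t_f) - 1e-9)
      stopf("control series does not cover the movie duration")
    conc_at(control_series)
  }

  h <- scene$shape[1]; w <- scene$shape[2]
  masks <- lapply(seq_len(nrow(scene$cells)),
                  function(k) cell_pixels(scene$cells[k, ], scene$shape))

  with_seed(noise$seed, {
    ## drift truth: integer-rendered random walk, frame 1 at (0,0)
    if (noise$drift_sd > 0) {
      dy <- as.integer(round(cumsum(c(0, rnorm(nt - 1L, 0, noise$drift_sd)))))
      dx <- as.integer(round(cumsum(c(0, rnorm(nt - 1L, 0, noise$drift_sd)))))
    } else dy <- dx <- integer(nt)

    num <- array(0, c(nt, h, w)); den <- array(0, c(nt, h, w))
    for (f in seq_len(nt)) {
      bnum <- scene$background * exp(-noise$bleach_num * t_f[f])
      bden <- scene$background * exp(-noise$bleach_den * t_f[f])
      fn <- matrix(bnum, h, w); fd <- matrix(bden, h, w)
      for (k in seq_len(nrow(scene$cells))) {
        conc <- if (scene$cells$knockout[k]) c_ko[f] else c_wt[f]
        r <- sensor_forward(conc, sensor)
        ii <- scene$cells$intensity[k]
        fd[masks[[k]]] <- ii * exp(-noise$bleach_den * t_f[f])
        fn[masks[[k]]] <- ii * r * exp(-noise$bleach_num * t_f[f])
      }
      if (dy[f] != 0 || dx[f] != 0) {
        fn <- shift_image(fn, dy[f], dx[f], fill = bnum)
        fd <- shift_image(fd, dy[f], dx[f], fill = bden)
      }
      if (noise$shot) {
        fn <- matrix(rpois(h * w, fn), h, w)
        fd <- matrix(rpois(h * w, fd), h, w)
      }
      if (noise$read_sd > 0) {
        fn <- pmax(fn + matrix(rnorm(h * w, 0, noise$read_sd), h, w), 0)
        fd <- pmax(fd + matrix(rnorm(h * w, 0, noise$read_sd), h, w), 0)
      }
      num[f, , ] <- fn; den[f, , ] <- fd
    }

    movie_stack(num, den, frame_rate,
                metadata = list(
                  protocol = attr(series, "protocol")$name,
                  sensor = sensor$analyte,
                  drift_truth = data.frame(frame = seq_len(nt), dy = dy, dx = dx),
                  scene = scene, seed = noise$seed))
  })
}
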