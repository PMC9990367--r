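## Disk formats: two-channel TIFF stacks with a JSON sidecar, CSV traces
## and tables.

#' Write a movie stack as a multi-page TIFF with a JSON sidecar
#'
#' Pages are interleaved `numerator, denominator` per frame and stored as
#' 32-bit float samples scaled into \[0, 1\]; the common scale factor, frame
#' rate, channel layout and metadata go into `<path>.json`. The ratio is
#' invariant to the common scale.
#'
#' @param movie A [movie_stack()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(movie, path) {
  if (!inherits(movie, "movie_stack")) stopf("'movie' must be a movie_stack")
  nt <- n_frames(movie)
  scale <- max(movie$num, movie$den, 1e-12) * (1 + 1e-7)
  pages <- vector("list", 2L * nt)
  for (f in seq_len(nt)) {
    pages[[2L * f - 1L]] <- movie$num[f, , ] / scale
    pages[[2L * f]] <- movie$den[f, , ] / scale
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- movie$metadata
  meta$scene <- NULL                       # not serializable, regenerate in code
  sidecar <- list(frame_rate = movie$frame_rate, n_frames = nt,
                  shape = dim(movie$num)[2:3], scale = scale,
                  channel_order = "interleaved_num_den",
                  drift_truth = meta$drift_truth, metadata = meta[
                    setdiff(names(meta), "drift_truth")])
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a movie stack written by [write_movie_tiff()]
#'
#' @param path TIFF path (the `<path>.json` sidecar must exist).
#' @return A [movie_stack()].
#' @export
read_movie_tiff <- function(path) {
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(path)) stopf("stack not found: %s", path)
  if (!file.exists(sidecar_path)) stopf("missing sidecar: %s", sidecar_path)
  sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  nt <- sc$n_frames
  if (length(pages) != 2L * nt)
    stopf("corrupt stack: expected %d pages, found %d", 2L * nt, length(pages))
  h <- sc$shape[1]; w <- sc$shape[2]
  num <- array(0, c(nt, h, w)); den <- array(0, c(nt, h, w))
  for (f in seq_len(nt)) {
    num[f, , ] <- pages[[2L * f - 1L]] * sc$scale
    den[f, , ] <- pages[[2L * f]] * sc$scale
  }
  md <- as.list(sc$metadata)
  if (!is.null(sc$drift_truth)) md$drift_truth <- as.data.frame(sc$drift_truth)
  movie_stack(num, den, sc$frame_rate, metadata = md)
}

#' Write a ratio trace as CSV
#'
#' Columns: `t_s`, `ratio`, `n_masked_pixels` (units in the column names).
#'
#' @param trace A [ratio_trace()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ratio_trace <- function(trace, path) {
  md <- attr(trace, "metadata")
  n_masked <- md$n_masked_pixels %||% rep(NA_integer_, nrow(trace))
  write.csv(data.frame(t_s = trace$t, ratio = trace$ratio,
                       n_masked_pixels = n_masked),
            path, row.names = FALSE)
  invisible(path)
}

#' Read a ratio trace CSV
#'
#' @param path CSV written by [write_ratio_trace()].
#' @param frame_rate Frames per second (recovered from the time base when
#'   omitted).
#' @return A [ratio_trace()].
#' @export
read_ratio_trace <- function(path, frame_rate = NULL) {
  d <- read.csv(path)
  if (!all(c("t_s", "ratio") %in% names(d))) stopf("not a ratio-trace CSV: %s", path)
  if (is.null(frame_rate)) {
    dt <- diff(d$t_s)
    if (length(dt) < 1L || any(abs(dt - dt[1]) > 1e-6))
      stopf("cannot infer frame rate from a non-uniform time base")
    frame_rate <- 1 / dt[1]
  }
  ratio_trace(d$t_s, d$ratio, frame_rate,
              metadata = list(n_masked_pixels = d$n_masked_pixels))
}
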