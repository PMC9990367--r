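## Li minimum cross-entropy thresholding and tissue masking.

#' Li minimum cross-entropy threshold
#'
#' Iterates the Li fixed-point update
#' `t' = (mu_b(t) - mu_f(t)) / (ln mu_b(t) - ln mu_f(t))`,
#' where `mu_b` and `mu_f` are the mean intensities at or below and above
#' `t`, until the change is smaller than `tol` intensity units. The fixed
#' point minimizes the cross-entropy between the image and its two-level
#' reconstruction. The iteration requires positive means, so images whose
#' minimum is <= 0 are shifted by `1 - min` and the threshold shifted back.
#'
#' @param image Numeric matrix (or vector) of intensities with at least two
#'   distinct values.
#' @param tol Convergence tolerance in intensity units.
#' @param max_iter Iteration cap.
#' @return The threshold value (foreground = pixels strictly above it).
#' @export
#' @examples
#' img <- c(rep(10, 50), rep(100, 50))
#' li_threshold(img)  # 90 / log(10) = 39.086...
li_threshold <- function(image, tol = 0.5, max_iter = 200L) {
  v <- as.numeric(image)
  v <- v[is.finite(v)]
  if (length(v) < 2L || diff(range(v)) == 0)
    stopf("threshold undefined: image is constant")
  shift <- if (min(v) <= 0) 1 - min(v) else 0
  v <- v + shift

  t_cur <- mean(v)
  for (i in seq_len(max_iter)) {
    back <- v[v <= t_cur]; fore <- v[v > t_cur]
    ## keep the threshold interior if one side empties
    if (!length(back)) { t_cur <- min(v); back <- v[v <= t_cur] }
    if (!length(fore)) { t_cur <- max(v[v < max(v)]); fore <- v[v > t_cur]; back <- v[v <= t_cur] }
    mu_b <- mean(back); mu_f <- mean(fore)
    t_new <- (mu_b - mu_f) / (log(mu_b) - log(mu_f))
    if (abs(t_new - t_cur) < tol) { t_cur <- t_new; break }
    t_cur <- t_new
  }
  t_cur - shift
}

## Li/Lee cross-entropy objective for a candidate threshold (positive data).
## Minimized by the Li fixed point; used by build_mask diagnostics and as a
## scan target in validation.
li_cross_entropy <- function(v, thr) {
  back <- v[v <= thr]; fore <- v[v > thr]
  if (!length(back) || !length(fore)) return(Inf)
  -(sum(back) * log(mean(back)) + sum(fore) * log(mean(fore)))
}

#' Build a static tissue mask for a registered movie
#'
#' The Li threshold is computed once on the time-averaged channel-sum image
#' (averaging only valid, non-fill pixels) and the static mask of
#' above-threshold pixels is applied to every frame, which keeps the ratio
#' trace free of frame-to-frame mask jitter.
#'
#' @param movie A (registered) [movie_stack()].
#' @return A `tissue_mask`: list with `mask` (logical matrix), `threshold`,
#'   and `fraction` of pixels retained.
#' @export
build_mask <- function(movie) {
  if (!inherits(movie, "movie_stack")) stopf("'movie' must be a movie_stack")
  total <- movie$num + movie$den
  if (is.null(movie$valid)) {
    avg <- apply(total, c(2, 3), mean)
  } else {
    s <- apply(total * movie$valid, c(2, 3), sum)
    nval <- apply(movie$valid, c(2, 3), sum)
    avg <- ifelse(nval > 0, s / pmax(nval, 1), 0)
  }
  thr <- li_threshold(avg)
  mask <- avg > thr
  if (!any(mask)) stopf("no tissue detected: empty mask")
  structure(list(mask = mask, threshold = thr,
                 fraction = mean(mask)),
            class = "tissue_mask")
}

#' @export
print.tissue_mask <- function(x, ...) {
  cat(sprintf("<tissue_mask> threshold %.4g, %.2f%% of pixels retained\n",
              x$threshold, 100 * x$fraction))
  invisible(x)
}
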