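## Scene phantoms and acquisition noise models for the movie renderer.

#' Create a scene phantom
#'
#' A field of elliptical "cells" on a uniform background. Cell intensities
#' are in expected photon counts per pixel per frame (the denominator
#' channel; the numerator is intensity times the sensor ratio).
#'
#' @param shape Frame shape `c(height, width)` in pixels; the acquisition
#'   default is 256 x 256.
#' @param cells data.frame with columns `cy`, `cx` (center, pixels), `ry`,
#'   `rx` (radii, pixels), `intensity` (counts), `knockout` (logical).
#' @param background Background level in counts (must be below every cell
#'   intensity).
#' @return A `scene_phantom` object.
#' @export
scene_phantom <- function(shape = c(256, 256), cells, background = 5) {
  if (length(shape) != 2L || any(shape < 4)) stopf("'shape' must be c(height, width)")
  need <- c("cy", "cx", "ry", "rx", "intensity", "knockout")
  if (!is.data.frame(cells) || !all(need %in% names(cells)) || nrow(cells) < 1L)
    stopf("'cells' must be a data.frame with columns %s", paste(need, collapse = ", "))
  check_number(background, "background", min = 0)
  if (any(cells$intensity <= background))
    stopf("cell intensities must exceed the background level")
  if (any(cells$cy - cells$ry < 1 | cells$cy + cells$ry > shape[1] |
          cells$cx - cells$rx < 1 | cells$cx + cells$rx > shape[2]))
    stopf("cell regions must lie inside the frame")
  structure(list(shape = as.integer(shape), cells = cells,
                 background = background),
            class = "scene_phantom")
}

#' Random non-overlapping cell layout
#'
#' Convenience generator used by [generate_cohort()]: places `n_cells`
#' ellipses by rejection sampling, optionally flagging each as knockout with
#' probability `mosaic_fraction` (mosaic Cre recombination).
#'
#' @param n_cells Number of cells.
#' @param shape Frame shape `c(height, width)`.
#' @param mosaic_fraction Probability a cell is knockout.
#' @param intensity Mean cell intensity, counts.
#' @param radius Mean cell radius, pixels.
#' @param background Background counts.
#' @param seed RNG seed.
#' @return A [scene_phantom()].
#' @export
random_scene <- function(n_cells = 12, shape = c(64, 64), mosaic_fraction = 0,
                         intensity = 100, radius = 4, background = 5,
                         seed = NULL) {
  with_seed(seed, {
    cells <- data.frame(cy = numeric(0), cx = numeric(0), ry = numeric(0),
                        rx = numeric(0), intensity = numeric(0),
                        knockout = logical(0))
    margin <- radius * 2 + 2
    tries <- 0
    while (nrow(cells) < n_cells && tries < n_cells * 200) {
      tries <- tries + 1
      ry <- radius * runif(1, 0.7, 1.3); rx <- radius * runif(1, 0.7, 1.3)
      cy <- runif(1, margin, shape[1] - margin)
      cx <- runif(1, margin, shape[2] - margin)
      sep <- pmax(cells$ry, cells$rx) + max(ry, rx) + 1
      if (nrow(cells) > 0 &&
          any((cells$cy - cy)^2 + (cells$cx - cx)^2 < sep^2)) next
      cells <- rbind(cells, data.frame(
        cy = cy, cx = cx, ry = ry, rx = rx,
        intensity = intensity * runif(1, 0.8, 1.2),
        knockout = runif(1) < mosaic_fraction))
    }
    if (nrow(cells) < n_cells)
      stopf("could not place %d non-overlapping cells in a %dx%d frame",
            n_cells, shape[1], shape[2])
    scene_phantom(shape = shape, cells = cells, background = background)
  })
}

## logical mask of one cell's pixels
cell_pixels <- function(cell, shape) {
  yy <- matrix(seq_len(shape[1]), shape[1], shape[2])
  xx <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  ((yy - cell$cy) / cell$ry)^2 + ((xx - cell$cx) / cell$rx)^2 <= 1
}

#' Acquisition noise model
#'
#' @param shot Apply Poisson shot noise on expected counts?
#' @param read_sd Gaussian read-noise SD, counts.
#' @param bleach_num,bleach_den Per-channel exponential bleaching rate, 1/s.
#' @param drift_sd Random-walk drift step SD, pixels/frame (rendered at
#'   integer precision).
#' @param seed RNG seed; identical seeds give bit-identical movies.
#' @return A `noise_model` object. `noise_model()` with no arguments is the
#'   noiseless, drift-free configuration.
#' @export
noise_model <- function(shot = FALSE, read_sd = 0, bleach_num = 0,
                        bleach_den = 0, drift_sd = 0, seed = NULL) {
  check_flag(shot, "shot")
  check_number(read_sd, "read_sd", min = 0)
  check_number(bleach_num, "bleach_num", min = 0)
  check_number(bleach_den, "bleach_den", min = 0)
  check_number(drift_sd, "drift_sd", min = 0)
  structure(list(shot = shot, read_sd = read_sd, bleach_num = bleach_num,
                 bleach_den = bleach_den, drift_sd = drift_sd, seed = seed),
            class = "noise_model")
}
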