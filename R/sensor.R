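## Sensor binding model: one-site Hill occupancy mapped to a fluorescence
## ratio that INCREASES with analyte for both sensor families. For the
## lactate sensor this corresponds to reporting donor/acceptor (mTFP/Venus):
## lactate binding lowers FRET, so the donor-over-acceptor ratio rises.

#' Create a FRET sensor model
#'
#' @param analyte `"lactate"` or `"glucose"`.
#' @param kd Dissociation constant, mM.
#' @param hill Hill coefficient (> 0).
#' @param r_min Ratio at zero analyte.
#' @param r_max Ratio at saturation (> r_min).
#' @return A `sensor_model` object.
#' @seealso [laconic_sensor()], [fliip_sensor()] for configured defaults.
#' @export
sensor_model <- function(analyte = c("lactate", "glucose"), kd, hill = 1,
                         r_min = 1, r_max) {
  analyte <- match.arg(analyte)
  check_number(kd, "kd", min = 0, strict_min = TRUE)
  check_number(hill, "hill", min = 0, strict_min = TRUE)
  check_number(r_min, "r_min", min = 0, strict_min = TRUE)
  check_number(r_max, "r_max", min = r_min, strict_min = TRUE)
  structure(list(analyte = analyte, kd = kd, hill = hill,
                 r_min = r_min, r_max = r_max),
            class = "sensor_model")
}

#' Default lactate sensor (Laconic-type)
#'
#' Ratio rises from 1.0 to 1.3 with Hill 1. The 8 mM Kd reflects the low
#' affinity of Laconic-type sensors and keeps physiological lactate
#' excursions (roughly 0.5 to 8 mM here) in the quasi-linear range, which is
#' what makes delta-ratio amplitudes and slopes proportional to
#' concentration changes. Configurable working defaults, not calibration
#' values.
#'
#' @param ... Overrides passed to [sensor_model()].
#' @export
laconic_sensor <- function(...) {
  args <- modifyList(list(analyte = "lactate", kd = 8, hill = 1,
                          r_min = 1, r_max = 1.3), list(...))
  do.call(sensor_model, args)
}

#' Default glucose sensor (FLII-type)
#'
#' Ratio rises from 1.0 to 1.8 with a 0.6 mM Kd, Hill 1.
#'
#' @param ... Overrides passed to [sensor_model()].
#' @export
fliip_sensor <- function(...) {
  args <- modifyList(list(analyte = "glucose", kd = 0.6, hill = 1,
                          r_min = 1, r_max = 1.8), list(...))
  do.call(sensor_model, args)
}

#' Map analyte concentration to sensor ratio
#'
#' `R = r_min + (r_max - r_min) * c^h / (kd^h + c^h)`; monotone
#' nondecreasing in `c`. Vectorized over `c`.
#'
#' @param c Analyte concentration(s), mM (>= 0).
#' @param sensor A [sensor_model()].
#' @return Ratio(s).
#' @export
#' @examples
#' s <- laconic_sensor()
#' sensor_forward(c(0, s$kd, 100 * s$kd), s)
sensor_forward <- function(c, sensor) {
  if (!inherits(sensor, "sensor_model")) stopf("'sensor' must be a sensor_model")
  if (any(!is.finite(c)) || any(c < 0)) stopf("concentration must be >= 0")
  ch <- c^sensor$hill
  sensor$r_min + (sensor$r_max - sensor$r_min) * ch / (sensor$kd^sensor$hill + ch)
}

#' Invert a sensor ratio to analyte concentration
#'
#' Exact algebraic inverse of [sensor_forward()]. Ratios slightly outside
#' the sensor range (within `tol`) are clipped to the range boundary; ratios
#' further out, or at/above saturation, are rejected.
#'
#' @param r Ratio(s).
#' @param sensor A [sensor_model()].
#' @param tol Tolerated out-of-range excursion in ratio units.
#' @return Concentration(s), mM.
#' @export
sensor_inverse <- function(r, sensor, tol = 1e-6) {
  if (!inherits(sensor, "sensor_model")) stopf("'sensor' must be a sensor_model")
  if (any(!is.finite(r))) stopf("ratio must be finite")
  if (any(r < sensor$r_min - tol) || any(r > sensor$r_max + tol))
    stopf("out of sensor range: ratio outside [r_min - tol, r_max + tol]")
  r <- pmin(pmax(r, sensor$r_min), sensor$r_max)
  if (any(r >= sensor$r_max))
    stopf("out of sensor range: ratio at saturation is unresolvable")
  occ <- (r - sensor$r_min) / (sensor$r_max - r)
  pmax(0, sensor$kd * occ^(1 / sensor$hill))
}

#' Local sensor gain dR/dc
#'
#' Derivative of [sensor_forward()] at concentration `c`; used to convert
#' ratio-unit slopes into concentration rates in the quasi-linear range.
#'
#' @inheritParams sensor_forward
#' @return Gain(s) in ratio units per mM.
#' @export
sensor_gain <- function(c, sensor) {
  if (!inherits(sensor, "sensor_model")) stopf("'sensor' must be a sensor_model")
  if (any(!is.finite(c)) || any(c < 0)) stopf("concentration must be >= 0")
  h <- sensor$hill; kdh <- sensor$kd^h
  (sensor$r_max - sensor$r_min) * h * kdh * ifelse(c > 0, c^(h - 1), if (h == 1) 1 else if (h > 1) 0 else Inf) /
    (kdh + ifelse(c > 0, c^h, 0))^2
}

#' @export
print.sensor_model <- function(x, ...) {
  cat(sprintf("<sensor_model> %s: kd %g mM, hill %g, ratio %g..%g\n",
              x$analyte, x$kd, x$hill, x$r_min, x$r_max))
  invisible(x)
}
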