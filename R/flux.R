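## Trace-level flux readouts: basal level, accumulation amplitude,
## production/consumption slope.

flux_estimate <- function(basal = NA_real_, amplitude = NA_real_,
                          slope = NA_real_, r2 = NA_real_, n = NA_integer_,
                          window = c(NA_real_, NA_real_), flags = character(0),
                          units = "dratio") {
  structure(list(basal = basal, amplitude = amplitude, slope = slope,
                 r2 = r2, n = n, window = window, flags = flags,
                 units = units),
            class = "flux_estimate")
}

#' @export
print.flux_estimate <- function(x, ...) {
  cat("<flux_estimate>\n")
  if (!is.na(x$basal)) cat(sprintf("  basal:     %.4g %s\n", x$basal, x$units))
  if (!is.na(x$amplitude)) cat(sprintf("  amplitude: %.4g %s\n", x$amplitude, x$units))
  if (!is.na(x$slope))
    cat(sprintf("  slope:     %.4g %s/min (r2 %.3f, n %d)\n",
                x$slope, x$units, x$r2, x$n))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

check_ntrace <- function(ntrace, kind = NULL) {
  if (!inherits(ntrace, "normalized_trace"))
    stopf("trace must come from anchor_normalize()")
  if (!is.null(kind) && attr(ntrace, "kind") != kind)
    stopf("trace must be anchored '%s' (got '%s')", kind, attr(ntrace, "kind"))
}

#' Estimate the basal (zero-anchored) level
#'
#' The basal level is the mean delta-ratio over the pre-intervention baseline
#' window of a trace anchored to its end-of-experiment zero (oxamate
#' depletion or aglycemia). A linear drift of the baseline above
#' `cfg$stability_tol` (ratio/min) raises the `unstable_baseline` flag.
#'
#' @param ntrace A `normalized_trace` anchored `end_zero`.
#' @param protocol The acquisition [protocol()].
#' @param cfg An [analysis_config()].
#' @return A `flux_estimate` with the `basal` field set.
#' @export
estimate_basal <- function(ntrace, protocol, cfg = analysis_config()) {
  check_ntrace(ntrace, "end_zero")
  onsets <- intervention_onsets(protocol)
  if (!length(onsets)) stopf("no intervention onset: baseline window undefined")
  w1 <- min(onsets); w0 <- w1 - cfg$baseline_window_s
  sel <- ntrace$t >= w0 - 1e-9 & ntrace$t <= w1 + 1e-9
  if (sum(sel) < 2L) stopf("baseline window unavailable")
  flags <- character(0)
  drift <- ols_line(ntrace$t[sel] / 60, ntrace$dr[sel])
  if (abs(drift$slope) > cfg$stability_tol) flags <- c(flags, "unstable_baseline")
  flux_estimate(basal = mean(ntrace$dr[sel]), n = sum(sel),
                window = c(w0, w1), flags = flags)
}

#' Estimate the accumulation amplitude
#'
#' Mean delta-ratio over the terminal plateau window of a baseline-anchored
#' trace (the lactate accumulated during transporter block). If a sensor is
#' supplied, raw plateau ratios above `saturation_guard` of the sensor range
#' raise the `saturation` flag.
#'
#' @param ntrace A `normalized_trace` anchored `baseline`.
#' @param protocol The acquisition [protocol()].
#' @param cfg An [analysis_config()].
#' @param sensor Optional [sensor_model()] for the saturation guard.
#' @return A `flux_estimate` with the `amplitude` field set.
#' @export
estimate_amplitude <- function(ntrace, protocol, cfg = analysis_config(),
                               sensor = NULL) {
  check_ntrace(ntrace, "baseline")
  if (!length(intervention_onsets(protocol)))
    stopf("no intervention onset: amplitude undefined")
  w1 <- max(ntrace$t); w0 <- w1 - cfg$plateau_window_s
  sel <- ntrace$t >= w0 - 1e-9
  if (sum(sel) < 2L) stopf("plateau window shorter than configured")
  flags <- character(0)
  if (!is.null(sensor)) {
    raw <- ntrace$dr[sel] + attr(ntrace, "anchor_value")
    guard <- sensor$r_min + cfg$saturation_guard * (sensor$r_max - sensor$r_min)
    if (any(raw > guard)) flags <- c(flags, "saturation")
  }
  flux_estimate(amplitude = mean(ntrace$dr[sel]), n = sum(sel),
                window = c(w0, w1), flags = flags)
}

#' Estimate the post-intervention slope
#'
#' Ordinary least-squares line over the window
#' `[onset + delay, onset + delay + duration]`, reported in delta-ratio per
#' minute. Positive slopes mean accumulation; consumption protocols
#' (cytochalasin B) give negative slopes whose magnitude is the consumption
#' rate. The fit r-squared and frame count are recorded; r-squared below
#' `cfg$r2_floor` raises the `low_r2` flag.
#'
#' @param ntrace A `normalized_trace` (either anchoring; slopes are
#'   anchor-invariant).
#' @param protocol The acquisition [protocol()].
#' @param cfg An [analysis_config()].
#' @param onset Intervention onset to fit after; defaults to the first.
#' @return A `flux_estimate` with the `slope` field set.
#' @export
estimate_slope <- function(ntrace, protocol, cfg = analysis_config(),
                           onset = NULL) {
  check_ntrace(ntrace)
  onsets <- intervention_onsets(protocol)
  if (!length(onsets)) stopf("no intervention onset: slope undefined")
  t0 <- (onset %||% min(onsets)) + cfg$slope_delay_s
  t1 <- t0 + cfg$slope_duration_s
  if (t1 > max(ntrace$t) + 1e-9) stopf("fit window exceeds the trace")
  sel <- ntrace$t >= t0 - 1e-9 & ntrace$t <= t1 + 1e-9
  if (sum(sel) < 5L) stopf("fewer than 5 frames in the fit window")
  fit <- ols_line(ntrace$t[sel] / 60, ntrace$dr[sel])
  flags <- if (fit$r2 < cfg$r2_floor) "low_r2" else character(0)
  flux_estimate(slope = fit$slope, r2 = fit$r2, n = sum(sel),
                window = c(t0, t1), flags = flags)
}

#' Convert a ratio-unit estimate to concentration units
#'
#' Basal and amplitude are converted by applying the exact sensor inverse at
#' the relevant ratio points; the slope is converted with the local
#' derivative of the inverse (1/gain) at the fit-window midpoint.
#'
#' @param est A `flux_estimate` in delta-ratio units.
#' @param anchor_value The absolute ratio the trace was anchored at.
#' @param sensor A [sensor_model()].
#' @param ntrace The normalized trace the estimate came from (needed for the
#'   slope conversion midpoint); optional if no slope is set.
#' @return A `flux_estimate` in mM (and mM/min for the slope).
#' @export
invert_to_concentration <- function(est, anchor_value, sensor, ntrace = NULL) {
  if (!inherits(est, "flux_estimate")) stopf("'est' must be a flux_estimate")
  c_anchor <- sensor_inverse(anchor_value, sensor)
  out <- est
  if (!is.na(est$basal))
    out$basal <- sensor_inverse(anchor_value + est$basal, sensor) - c_anchor
  if (!is.na(est$amplitude))
    out$amplitude <- sensor_inverse(anchor_value + est$amplitude, sensor) - c_anchor
  if (!is.na(est$slope)) {
    if (is.null(ntrace)) stopf("'ntrace' is needed to convert a slope")
    sel <- ntrace$t >= est$window[1] - 1e-9 & ntrace$t <= est$window[2] + 1e-9
    r_mid <- mean(ntrace$dr[sel]) + anchor_value
    c_mid <- sensor_inverse(r_mid, sensor)
    out$slope <- est$slope / sensor_gain(c_mid, sensor)
  }
  out$units <- "mM"
  out
}

#' Analyze one trace under its protocol
#'
#' Convenience wrapper mapping each protocol to its defined readouts:
#' \describe{
#'   \item{trans_acceleration, aglycemia_only}{end-zero anchoring; basal.}
#'   \item{mct_block}{baseline anchoring; amplitude and slope.}
#'   \item{glut_block_then_aglycemia}{end-zero anchoring; basal and
#'     (consumption) slope after the transport block.}
#' }
#'
#' @param trace A [ratio_trace()].
#' @param protocol The acquisition [protocol()] (a preset name also works).
#' @param cfg An [analysis_config()].
#' @param sensor Optional [sensor_model()] for saturation guarding.
#' @return A `flux_estimate`; unavailable readouts stay `NA`.
#' @export
analyze_trace <- function(trace, protocol, cfg = analysis_config(),
                          sensor = NULL) {
  if (is.character(protocol)) protocol <- protocol_preset(protocol)
  flags <- character(0)
  out <- flux_estimate()
  if (protocol$name %in% c("trans_acceleration", "aglycemia_only",
                           "glut_block_then_aglycemia")) {
    nz <- anchor_normalize(trace, protocol, "end_zero", cfg)
    b <- estimate_basal(nz, protocol, cfg)
    out$basal <- b$basal; flags <- union(flags, b$flags)
    if (protocol$name == "glut_block_then_aglycemia") {
      s <- estimate_slope(nz, protocol, cfg)
      out$slope <- s$slope; out$r2 <- s$r2; out$n <- s$n; out$window <- s$window
      flags <- union(flags, s$flags)
    }
    attr(out, "anchor_value") <- attr(nz, "anchor_value")
  } else {
    nb <- anchor_normalize(trace, protocol, "baseline", cfg)
    a <- estimate_amplitude(nb, protocol, cfg, sensor = sensor)
    s <- estimate_slope(nb, protocol, cfg)
    out$amplitude <- a$amplitude; out$slope <- s$slope
    out$r2 <- s$r2; out$n <- s$n; out$window <- s$window
    flags <- union(flags, c(a$flags, s$flags))
    attr(out, "anchor_value") <- attr(nb, "anchor_value")
  }
  out$flags <- flags
  out
}
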