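## Trace anchoring ("normalization" to nominal zero or to baseline).

#' Analysis window configuration
#'
#' Window lengths are in seconds; none of them is dictated by the acquisition
#' itself, so all are configurable. Defaults: 60 s baseline window ending at
#' the first intervention, 30 s anchor window at the trace end, a 10 s
#' post-onset delay (perfusion dead time) before a 60 s slope-fit window, and
#' a 60 s terminal plateau window.
#'
#' @param baseline_window_s Baseline window length.
#' @param anchor_window_s End-of-trace anchor window length.
#' @param slope_delay_s Delay between intervention onset and slope fit.
#' @param slope_duration_s Slope-fit window length.
#' @param plateau_window_s Terminal plateau window length.
#' @param stability_tol Maximal tolerated |baseline drift| in ratio units per
#'   minute before the unstable-baseline flag is raised.
#' @param saturation_guard Fraction of the sensor range above which the
#'   saturation flag is raised.
#' @param r2_floor Minimal slope-fit r-squared before the low-r2 flag.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(baseline_window_s = 60, anchor_window_s = 30,
                            slope_delay_s = 10, slope_duration_s = 60,
                            plateau_window_s = 60, stability_tol = 0.01,
                            saturation_guard = 0.95, r2_floor = 0.5) {
  cfg <- list(baseline_window_s = baseline_window_s,
              anchor_window_s = anchor_window_s,
              slope_delay_s = slope_delay_s,
              slope_duration_s = slope_duration_s,
              plateau_window_s = plateau_window_s,
              stability_tol = stability_tol,
              saturation_guard = saturation_guard,
              r2_floor = r2_floor)
  for (nm in c("baseline_window_s", "anchor_window_s", "slope_duration_s",
               "plateau_window_s"))
    check_number(cfg[[nm]], nm, min = 0, strict_min = TRUE)
  check_number(slope_delay_s, "slope_delay_s", min = 0)
  check_number(stability_tol, "stability_tol", min = 0)
  check_number(saturation_guard, "saturation_guard", min = 0, max = 1)
  check_number(r2_floor, "r2_floor", min = 0, max = 1)
  structure(cfg, class = "analysis_config")
}

#' Anchor-normalize a ratio trace
#'
#' Subtracts the mean ratio over an anchor window so the trace reads in
#' delta-ratio units: `end_zero` anchors to the final-window mean (the
#' nominal zero-analyte level reached under oxamate depletion or aglycemia),
#' `baseline` anchors to the pre-intervention window. A divisive variant
#' (`dR/R0`) is available via `arithmetic = "divide"`.
#'
#' @param trace A [ratio_trace()].
#' @param protocol The [protocol()] the trace was acquired under.
#' @param kind `"end_zero"` or `"baseline"`.
#' @param cfg An [analysis_config()].
#' @param arithmetic `"subtract"` (default, delta-ratio) or `"divide"`.
#' @return A `normalized_trace` data.frame with columns `t`, `dr`; the anchor
#'   kind, window and value are attached as attributes.
#' @export
anchor_normalize <- function(trace, protocol, kind = c("end_zero", "baseline"),
                             cfg = analysis_config(),
                             arithmetic = c("subtract", "divide")) {
  if (!inherits(trace, "ratio_trace") && !inherits(trace, "normalized_trace"))
    stopf("'trace' must be a ratio_trace")
  if (!inherits(protocol, "protocol")) stopf("'protocol' must be a protocol")
  kind <- match.arg(kind)
  arithmetic <- match.arg(arithmetic)
  t <- trace$t
  r <- if (inherits(trace, "normalized_trace")) trace$dr else trace$ratio
  onsets <- intervention_onsets(protocol)

  if (kind == "end_zero") {
    w1 <- max(t); w0 <- w1 - cfg$anchor_window_s
    if (length(onsets) && w0 < max(onsets))
      stopf("anchor window overlaps an intervention onset")
  } else {
    if (!length(onsets)) stopf("baseline anchoring needs an intervention onset")
    w1 <- min(onsets); w0 <- w1 - cfg$baseline_window_s
    if (w0 < min(t)) stopf("baseline window starts before the trace")
  }
  in_win <- t >= w0 - 1e-9 & t <= w1 + 1e-9
  if (!any(in_win)) stopf("anchor window is empty")
  anchor <- mean(r[in_win])
  dr <- if (arithmetic == "subtract") r - anchor else r / anchor - 1

  structure(data.frame(t = t, dr = dr),
            class = c("normalized_trace", "data.frame"),
            kind = kind, window = c(w0, w1), anchor_value = anchor,
            arithmetic = arithmetic,
            frame_rate = attr(trace, "frame_rate"),
            metadata = attr(trace, "metadata"))
}
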