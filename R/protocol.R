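## Intervention protocols: ordered bath-switch events driving both the
## simulator and the analysis windows.

PROTOCOL_EVENT_KINDS <- c("BASELINE", "OXAMATE_ON", "ARC_ON", "CYTB_ON",
                          "AGLYCEMIA_ON", "WASHOUT")

#' Create a protocol event
#'
#' A single bath-switch intervention: the perfusion medium changes at `onset`
#' (seconds from acquisition start). Doses are stored in mM (5 uM = 0.005 mM).
#'
#' @param kind One of `"BASELINE"`, `"OXAMATE_ON"`, `"ARC_ON"`, `"CYTB_ON"`,
#'   `"AGLYCEMIA_ON"`, `"WASHOUT"`.
#' @param onset Onset time in seconds.
#' @param dose Dose in mM (ignored for `BASELINE`, `AGLYCEMIA_ON`, `WASHOUT`).
#' @return A `protocol_event` list.
#' @export
protocol_event <- function(kind, onset, dose = 0) {
  kind <- match.arg(kind, PROTOCOL_EVENT_KINDS)
  check_number(onset, "onset", min = 0)
  check_number(dose, "dose", min = 0)
  structure(list(kind = kind, onset = onset, dose = dose),
            class = "protocol_event")
}

#' Create an imaging protocol
#'
#' An ordered list of bath-switch events plus a total duration. The first
#' event must be `BASELINE` at t = 0 and onsets must be strictly increasing.
#'
#' @param name Protocol name.
#' @param events List of [protocol_event()] objects.
#' @param duration Total acquisition duration in seconds (> last onset).
#' @return A `protocol` object.
#' @seealso [protocol_preset()] for the four built-in protocols.
#' @export
protocol <- function(name, events, duration) {
  if (!is.character(name) || length(name) != 1L)
    stopf("'name' must be a single string")
  if (!length(events) || !all(vapply(events, inherits, TRUE, "protocol_event")))
    stopf("'events' must be a non-empty list of protocol_event objects")
  onsets <- vapply(events, `[[`, numeric(1), "onset")
  if (events[[1]]$kind != "BASELINE" || onsets[1] != 0)
    stopf("first event must be BASELINE at t = 0")
  if (any(diff(onsets) <= 0))
    stopf("event onsets must be strictly increasing")
  check_number(duration, "duration", min = max(onsets), strict_min = TRUE)
  structure(list(name = name, events = events, duration = duration),
            class = "protocol")
}

#' Built-in protocol presets
#'
#' The four imaging protocols used by the pipeline, with a 120 s baseline:
#' \describe{
#'   \item{trans_acceleration}{20 mM oxamate at 120 s; lactate is depleted by
#'     MCT trans-acceleration. Duration 1320 s so the trace reaches its floor.}
#'   \item{mct_block}{5 uM AR-C155858 at 120 s; lactate accumulates at the
#'     net production rate. Duration 420 s.}
#'   \item{glut_block_then_aglycemia}{20 uM cytochalasin B at 120 s (glucose
#'     decays at the hexokinase rate), aglycemia at 420 s for the zero-glucose
#'     anchor. Duration 720 s.}
#'   \item{aglycemia_only}{0 mM glucose at 120 s. Duration 1320 s, matching
#'     `trans_acceleration` so floor endpoints are comparable.}
#' }
#'
#' @param name Preset name.
#' @return A [protocol()] object.
#' @export
#' @examples
#' protocol_preset("mct_block")
protocol_preset <- function(name = c("trans_acceleration", "mct_block",
                                     "glut_block_then_aglycemia",
                                     "aglycemia_only")) {
  name <- match.arg(name)
  switch(name,
    trans_acceleration = protocol(name, list(
      protocol_event("BASELINE", 0),
      protocol_event("OXAMATE_ON", 120, dose = 20)), duration = 1320),
    mct_block = protocol(name, list(
      protocol_event("BASELINE", 0),
      protocol_event("ARC_ON", 120, dose = 0.005)), duration = 420),
    glut_block_then_aglycemia = protocol(name, list(
      protocol_event("BASELINE", 0),
      protocol_event("CYTB_ON", 120, dose = 0.02),
      protocol_event("AGLYCEMIA_ON", 420)), duration = 720),
    aglycemia_only = protocol(name, list(
      protocol_event("BASELINE", 0),
      protocol_event("AGLYCEMIA_ON", 120)), duration = 1320))
}

#' @export
print.protocol <- function(x, ...) {
  cat(sprintf("<protocol> %s (%.0f s)\n", x$name, x$duration))
  for (e in x$events)
    cat(sprintf("  %6.0f s  %-12s dose %g mM\n", e$onset, e$kind, e$dose))
  invisible(x)
}

## Bath/intervention state within one protocol segment.
## WASHOUT resets everything to baseline.
bath_state <- function(events_so_far, glc_out_baseline, lac_out_baseline) {
  st <- list(ox = 0, arc = FALSE, cytb = FALSE,
             glc_out = glc_out_baseline, lac_out = lac_out_baseline)
  for (e in events_so_far) {
    switch(e$kind,
      BASELINE = NULL,
      OXAMATE_ON = { st$ox <- e$dose },
      ARC_ON = { st$arc <- TRUE },
      CYTB_ON = { st$cytb <- TRUE },
      AGLYCEMIA_ON = { st$glc_out <- 0 },
      WASHOUT = {
        st <- list(ox = 0, arc = FALSE, cytb = FALSE,
                   glc_out = glc_out_baseline, lac_out = lac_out_baseline)
      })
  }
  st
}

## Onset times of all non-BASELINE events (the analysis "interventions")
intervention_onsets <- function(protocol) {
  on <- vapply(protocol$events, `[[`, numeric(1), "onset")
  kinds <- vapply(protocol$events, `[[`, character(1), "kind")
  on[kinds != "BASELINE"]
}

## First onset of a given kind, or NA
onset_of <- function(protocol, kind) {
  for (e in protocol$events) if (e$kind == kind) return(e$onset)
  NA_real_
}
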