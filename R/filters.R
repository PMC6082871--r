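#' Trace-acceptance filter for two-pulse cleavage kinetics
#'
#' Applies the recording-quality rules used for the cleavage-kinetics
#' ensembles: a trace is accepted only if it shows between five and eight
#' unfolding events (~15 nm), between five and eight reduction events
#' (~10 nm) in the test pulse, and no unfolding-class event inside the
#' high-force test pulse. The first violated rule is recorded as the
#' rejection reason. The filter is idempotent.
#'
#' @param events An `fc_events` set from [detect_steps()] on a two-pulse
#'   trajectory.
#' @param min_events,max_events Acceptance band for both event counts.
#' @return The same `fc_events` with `accepted`/`rejection_reason` updated.
#' @export
filter_kinetics_trace <- function(events, min_events = 5, max_events = 8) {
  n_unfold <- sum(events$event_class == "unfold")
  n_reduce <- sum(events$event_class == "reduction" &
    events$segment_label == "test")
  late_unfold <- sum(events$event_class == "unfold" &
    events$segment_label == "test")
  reason <- if (n_unfold < min_events) {
    sprintf("fewer than %d unfolding events (%d)", min_events, n_unfold)
  } else if (n_unfold > max_events) {
    sprintf("more than %d unfolding events (%d)", max_events, n_unfold)
  } else if (n_reduce < min_events) {
    sprintf("fewer than %d reduction events (%d)", min_events, n_reduce)
  } else if (n_reduce > max_events) {
    sprintf("more than %d reduction events (%d)", max_events, n_reduce)
  } else if (late_unfold > 0) {
    "unfolding event in the high-force pulse"
  } else {
    ""
  }
  set_acceptance(events, reason)
}

#' Trace-acceptance filter for five-pulse reformation recordings
#'
#' A reformation recording is analyzed only if the first high-force pulse
#' shows between five and eight disulfide rupture events and the protein was
#' extended to the same length (within `extension_match_tol_nm`) in the
#' initial and probe pulses. The default tolerance of 10 nm is one reduction
#' step.
#'
#' @param events An `fc_events` set from a five-pulse trajectory.
#' @param extension_match_tol_nm Allowed difference between the final
#'   extensions of the first high-force pulse and of the probe pulse.
#' @inheritParams filter_kinetics_trace
#' @return The same `fc_events` with `accepted`/`rejection_reason` updated.
#' @export
filter_reformation_trace <- function(events, extension_match_tol_nm = 10,
                                     min_events = 5, max_events = 8) {
  ss <- attr(events, "segment_summary")
  if (is.null(ss) || !"probe" %in% ss$label) {
    abort("events lack a probe segment; not a five-pulse recording")
  }
  n_rupture <- sum(events$event_class == "reduction" &
    events$segment_label == "test")
  ext_test <- ss$final_extension_nm[ss$label == "test"][1]
  ext_probe <- tail(ss$final_extension_nm[ss$label == "probe"], 1)
  reason <- if (n_rupture < min_events) {
    sprintf("fewer than %d rupture events in the first high-force pulse (%d)",
      min_events, n_rupture)
  } else if (n_rupture > max_events) {
    sprintf("more than %d rupture events in the first high-force pulse (%d)",
      max_events, n_rupture)
  } else if (abs(ext_test - ext_probe) > extension_match_tol_nm) {
    sprintf("extension mismatch between initial and probe pulses (%.1f nm)",
      abs(ext_test - ext_probe))
  } else {
    ""
  }
  set_acceptance(events, reason)
}

set_acceptance <- function(events, reason) {
  attr(events, "accepted") <- !nzchar(reason)
  attr(events, "rejection_reason") <- reason
  events
}

is_accepted <- function(events) isTRUE(attr(events, "accepted"))
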