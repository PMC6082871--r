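#' Constant-force pulse protocols
#'
#' A force protocol is an ordered tibble of constant-force segments with
#' columns `force_pN`, `duration_s` and `label`
#' (one of `"unfold"`, `"test"`, `"quench"`, `"probe"`).
#'
#' `two_pulse_protocol()` is the cleavage-kinetics assay: a low-force unfolding
#' pulse (150 pN, 0.5 s by default) that exposes the buried disulfide, then a
#' high-force test pulse during which reduction is monitored.
#'
#' `five_pulse_protocol()` is the reformation assay: unfold, high-force
#' cleavage, an 8 s zero-force quench during which the collapsed protein's
#' chemistry proceeds unbiased, a second unfolding pulse, and a high-force
#' probe pulse that re-cleaves any reformed disulfides.
#'
#' @param test_force_pN Force of the high-force (test/probe) pulse in pN.
#' @param test_duration_s Duration of the test pulse in s.
#' @param unfold_force_pN,unfold_duration_s Unfolding pulse parameters.
#' @param quench_duration_s Zero-force quench duration (default 8 s).
#' @param probe_duration_s Probe pulse duration; defaults to the test
#'   duration.
#' @return A tibble of class `fc_protocol`.
#' @examples
#' two_pulse_protocol(350, 10)
#' five_pulse_protocol(350, 5)
#' @name protocols
NULL

new_protocol <- function(force_pN, duration_s, label) {
  ok <- c("unfold", "test", "quench", "probe")
  if (!length(force_pN)) abort("protocol must have at least one segment")
  if (any(!label %in% ok)) {
    abort(paste0("segment labels must be one of: ", paste(ok, collapse = ", ")))
  }
  if (any(force_pN < 0) || any(duration_s <= 0)) {
    abort("segment forces must be >= 0 and durations > 0")
  }
  structure(
    tibble(force_pN = force_pN, duration_s = duration_s, label = label),
    class = c("fc_protocol", class(tibble()))
  )
}

#' @rdname protocols
#' @export
two_pulse_protocol <- function(test_force_pN, test_duration_s,
                               unfold_force_pN = 150, unfold_duration_s = 0.5) {
  new_protocol(
    force_pN = c(unfold_force_pN, test_force_pN),
    duration_s = c(unfold_duration_s, test_duration_s),
    label = c("unfold", "test")
  )
}

#' @rdname protocols
#' @export
five_pulse_protocol <- function(test_force_pN, test_duration_s = 5,
                                quench_duration_s = 8,
                                probe_duration_s = NULL,
                                unfold_force_pN = 150,
                                unfold_duration_s = 0.5) {
  probe_duration_s <- probe_duration_s %||% test_duration_s
  new_protocol(
    force_pN = c(
      unfold_force_pN, test_force_pN, 0, unfold_force_pN, test_force_pN
    ),
    duration_s = c(
      unfold_duration_s, test_duration_s, quench_duration_s,
      unfold_duration_s, probe_duration_s
    ),
    label = c("unfold", "test", "quench", "unfold", "probe")
  )
}

# segment bookkeeping: absolute start/end times
protocol_bounds <- function(protocol) {
  end <- cumsum(protocol$duration_s)
  tibble(
    segment_id = seq_len(nrow(protocol)),
    label = protocol$label,
    force_pN = protocol$force_pN,
    t_start = c(0, head(end, -1)),
    t_end = end
  )
}

is_two_pulse <- function(protocol) {
  identical(protocol$label, c("unfold", "test"))
}

is_five_pulse <- function(protocol) {
  identical(protocol$label, c("unfold", "test", "quench", "unfold", "probe")) &&
    protocol$force_pN[3] == 0
}
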