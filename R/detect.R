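#' Detect stepwise extension increases in a force-clamp trajectory
#'
#' Segments the extension signal within each constant-force segment into
#' plateaus by binary-segmentation change-point detection on the mean, then
#' turns every inter-plateau jump at least `min_step_nm` tall (with plateaus
#' at least `min_dwell_s` long) into a step event. Event size is the
#' difference of plateau means, estimated after discarding the feedback
#' settling interval at the start of each plateau. The first settling window
#' after every force change is masked from detection so elastic re-extension
#' jumps are not scored as events.
#'
#' Steps are classified by size window and protocol phase: ~15 nm steps
#' (15 +/- 4 nm) are domain unfolding events; ~10 nm steps (10 +/- 3 nm) in a
#' test or probe segment are disulfide cleavage events (`"reduction"` in the
#' test pulse, `"reform_probe"` in the probe pulse). Where the windows
#' overlap, the unfolding pulse phase wins in the unfolding pulse and the
#' nearer window centre wins elsewhere; exact ties are left `"unclassified"`.
#'
#' @param trajectory An `fc_trajectory` (or any tibble with `time_s`,
#'   `extension_nm`, `segment_id`, `segment_label`, `force_pN` and uniform
#'   sampling).
#' @param min_step_nm Smallest detectable step (default 5 nm).
#' @param min_dwell_s Shortest plateau retained (default 0.004 s).
#' @param unfold_window,reduction_window Classification windows in nm.
#' @return A tibble of class `fc_events` with columns `time_s`, `size_nm`,
#'   `event_class`, `segment_label`, `segment_id`, and attributes
#'   `trajectory_id`, `accepted`, `rejection_reason`, `segment_summary`
#'   (per-segment force, bounds and final extension), `compound`, `config`.
#' @export
detect_steps <- function(trajectory, min_step_nm = 5, min_dwell_s = 0.004,
                         unfold_window = c(11, 19),
                         reduction_window = c(7, 13)) {
  stopifnot(min_step_nm > 0, min_dwell_s > 0)
  if (!nrow(trajectory)) abort("empty trajectory")
  dt <- diff(trajectory$time_s)
  if (any(dt <= 0)) abort("time axis must be strictly increasing")
  if (max(dt) - min(dt) > 1e-9) abort("non-uniform sampling detected")
  fs <- 1 / dt[1]

  config <- attr(trajectory, "config")
  tau <- if (!is.null(config)) config$feedback_tau_s else 0.002
  settle <- ceiling(5 * tau * fs)
  min_len <- max(2L, round(min_dwell_s * fs))
  labels_by_seg <- trajectory$segment_label[!duplicated(trajectory$segment_id)]

  segs <- unique(trajectory$segment_id)
  events <- vector("list", length(segs))
  summary_rows <- vector("list", length(segs))

  for (k in seq_along(segs)) {
    idx <- which(trajectory$segment_id == segs[k])
    lab <- trajectory$segment_label[idx[1]]
    f <- trajectory$force_pN[idx[1]]
    t_seg <- trajectory$time_s[idx]
    # mask the feedback settling interval at the segment start: one time
    # constant suffices after a plain force step (the extension is
    # continuous), but the large elastic excursions around a quench --
    # collapse at its onset, bulk re-extension after it -- need the full
    # settling of ~5 tau before plateaus are trustworthy
    big_jump <- lab == "quench" || (k > 1 && labels_by_seg[k - 1] == "quench")
    mask <- if (big_jump) settle else ceiling(tau * fs)
    use <- if (mask > 0 && length(idx) > mask + 2 * min_len) {
      idx[-seq_len(mask)]
    } else {
      idx
    }
    y <- trajectory$extension_nm[use]
    tt <- trajectory$time_s[use]

    st <- staircase_fit(y, min_len, min_step_nm, settle, tau * fs)
    n_last <- min(length(idx), max(settle, 20L))
    summary_rows[[k]] <- tibble(
      segment_id = segs[k], label = lab, force_pN = f,
      t_start = t_seg[1], t_end = t_seg[length(t_seg)],
      final_extension_nm = mean(trajectory$extension_nm[tail(idx, n_last)])
    )
    if (!length(st$cp)) {
      events[[k]] <- NULL
      next
    }
    events[[k]] <- tibble(
      time_s = tt[st$cp],
      size_nm = st$size,
      segment_label = lab,
      segment_id = segs[k]
    )
  }

  ev <- bind_rows(events)
  if (nrow(ev)) {
    ev <- ev[order(ev$time_s), ]
    ev$event_class <- classify_steps(
      ev$size_nm, ev$segment_label, unfold_window, reduction_window
    )
    ev <- expand_compound_steps(ev)
    ev <- ev[, c("time_s", "size_nm", "event_class", "segment_label", "segment_id")]
  } else {
    ev <- tibble(
      time_s = numeric(), size_nm = numeric(), event_class = character(),
      segment_label = character(), segment_id = integer()
    )
  }

  structure(
    ev,
    trajectory_id = paste0(
      attr(trajectory, "compound_name") %||% "trace", "_seed",
      attr(trajectory, "seed") %||% 0L
    ),
    accepted = nrow(ev) > 0,
    rejection_reason = if (nrow(ev) > 0) "" else "no events",
    segment_summary = bind_rows(summary_rows),
    compound = attr(trajectory, "compound"),
    config = config,
    class = c("fc_events", class(tibble()))
  )
}

# Binary segmentation on the mean, followed by iterative merging of jumps
# below the detection threshold. Plateau levels are estimated from the
# samples beyond the settling window of each plateau; short plateaus fall
# back to the feedback-deconvolved signal, whose levels are unbiased at the
# cost of amplified noise. Returns change-point indices (first sample of
# each new plateau) and jump sizes.
staircase_fit <- function(y, min_len, min_step, settle, tau_samples) {
  n <- length(y)
  if (n < 2 * min_len) return(list(cp = integer(0), size = numeric(0)))
  sigma <- mad(diff(y)) / sqrt(2)
  penalty <- max(10 * sigma^2 * log(n), 1e-12)
  y_dec <- if (tau_samples > 0) {
    a <- exp(-1 / tau_samples)
    c(y[1], (y[-1] - a * y[-n]) / (1 - a))
  } else {
    y
  }
  cp <- binseg_cps(y, min_len, penalty)
  repeat {
    if (!length(cp)) return(list(cp = integer(0), size = numeric(0)))
    lev <- plateau_levels(y, y_dec, cp, settle)
    jump <- diff(lev)
    drop <- which(abs(jump) < min_step)
    if (!length(drop)) break
    cp <- cp[-drop]
  }
  list(cp = cp + 1L, size = jump) # cp indexes first sample of the new plateau
}

binseg_cps <- function(y, min_len, penalty) {
  n <- length(y)
  cs <- cumsum(y)
  out <- integer(0)
  stack <- list(c(1L, n))
  while (length(stack)) {
    seg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    l <- seg[1]; r <- seg[2]
    n_seg <- r - l + 1L
    if (n_seg < 2L * min_len) next
    k <- (l + min_len - 1L):(r - min_len)
    s0 <- if (l > 1L) cs[l - 1L] else 0
    s_tot <- cs[r] - s0
    s_left <- cs[k] - s0
    n_l <- k - l + 1L
    n_r <- n_seg - n_l
    gain <- (s_left - n_l / n_seg * s_tot)^2 * n_seg / (n_l * n_r)
    i <- which.max(gain)
    if (gain[i] > penalty) {
      out <- c(out, k[i])
      stack <- c(stack, list(c(l, k[i])), list(c(k[i] + 1L, r)))
    }
  }
  sort(out)
}

# mean level of each plateau delimited by change points (indices of the last
# sample of the left plateau)
plateau_levels <- function(y, y_dec, cp, settle) {
  starts <- c(1L, cp + 1L)
  ends <- c(cp, length(y))
  vapply(seq_along(starts), function(j) {
    a <- starts[j]; b <- ends[j]
    # skip the settling ramp (none at the very start of the segment window)
    a_eff <- if (j == 1L) a else a + settle
    if (b - a_eff + 1L >= 3L) {
      mean(y[a_eff:b])
    } else {
      # plateau shorter than the settling window: read the deconvolved
      # signal instead, dropping the first (change-point-uncertain) sample
      mean(y_dec[min(a + 1L, b):b])
    }
  }, numeric(1))
}

# Size classification. Two events closer than the dwell/settling resolution
# of the detector appear as one step of summed size, so each class also has
# a "compound" window at twice the single-event sizes: such steps are scored
# as two events of half size (expand_compound_steps). In the test/probe
# pulses the compound-reduction window starts at 17 nm, above the single
# unfolding sizes, so genuine ~15 nm unfolding steps in the high-force pulse
# are still classified as unfolding and rejected by the kinetics filter.
classify_steps <- function(size, segment_label, unfold_window, reduction_window) {
  in_u <- size >= unfold_window[1] & size <= unfold_window[2]
  in_r <- size >= reduction_window[1] & size <= reduction_window[2]
  in_u2 <- size >= 2 * unfold_window[1] & size <= 2 * unfold_window[2]
  in_r2 <- size > max(unfold_window[2] - 2, 2 * reduction_window[1]) &
    size <= 2 * reduction_window[2]
  u_mid <- mean(unfold_window)
  r_mid <- mean(reduction_window)
  red_lab <- ifelse(segment_label == "probe", "reform_probe", "reduction")
  out <- rep("unclassified", length(size))
  unfold_phase <- segment_label == "unfold"
  # unfolding pulse: phase wins
  out[unfold_phase & in_u] <- "unfold"
  out[unfold_phase & in_u2] <- "unfold x2"
  # test/probe: size windows, overlap resolved by nearest window centre
  both <- !unfold_phase & in_u & in_r
  d_u <- abs(size - u_mid)
  d_r <- abs(size - r_mid)
  out[!unfold_phase & in_r & !in_u] <- red_lab[!unfold_phase & in_r & !in_u]
  out[!unfold_phase & in_u & !in_r] <- "unfold"
  out[both & d_r < d_u] <- red_lab[both & d_r < d_u]
  out[both & d_u < d_r] <- "unfold"
  out[!unfold_phase & in_r2] <- paste0(red_lab[!unfold_phase & in_r2], " x2")
  out[!unfold_phase & in_u2 & !in_r2] <- "unfold x2"
  out
}

# turn each compound "<class> x2" step into two half-size events
expand_compound_steps <- function(ev) {
  double <- grepl(" x2$", ev$event_class)
  if (!any(double)) return(ev)
  twice <- ev[double, ]
  twice$event_class <- sub(" x2$", "", twice$event_class)
  twice$size_nm <- twice$size_nm / 2
  ev <- bind_rows(ev[!double, ], twice, twice)
  ev[order(ev$time_s), ]
}

#' @export
print.fc_events <- function(x, ...) {
  cat(sprintf(
    "<fc_events> %s: %d events, accepted = %s%s\n",
    attr(x, "trajectory_id"), nrow(x), attr(x, "accepted"),
    if (nzchar(attr(x, "rejection_reason"))) {
      paste0(" (", attr(x, "rejection_reason"), ")")
    } else ""
  ))
  NextMethod()
}
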