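# Shared fixtures, built in code at test time.

# A hand-built event set with the attribute scaffolding the filters and
# kinetics stages expect, bypassing simulation and detection.
make_eventset <- function(unfold_times = seq(0.05, 0.4, length.out = 6),
                          reduce_times = seq(1, 6, length.out = 6),
                          unfold_sizes = rep(15, length(unfold_times)),
                          reduce_sizes = rep(10, length(reduce_times)),
                          test_onset = 0.5,
                          test_duration = 10,
                          force_pN = 350,
                          compound = "L-cysteine",
                          extra_events = NULL) {
  cpd <- as.list(get_compound(compound))
  ev <- dplyr::bind_rows(
    tibble::tibble(
      time_s = unfold_times, size_nm = unfold_sizes,
      event_class = "unfold", segment_label = "unfold", segment_id = 1L
    ),
    tibble::tibble(
      time_s = test_onset + reduce_times, size_nm = reduce_sizes,
      event_class = "reduction", segment_label = "test", segment_id = 2L
    ),
    extra_events
  )
  ev <- ev[order(ev$time_s), ]
  structure(
    ev,
    trajectory_id = "fixture",
    accepted = TRUE,
    rejection_reason = "",
    segment_summary = tibble::tibble(
      segment_id = 1:2, label = c("unfold", "test"),
      force_pN = c(150, force_pN),
      t_start = c(0, test_onset),
      t_end = c(test_onset, test_onset + test_duration),
      final_extension_nm = c(sum(unfold_sizes), sum(unfold_sizes) + sum(reduce_sizes))
    ),
    compound = cpd,
    config = sim_config(),
    class = c("fc_events", class(tibble::tibble()))
  )
}

# A plain staircase trajectory tibble (no simulator attributes).
make_staircase <- function(step_times, step_sizes, duration = 2,
                           fs = 1000, label = "unfold", force = 150,
                           noise_sd = 0, offset = 0) {
  t <- (seq_len(duration * fs) - 0.5) / fs
  x <- rep(offset, length(t))
  for (k in seq_along(step_times)) {
    x[t >= step_times[k]] <- x[t >= step_times[k]] + step_sizes[k]
  }
  if (noise_sd > 0) x <- x + rnorm(length(t), 0, noise_sd)
  tibble::tibble(
    time_s = t, force_pN = force, extension_nm = x,
    segment_id = 1L, segment_label = label
  )
}

# greedy nearest-time matching of detected events to ground truth
match_events <- function(detected, truth, max_dt = 0.015) {
  used <- rep(FALSE, nrow(detected))
  errs <- rep(NA_real_, nrow(truth))
  for (j in order(truth$time_s)) {
    dt <- abs(detected$time_s - truth$time_s[j])
    dt[used] <- Inf
    i <- which.min(dt)
    if (length(i) && is.finite(dt[i]) && dt[i] <= max_dt) {
      used[i] <- TRUE
      errs[j] <- detected$size_nm[i] - truth$size_nm[j]
    }
  }
  errs
}
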