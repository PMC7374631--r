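# Phase segmentation of jump trials from the force record.

#' Default event-detection thresholds
#'
#' @return list: `contact_n` contact/takeoff threshold on total vertical force
#'   (N, common plate-noise floor), `onset_frac` countermovement-onset
#'   deviation as a fraction of body weight, `onset_sustain_s` minimum
#'   duration of that deviation, `flight_min_s` minimum time below/above the
#'   contact threshold for a real flight/contact transition.
#' @export
default_thresholds <- function() {
  list(contact_n = 20, onset_frac = 0.05, onset_sustain_s = 0.05,
       flight_min_s = 0.04)
}

total_fz <- function(trial) {
  ts_channel(trial$force, "fz_l") + ts_channel(trial$force, "fz_r")
}

#' Measure body weight from quiet standing
#'
#' Mean total vertical force over a quiet-standing window (CMJ trials). Drop
#' jumps begin airborne, so the fallback `subject mass * g` is used there.
#'
#' @param trial a `jw_trial`.
#' @param window `c(start, end)` in s within the recording (CMJ only).
#' @return body weight in N.
#' @export
measure_body_weight <- function(trial, window = c(0.05, 0.35)) {
  if (trial$jump_type != "CMJ") {
    return(trial$subject$body_mass * GRAV)
  }
  t <- trial$force$t
  if (length(window) != 2L || diff(window) <= 0) {
    jw_abort("window must be c(start, end) with start < end", "jw_argument_error")
  }
  if (window[1L] < t[1L] - 1e-9 || window[2L] > t[length(t)] + 1e-9) {
    jw_abort("body-weight window lies outside the recording", "jw_argument_error")
  }
  sel <- t >= window[1L] & t <= window[2L]
  if (!any(sel)) jw_abort("body-weight window contains no samples", "jw_argument_error")
  mean(total_fz(trial)[sel])
}

#' Phase events of a jump trial
#'
#' Detects the boundaries of the analysis window from the (filtered) total
#' vertical force:
#' * drop jumps: `t_contact` = first sample above the contact threshold that
#'   stays in contact for at least `flight_min_s`;
#' * CMJ: `t_onset` = first sustained (>= `onset_sustain_s`) deviation of
#'   force from body weight by more than `onset_frac * bw`, walked back to the
#'   last crossing of body weight;
#' * `t_takeoff` = first drop below the contact threshold (after the window
#'   start) followed by at least `flight_min_s` of flight;
#' * `t_lowest` = minimum of the COM displacement obtained by double
#'   integration of force over the window.
#'
#' The analysis window is `[t_onset | t_contact, t_takeoff]`.
#'
#' @param trial a `jw_trial`.
#' @param bw body weight in N (default from [measure_body_weight()]).
#' @param thresholds see [default_thresholds()].
#' @param filter_cutoff low-pass cutoff (Hz) applied to the force before
#'   thresholding; `NULL` uses the raw force.
#' @return An object of class `jw_events`: `t_onset`, `t_contact`, `t_lowest`,
#'   `t_takeoff`, `window = c(start, end)`.
#' @export
detect_events <- function(trial, bw = NULL, thresholds = default_thresholds(),
                          filter_cutoff = NULL) {
  th <- utils::modifyList(default_thresholds(), as.list(thresholds))
  fz_raw <- total_fz(trial)
  fz <- if (is.null(filter_cutoff)) fz_raw else {
    lowpass_zero_lag(timeseries(fz_raw, trial$force$rate), filter_cutoff)$values[, 1L]
  }
  t <- trial$force$t
  rate <- trial$force$rate
  n <- length(t)
  if (all(fz_raw < th$contact_n)) {
    jw_abort("no ground contact found (all force below threshold)", "jw_event_error")
  }
  if (is.null(bw)) bw <- measure_body_weight(trial)
  run_len <- function(x) {            # lengths of runs of TRUE, aligned to starts
    r <- rle(x)
    ends <- cumsum(r$lengths)
    list(starts = ends - r$lengths + 1L, lengths = r$lengths, values = r$values)
  }
  min_run <- max(1L, round(th$flight_min_s * rate))
  above <- fz > th$contact_n
  runs <- run_len(above)

  if (trial$jump_type == "CMJ") {
    t_contact <- NA_real_
    start_idx <- 1L
    # onset: sustained deviation from body weight, walked back to BW crossing
    dev <- abs(fz - bw) > th$onset_frac * bw
    druns <- run_len(dev)
    need <- max(1L, round(th$onset_sustain_s * rate))
    oi <- druns$starts[druns$values & druns$lengths >= need][1L]
    if (is.na(oi)) jw_abort("no countermovement onset found", "jw_event_error")
    j <- oi
    while (j > 1L && sign(fz[j] - bw) == sign(fz[oi] - bw)) j <- j - 1L
    t_onset <- t[j]
    win_start_idx <- j
  } else {
    t_onset <- NA_real_
    ci <- runs$starts[runs$values & runs$lengths >= min_run][1L]
    if (is.na(ci)) jw_abort("no sustained ground contact found", "jw_event_error")
    t_contact <- t[ci]
    win_start_idx <- ci
  }

  below <- !above
  bruns <- run_len(below)
  cand <- bruns$starts[bruns$values & bruns$lengths >= min_run &
                         bruns$starts > win_start_idx]
  if (!length(cand)) jw_abort("no takeoff found after the window start", "jw_event_error")
  toff_idx <- cand[1L]
  t_takeoff <- t[toff_idx]

  # lowest COM position from double integration of the raw force
  sel <- win_start_idx:toff_idx
  m <- trial$subject$body_mass
  a <- fz_raw[sel] / m - GRAV
  v0 <- if (trial$jump_type == "CMJ") 0 else -sqrt(2 * GRAV * trial$drop_height)
  v <- v0 + cumtrapz(t[sel], a)
  x <- cumtrapz(t[sel], v)
  t_lowest <- t[sel][which.min(x)]

  structure(
    list(t_onset = t_onset, t_contact = t_contact, t_lowest = t_lowest,
         t_takeoff = t_takeoff,
         window = c(if (trial$jump_type == "CMJ") t_onset else t_contact, t_takeoff),
         bw = bw, thresholds = th),
    class = "jw_events"
  )
}

#' @export
print.jw_events <- function(x, ...) {
  cat(sprintf("<jw_events> window %.3f..%.3f s (lowest %.3f s)\n",
              x$window[1L], x$window[2L], x$t_lowest))
  invisible(x)
}
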