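# Stimulus protocols -----------------------------------------------------
#
# A protocol describes one trial's stimulus: a step (rapid rotation to an
# eccentric roll angle, a multi-second hold, rapid return) or an impulse
# (rotation out and immediately back within milliseconds, leaving no
# steady-state component). Directions are expressed relative to the recorded
# neuron: "ipsi" rolls the neuron's ear down (positive signed angle),
# "contra" the opposite.

# measured platform kinematics: ramp/dwell durations by step magnitude
.step_ramp_ms <- function(magnitude_deg) {
  stats::approx(c(10, 20, 30), c(2.2, 3.9, 5.3), xout = magnitude_deg,
                rule = 2)$y
}
.impulse_total_ms <- function(magnitude_deg) {
  stats::approx(c(10, 15, 30), c(5.0, 5.6, 13.0), xout = magnitude_deg,
                rule = 2)$y
}
.impulse_dwell_ms <- function(magnitude_deg) {
  stats::approx(c(10, 15, 30), c(0.3, 0.4, 2.5), xout = magnitude_deg,
                rule = 2)$y
}

default_transition_ms <- function(kind, magnitude_deg) {
  ifelse(kind == "step",
         .step_ramp_ms(magnitude_deg),
         (.impulse_total_ms(magnitude_deg) - .impulse_dwell_ms(magnitude_deg)) / 2)
}

#' Construct a stimulus protocol
#'
#' @param kind `"step"` or `"impulse"`.
#' @param direction `"ipsi"` or `"contra"` (relative to the recorded neuron).
#' @param magnitude_deg Eccentric roll magnitude in degrees (>= 0; 0 yields a
#'   flat trajectory, useful as a control).
#' @param baseline_s Pre-stimulus baseline duration in seconds (>= 5 s is
#'   required downstream by trial-baseline normalization).
#' @param hold_s Duration at the eccentric angle, seconds. Steps hold for
#'   many seconds (default 15); impulses dwell for milliseconds (default from
#'   the measured platform kinematics).
#' @param response_s Post-return recording duration in seconds.
#' @param transition_ms One-way ramp duration in milliseconds; defaults to
#'   the measured platform kinematics for the requested magnitude.
#' @return A one-row tibble; bind rows to form a protocol table.
#' @export
#' @examples
#' stim_protocol("step", "ipsi", 30)
#' stim_protocol("impulse", "contra", 15)
stim_protocol <- function(kind = c("step", "impulse"),
                          direction = c("ipsi", "contra"),
                          magnitude_deg,
                          baseline_s = 10,
                          hold_s = NULL,
                          response_s = 10,
                          transition_ms = NULL) {
  kind <- match.arg(kind)
  direction <- match.arg(direction)
  hold_s <- hold_s %||%
    if (kind == "step") 15 else .impulse_dwell_ms(magnitude_deg) / 1000
  transition_ms <- transition_ms %||% default_transition_ms(kind, magnitude_deg)
  p <- tibble::tibble(
    stim_kind = kind, stim_direction = direction,
    stim_magnitude_deg = as.numeric(magnitude_deg),
    baseline_s = as.numeric(baseline_s), hold_s = as.numeric(hold_s),
    response_s = as.numeric(response_s),
    transition_ms = as.numeric(transition_ms)
  )
  validate_protocols(p)
  p
}

#' Validate a protocol table
#'
#' Checks the structural invariants of a protocol table: positive durations,
#' non-negative magnitudes, impulse dwells of at most 10 ms and step holds of
#' at least 1 s.
#'
#' @param protocols A tibble as built by [stim_protocol()].
#' @return The input, invisibly; errors describe the offending row.
#' @export
validate_protocols <- function(protocols) {
  need <- c("stim_kind", "stim_direction", "stim_magnitude_deg",
            "baseline_s", "hold_s", "response_s", "transition_ms")
  missing_cols <- setdiff(need, names(protocols))
  if (length(missing_cols) > 0) {
    abort_user("protocol table lacks columns: ",
               paste(missing_cols, collapse = ", "))
  }
  for (i in seq_len(nrow(protocols))) {
    p <- protocols[i, ]
    lab <- paste0("protocol row ", i, " (", p$stim_kind, " ",
                  p$stim_direction, " ", p$stim_magnitude_deg, " deg)")
    if (!p$stim_kind %in% c("step", "impulse")) {
      abort_user(lab, ": unknown stimulus kind")
    }
    if (!p$stim_direction %in% c("ipsi", "contra")) {
      abort_user(lab, ": unknown stimulus direction")
    }
    if (!is.finite(p$stim_magnitude_deg) || p$stim_magnitude_deg < 0) {
      abort_user(lab, ": magnitude must be >= 0 degrees")
    }
    if (p$baseline_s <= 0 || p$response_s <= 0 || p$hold_s < 0 ||
        p$transition_ms < 0) {
      abort_user(lab, ": durations must be positive")
    }
    if (p$stim_kind == "impulse" && p$hold_s > 0.01) {
      abort_user(lab, ": an impulse dwell must be <= 0.01 s")
    }
    if (p$stim_kind == "step" && p$hold_s < 1) {
      abort_user(lab, ": a step hold must be >= 1 s")
    }
  }
  invisible(protocols)
}

#' Standard step and impulse protocol tables
#'
#' `step_protocols()` builds the standard roll-step battery (each magnitude
#' in each direction, 15 s eccentric hold); `impulse_protocols()` the
#' impulse battery.
#'
#' @param magnitudes Step magnitudes in degrees.
#' @param directions Stimulus directions to include.
#' @inheritParams stim_protocol
#' @return A protocol tibble, one row per stimulus.
#' @export
#' @examples
#' step_protocols()
step_protocols <- function(magnitudes = c(10, 20, 30),
                           directions = c("ipsi", "contra"),
                           baseline_s = 10, hold_s = 15, response_s = 10) {
  do.call(rbind, lapply(directions, function(d) {
    do.call(rbind, lapply(magnitudes, function(m) {
      stim_protocol("step", d, m, baseline_s = baseline_s, hold_s = hold_s,
                    response_s = response_s)
    }))
  }))
}

#' @rdname step_protocols
#' @export
impulse_protocols <- function(magnitudes = c(10, 15, 30),
                              directions = c("ipsi", "contra"),
                              baseline_s = 10, response_s = 10) {
  do.call(rbind, lapply(directions, function(d) {
    do.call(rbind, lapply(magnitudes, function(m) {
      stim_protocol("impulse", d, m, baseline_s = baseline_s,
                    response_s = response_s)
    }))
  }))
}

#' Event times of a protocol's trial timeline
#'
#' A trial consists of a shared baseline followed by `repeats` consecutive
#' stimulus events (ramp out, hold, ramp back, response window). Returns the
#' onset (start of the outward ramp), return (end of the inward ramp, i.e.
#' the moment the platform is back at horizontal), and event-end times for
#' each repeat, plus the total trial duration as an attribute.
#'
#' @param protocol One-row protocol tibble.
#' @param repeats Number of stimulus events sharing the trial baseline.
#' @return Tibble with columns `repeat_id`, `t_onset`, `t_eccentric`,
#'   `t_return`, `t_end` (seconds from trial start).
#' @export
protocol_event_times <- function(protocol, repeats = 1) {
  stopifnot(nrow(protocol) == 1, repeats >= 1)
  tr <- protocol$transition_ms / 1000
  event_dur <- 2 * tr + protocol$hold_s + protocol$response_s
  onset <- protocol$baseline_s + (seq_len(repeats) - 1) * event_dur
  out <- tibble::tibble(
    repeat_id = seq_len(repeats),
    t_onset = onset,
    t_eccentric = onset + tr,
    t_return = onset + 2 * tr + protocol$hold_s,
    t_end = onset + event_dur
  )
  attr(out, "total_s") <- protocol$baseline_s + repeats * event_dur
  out
}

#' Generate an idealized platform trajectory
#'
#' Builds the roll-angle time series for one trial of a protocol on a fine,
#' uniform time grid: zero during baseline, a linear ramp of `transition_ms`
#' to the signed eccentric angle, the hold, a ramp back to zero, and the
#' response window; repeated `repeats` times after a single shared baseline.
#' Ipsilateral rolls are positive, contralateral negative.
#'
#' @param protocol One-row protocol tibble from [stim_protocol()].
#' @param dt Grid spacing in seconds (default 1 ms; impulses are resolved
#'   provided `dt` is no larger than the ramp duration).
#' @param repeats Number of stimulus events in the trial.
#' @return Tibble with columns `time_s` and `angle_deg`.
#' @export
#' @examples
#' w <- generate_waveform(stim_protocol("step", "ipsi", 30))
#' max(w$angle_deg)
generate_waveform <- function(protocol, dt = 0.001, repeats = 1) {
  validate_protocols(protocol)
  stopifnot(nrow(protocol) == 1, dt > 0)
  ev <- protocol_event_times(protocol, repeats)
  total <- attr(ev, "total_s")
  time_s <- seq(0, total, by = dt)
  angle <- numeric(length(time_s))
  sgn <- if (protocol$stim_direction == "ipsi") 1 else -1
  mag <- sgn * protocol$stim_magnitude_deg
  tr <- protocol$transition_ms / 1000
  for (k in seq_len(repeats)) {
    u <- time_s - ev$t_onset[k]
    if (tr > 0) {
      up <- u >= 0 & u < tr
      angle[up] <- mag * u[up] / tr
      down <- u >= tr + protocol$hold_s & u < 2 * tr + protocol$hold_s
      angle[down] <- mag * (1 - (u[down] - tr - protocol$hold_s) / tr)
    }
    at <- u >= tr & u < tr + protocol$hold_s
    angle[at] <- mag
  }
  tibble::tibble(time_s = time_s, angle_deg = angle)
}
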