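# Forward simulation: stimulus -> drive -> fluorescence -------------------
#
# The response model has two components. The tonic component follows the
# held roll angle: drive = utricle_scale * gain_ipsi * max(angle, 0) +
# gain_contra * max(-angle, 0), optionally declining linearly during the
# eccentric hold for fast-decay cells (floored at zero). The phasic
# component is a delta at the end of every rapid platform transition whose
# area is chosen so that the rendered transient peaks at `phasic_gain`,
# independent of stimulus magnitude and direction. Fluorescence is the
# unit-area double-exponential kernel convolution of the drive, scaled onto
# the baseline fluorescence, resampled at the volume rate, and corrupted
# with additive Gaussian noise.

# indices of samples ending a rapid transition, plus time-since-onset of
# each eccentric excursion (for hold-decay shaping)
stim_events <- function(angle, dt, speed_threshold = 1000) {
  n <- length(angle)
  ramp <- numeric(n)
  ecc <- abs(angle) > 1e-9
  r <- rle(ecc)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (j in which(r$values)) {
    ramp[starts[j]:ends[j]] <- (0:(ends[j] - starts[j])) * dt
  }
  event_idx <- integer(0)
  if (n > 1) {
    speed <- diff(angle) / dt
    grp <- sign(speed) * (abs(speed) > speed_threshold)
    rg <- rle(grp)
    ge <- cumsum(rg$lengths)
    event_idx <- ge[rg$values != 0] + 1L  # sample at which the motion stops
  }
  list(event_idx = event_idx, ramp = ramp)
}

as_neuron_row <- function(neuron) {
  if (is.data.frame(neuron)) {
    stopifnot(nrow(neuron) == 1)
    neuron <- as.list(neuron)
  }
  neuron
}

#' Instantaneous neural drive for a stimulus trajectory
#'
#' Maps a platform trajectory onto a single cell's instantaneous drive
#' (delta-F/F-equivalent level): the direction-specific tonic term shaped by
#' the cell's hold-decay class, plus a delta at each rapid transition for the
#' phasic term. Deltas appear as single tall samples carrying area
#' `phasic_gain / kernel_peak`, so the rendered transient peaks at
#' `phasic_gain`.
#'
#' @param waveform Tibble from [generate_waveform()] (`time_s`, `angle_deg`).
#' @param neuron One-row neuron tibble or named list (see
#'   [validate_neurons()] for the fields).
#' @param speed_threshold Angular speed (degrees/s) above which motion counts
#'   as a rapid transition.
#' @return Tibble with columns `time_s` and `drive`.
#' @export
simulate_drive <- function(waveform, neuron, speed_threshold = 1000) {
  neuron <- as_neuron_row(neuron)
  angle <- waveform$angle_deg
  dt <- median(diff(waveform$time_s))
  ev <- stim_events(angle, dt, speed_threshold)
  tonic <- neuron$utricle_scale * neuron$tonic_gain_ipsi * pmax(angle, 0) +
    neuron$tonic_gain_contra * pmax(-angle, 0)
  if (neuron$decay_class == "fast_decay" && neuron$hold_decay_rate > 0) {
    tonic <- tonic - neuron$hold_decay_rate * ev$ramp * (abs(angle) > 1e-9)
  }
  drive <- pmax(tonic, 0)
  if (neuron$phasic_gain > 0 && length(ev$event_idx) > 0) {
    k_max <- kernel_peak(neuron$rise_tau_s, neuron$decay_tau_s)$k_max
    drive[ev$event_idx] <- drive[ev$event_idx] +
      neuron$phasic_gain / k_max / dt
  }
  tibble::tibble(time_s = waveform$time_s, drive = drive)
}

#' Render sampled fluorescence from a drive time series
#'
#' Convolves the drive with the cell's unit-area double-exponential indicator
#' kernel, scales onto the baseline fluorescence
#' (`F = baseline_F * (1 + dff)`), resamples at the volume rate, and adds
#' Gaussian noise of SD `noise_sd * baseline_F` per sampled volume. With
#' `anesthetized = TRUE` all neural drive is suppressed and the trace is
#' baseline plus noise.
#'
#' @param drive Tibble from [simulate_drive()] (`time_s`, `drive`).
#' @param neuron One-row neuron tibble or named list.
#' @param sample_rate_hz Imaging volume rate (volumes per second).
#' @param seed Integer seed for the noise draw.
#' @param anesthetized If `TRUE`, suppress all drive.
#' @return Tibble with columns `time_s` and `F` at the volume rate.
#' @export
render_fluorescence <- function(drive, neuron, sample_rate_hz = 2.2,
                                seed = 1, anesthetized = FALSE) {
  neuron <- as_neuron_row(neuron)
  check_taus(neuron$rise_tau_s, neuron$decay_tau_s)
  stopifnot(sample_rate_hz > 0)
  dt <- median(diff(drive$time_s))
  if (anesthetized) {
    dffc <- numeric(nrow(drive))
  } else {
    dffc <- convolve_kernel(drive$drive, neuron$rise_tau_s,
                            neuron$decay_tau_s, dt)
  }
  total <- drive$time_s[nrow(drive)]
  t_s <- seq(0, by = 1 / sample_rate_hz, length.out = floor(total * sample_rate_hz) + 1)
  idx <- pmin(round(t_s / dt) + 1, length(dffc))
  f_clean <- neuron$baseline_F * (1 + dffc[idx])
  noise <- with_seed(seed, rnorm(length(idx), 0, neuron$noise_sd * neuron$baseline_F))
  tibble::tibble(time_s = t_s, F = f_clean + noise)
}

# default simulation grid: steps are smooth on a 5 ms grid; impulses need a
# finer grid to resolve millisecond transitions
default_sim_dt <- function(kind) ifelse(kind == "impulse", 5e-4, 5e-3)

#' Simulate a full tilt-in-place imaging session
#'
#' Batched forward simulation of a population of cells across a protocol
#' battery: for every protocol, `trials_per_magnitude` trials are recorded,
#' each with `repeats_per_trial` stimulus events sharing the trial's
#' baseline. Noise is drawn from per-(cell, protocol, trial) substreams of
#' the master seed, so identical seeds give bit-identical traces and adding
#' trials or protocols never reshuffles existing ones.
#'
#' Alongside the traces, the noise-free forward model is pushed through the
#' same trial-baseline normalization and peak-window readout to produce the
#' *implied* ground truth: per-cell implied peak responses, sensitivity
#' slopes per direction, and directionality index. These are the reference
#' values that downstream estimators should recover.
#'
#' @param neurons Neuron ground-truth tibble ([simulate_neurons()]).
#' @param protocols Protocol tibble ([step_protocols()]).
#' @param trials_per_magnitude Trials recorded per protocol row.
#' @param repeats_per_trial Stimulus events per trial (sharing one baseline).
#' @param sample_rate_hz Imaging volume rate.
#' @param seed Master seed.
#' @param anesthetized If `TRUE`, all neural gains are suppressed.
#' @param mount_roll_jitter_deg SD of a per-session roll offset added to the
#'   platform angle (0 disables mounting jitter).
#' @param age_dpf,session_id Metadata attached to every trace row.
#' @param dt Simulation grid spacing override (seconds); by default 5 ms for
#'   steps and 0.5 ms for impulses.
#' @param ground_truth Compute implied ground truth (slightly more work).
#' @return An object of class `tipm_sim`: a list with `traces` (tidy trace
#'   tibble), `neurons`, `truth` (per-cell implied slopes/DI, or `NULL`),
#'   `truth_peaks` (implied noise-free peak per cell/protocol/repeat),
#'   `protocols`, and `params`.
#' @export
#' @examples
#' sim <- simulate_experiment(simulate_neurons(3, seed = 1),
#'                            step_protocols(magnitudes = c(10, 30)),
#'                            trials_per_magnitude = 2, seed = 5)
#' head(sim$traces)
simulate_experiment <- function(neurons,
                                protocols = step_protocols(),
                                trials_per_magnitude = 3,
                                repeats_per_trial = 2,
                                sample_rate_hz = 2.2,
                                seed = 1,
                                anesthetized = FALSE,
                                mount_roll_jitter_deg = 0,
                                age_dpf = 4,
                                session_id = "s01",
                                dt = NULL,
                                ground_truth = TRUE) {
  validate_neurons(neurons)
  validate_protocols(protocols)
  stopifnot(trials_per_magnitude >= 1, repeats_per_trial >= 1,
            sample_rate_hz > 0)
  n_cells <- nrow(neurons)
  roll_offset <- if (mount_roll_jitter_deg > 0) {
    with_seed(mix_seed(seed, 7), rnorm(1, 0, mount_roll_jitter_deg))
  } else 0
  tau_key <- paste(neurons$rise_tau_s, neurons$decay_tau_s)
  k_max <- vapply(seq_len(n_cells), function(j) {
    kernel_peak(neurons$rise_tau_s[j], neurons$decay_tau_s[j])$k_max
  }, numeric(1))
  gain_i <- neurons$utricle_scale * neurons$tonic_gain_ipsi
  gain_c <- neurons$tonic_gain_contra
  d_rate <- ifelse(neurons$decay_class == "fast_decay",
                   neurons$hold_decay_rate, 0)

  trace_pieces <- list()
  truth_pieces <- list()
  for (pi in seq_len(nrow(protocols))) {
    p <- protocols[pi, ]
    dt_p <- dt %||% default_sim_dt(p$stim_kind)
    wave <- generate_waveform(p, dt = dt_p, repeats = repeats_per_trial)
    ev_times <- protocol_event_times(p, repeats_per_trial)
    angle_stim <- wave$angle_deg
    angle_tot <- angle_stim + roll_offset
    nt <- length(angle_tot)
    ev <- stim_events(angle_stim, dt_p)

    if (anesthetized) {
      dffc <- matrix(0, nt, n_cells)
    } else {
      pos <- pmax(angle_tot, 0)
      neg <- pmax(-angle_tot, 0)
      D <- outer(pos, gain_i)
      if (any(neg > 0)) D <- D + outer(neg, gain_c)
      if (any(d_rate > 0)) {
        hold <- ev$ramp * (abs(angle_stim) > 1e-9)
        D <- D - outer(hold, d_rate)
      }
      D <- pmax(D, 0)
      if (length(ev$event_idx) > 0) {
        add <- neurons$phasic_gain / k_max / dt_p
        D[ev$event_idx, ] <- D[ev$event_idx, , drop = FALSE] +
          rep(add, each = length(ev$event_idx))
      }
      dffc <- matrix(0, nt, n_cells)
      for (key in unique(tau_key)) {
        cols <- which(tau_key == key)
        dffc[, cols] <- convolve_kernel(D[, cols, drop = FALSE],
                                        neurons$rise_tau_s[cols[1]],
                                        neurons$decay_tau_s[cols[1]], dt_p)
      }
    }

    total <- wave$time_s[nt]
    t_s <- seq(0, by = 1 / sample_rate_hz,
               length.out = floor(total * sample_rate_hz) + 1)
    idx <- pmin(round(t_s / dt_p) + 1, nt)
    ns <- length(t_s)
    dffc_s <- dffc[idx, , drop = FALSE]
    f_clean <- sweep(1 + dffc_s, 2, neurons$baseline_F, `*`)
    seg <- findInterval(t_s, ev_times$t_onset)  # 0 = baseline, k = event k

    if (ground_truth) {
      f0_rows <- which(t_s >= p$baseline_s - 5 & t_s < p$baseline_s)
      m <- colMeans(dffc_s[f0_rows, , drop = FALSE])
      for (k in seq_len(repeats_per_trial)) {
        w_rows <- which(t_s >= ev_times$t_return[k] &
                          t_s < ev_times$t_return[k] + 1)
        pk <- (colMeans(dffc_s[w_rows, , drop = FALSE]) - m) / (1 + m)
        truth_pieces[[length(truth_pieces) + 1]] <- tibble::tibble(
          cell_id = neurons$cell_id,
          stim_kind = p$stim_kind, stim_direction = p$stim_direction,
          stim_magnitude_deg = p$stim_magnitude_deg,
          repeat_id = k, implied_peak = pk
        )
      }
    }

    for (trial in seq_len(trials_per_magnitude)) {
      noise <- matrix(0, ns, n_cells)
      for (j in seq_len(n_cells)) {
        s <- mix_seed(seed, j, pi, trial)
        noise[, j] <- with_seed(s, rnorm(ns, 0,
                                         neurons$noise_sd[j] * neurons$baseline_F[j]))
      }
      trial_id <- sprintf("%s_%s_%02ddeg_tr%d", p$stim_kind, p$stim_direction,
                          round(p$stim_magnitude_deg), trial)
      trace_pieces[[length(trace_pieces) + 1]] <- tibble::tibble(
        fish_id = rep(neurons$fish_id, each = ns),
        cell_id = rep(neurons$cell_id, each = ns),
        session_id = session_id,
        age_dpf = age_dpf,
        trial_id = trial_id,
        repeat_id = rep(seg, n_cells),
        stim_kind = p$stim_kind,
        stim_direction = p$stim_direction,
        stim_magnitude_deg = p$stim_magnitude_deg,
        time_s = rep(t_s, n_cells),
        F = as.vector(f_clean + noise),
        baseline_s = p$baseline_s,
        hold_s = p$hold_s,
        response_s = p$response_s,
        transition_ms = p$transition_ms
      )
    }
  }

  traces <- dplyr::bind_rows(trace_pieces)
  truth_peaks <- if (ground_truth) dplyr::bind_rows(truth_pieces) else NULL
  truth <- if (ground_truth) implied_truth(truth_peaks) else NULL
  structure(list(traces = traces, neurons = neurons, truth = truth,
                 truth_peaks = truth_peaks, protocols = protocols,
                 params = list(trials_per_magnitude = trials_per_magnitude,
                               repeats_per_trial = repeats_per_trial,
                               sample_rate_hz = sample_rate_hz, seed = seed,
                               anesthetized = anesthetized,
                               mount_roll_offset_deg = roll_offset,
                               age_dpf = age_dpf, session_id = session_id)),
            class = "tipm_sim")
}

# per-cell implied (noise-free) slopes and directionality index
implied_truth <- function(truth_peaks) {
  steps <- dplyr::filter(truth_peaks, stim_kind == "step")
  slope_one <- function(d) {
    if (nrow(d) < 2 || length(unique(d$stim_magnitude_deg)) < 2) {
      return(NA_real_)
    }
    slope_fit(d$stim_magnitude_deg, d$implied_peak)$slope
  }
  slopes <- steps |>
    dplyr::group_by(cell_id, stim_direction) |>
    dplyr::summarise(slope = slope_one(dplyr::pick(dplyr::everything())),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = stim_direction, values_from = slope,
                       names_prefix = "slope_implied_")
  di <- steps |>
    dplyr::filter(stim_magnitude_deg == 30) |>
    dplyr::group_by(cell_id, stim_direction) |>
    dplyr::summarise(peak = mean(implied_peak), .groups = "drop") |>
    tidyr::pivot_wider(names_from = stim_direction, values_from = peak,
                       names_prefix = "peak30_")
  out <- dplyr::full_join(slopes, di, by = "cell_id")
  if (all(c("peak30_ipsi", "peak30_contra") %in% names(out))) {
    out$di_implied <- directionality_index(out$peak30_ipsi, out$peak30_contra)
  }
  out
}

#' @export
print.tipm_sim <- function(x, ...) {
  cat("<tipm_sim>", nrow(x$neurons), "cells,",
      nrow(x$protocols), "protocols,",
      length(unique(x$traces$trial_id)), "trials,",
      nrow(x$traces), "trace samples\n")
  invisible(x)
}

#' Per-cell baseline fluorescence from an anesthetized recording
#'
#' Summarizes an anesthetized session into one baseline fluorescence value
#' per cell (the mean of the whole trace), for use as the `f0` source of the
#' anesthetized-baseline normalization scheme.
#'
#' @param traces A trace tibble from an anesthetized [simulate_experiment()]
#'   run (or real data in the same layout).
#' @return Tibble with columns `cell_id` and `f0`.
#' @export
anesthetized_f0 <- function(traces) {
  traces |>
    dplyr::group_by(cell_id) |>
    dplyr::summarise(f0 = mean(F), .groups = "drop")
}
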