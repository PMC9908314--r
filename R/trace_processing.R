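# delta-F/F normalization and per-trial response extraction ---------------

TRACE_KEY <- c("fish_id", "cell_id", "session_id", "age_dpf", "trial_id")

check_trace_cols <- function(traces) {
  need <- c(TRACE_KEY, "repeat_id", "stim_kind", "stim_direction",
            "stim_magnitude_deg", "time_s", "F",
            "baseline_s", "hold_s", "response_s", "transition_ms")
  missing_cols <- setdiff(need, names(traces))
  if (length(missing_cols) > 0) {
    abort_user("trace table lacks columns: ",
               paste(missing_cols, collapse = ", "))
  }
  invisible(traces)
}

#' Normalize fluorescence traces to delta-F/F
#'
#' Two schemes are supported. `trial_baseline` (the standard paradigm when
#' every trial is imaged at horizontal) divides by the mean fluorescence over
#' the last 5 s of that trial's baseline period. `anesthetized_baseline`
#' (required when comparing recordings made at different orientations, where
#' the light path differs) divides by a per-cell baseline measured in a
#' matched anesthetized recording at the same angle, supplied via `f0`.
#'
#' @param traces Trace tibble (see [simulate_experiment()] for the layout).
#' @param scheme `"trial_baseline"` or `"anesthetized_baseline"`.
#' @param f0 For the anesthetized scheme: a tibble with columns `cell_id`
#'   and `f0` (see [anesthetized_f0()]).
#' @return The trace tibble with added columns `f0`, `dff`
#'   (`(F - f0) / f0`), and `norm_scheme`.
#' @export
normalize_traces <- function(traces,
                             scheme = c("trial_baseline",
                                        "anesthetized_baseline"),
                             f0 = NULL) {
  scheme <- match.arg(scheme)
  check_trace_cols(traces)
  if (scheme == "trial_baseline") {
    short <- traces$baseline_s < 5
    if (any(short)) {
      abort_user("trial-baseline normalization needs a baseline of >= 5 s; ",
                 "trial ", traces$trial_id[which(short)[1]], " has ",
                 traces$baseline_s[which(short)[1]], " s")
    }
    out <- traces |>
      dplyr::group_by(dplyr::across(dplyr::all_of(TRACE_KEY))) |>
      dplyr::mutate(f0 = mean(F[time_s >= baseline_s - 5 &
                                  time_s < baseline_s])) |>
      dplyr::ungroup()
  } else {
    if (is.null(f0) || !all(c("cell_id", "f0") %in% names(f0))) {
      abort_user("anesthetized-baseline normalization requires an f0 table ",
                 "with columns cell_id and f0")
    }
    out <- dplyr::left_join(traces, f0[, c("cell_id", "f0")], by = "cell_id")
    if (anyNA(out$f0)) {
      miss <- unique(out$cell_id[is.na(out$f0)])
      abort_user("no anesthetized f0 for cell(s): ",
                 paste(head(miss, 3), collapse = ", "))
    }
  }
  if (any(out$f0 <= 0)) {
    bad <- out[out$f0 <= 0, ]
    abort_user("non-positive F0 for cell ", bad$cell_id[1],
               " trial ", bad$trial_id[1])
  }
  out$dff <- (out$F - out$f0) / out$f0
  out$norm_scheme <- scheme
  out
}

#' Extract per-trial scalar peak responses
#'
#' Computes, for every (cell, trial, stimulus repeat), the mean delta-F/F
#' over a 1 s readout window keyed to the stimulus log (not to trace
#' features): `post_return_first_1s` is the first second after the platform
#' returns to horizontal (the standard peak response), `eccentric_last_1s`
#' the last second before the return (for recordings made at the eccentric
#' angle). Windows are half-open `[start, start + 1)` over sample
#' timestamps. Also records the mean delta-F/F over the first second of the
#' trial's baseline, the paired reference for responsiveness testing.
#'
#' @param ntraces Normalized trace tibble from [normalize_traces()].
#' @param window `"post_return_first_1s"` or `"eccentric_last_1s"`.
#' @return A peak-response tibble: one row per (cell, trial, repeat) with
#'   `peak_response`, `baseline_dff`, `n_samples`, and `window`.
#' @export
extract_peaks <- function(ntraces,
                          window = c("post_return_first_1s",
                                     "eccentric_last_1s")) {
  window <- match.arg(window)
  check_trace_cols(ntraces)
  if (!"dff" %in% names(ntraces)) {
    abort_user("traces must be normalized first (no dff column); ",
               "see normalize_traces()")
  }
  tr <- ntraces$transition_ms / 1000
  # return time of the repeat each sample belongs to (NA during baseline)
  event_dur <- 2 * tr + ntraces$hold_s + ntraces$response_s
  t_return <- ntraces$baseline_s + (ntraces$repeat_id - 1) * event_dur +
    2 * tr + ntraces$hold_s
  in_win <- if (window == "post_return_first_1s") {
    ntraces$repeat_id > 0 & ntraces$time_s >= t_return &
      ntraces$time_s < t_return + 1
  } else {
    ntraces$repeat_id > 0 & ntraces$time_s >= t_return - 1 &
      ntraces$time_s < t_return
  }
  base <- ntraces |>
    dplyr::filter(repeat_id == 0, time_s < 1) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(TRACE_KEY))) |>
    dplyr::summarise(baseline_dff = mean(dff), .groups = "drop")
  peaks <- ntraces[in_win, ] |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(
      TRACE_KEY, "repeat_id", "stim_kind", "stim_direction",
      "stim_magnitude_deg")))) |>
    dplyr::summarise(peak_response = mean(dff),
                     n_samples = dplyr::n(),
                     f0 = f0[1], .groups = "drop")
  n_expected <- ntraces |>
    dplyr::distinct(dplyr::across(dplyr::all_of(TRACE_KEY))) |>
    nrow()
  n_repeats <- max(ntraces$repeat_id)
  if (nrow(peaks) < n_expected * n_repeats) {
    rate <- 1 / median(diff(ntraces$time_s[ntraces$cell_id ==
                                             ntraces$cell_id[1] &
                                             ntraces$trial_id ==
                                             ntraces$trial_id[1]]))
    abort_user("some trials have no samples in the ", window,
               " window at a sample rate of ", signif(rate, 3), " Hz")
  }
  out <- dplyr::left_join(peaks, base, by = TRACE_KEY)
  out$window <- window
  out
}

#' Test per-cell stimulus responsiveness
#'
#' For each cell and stimulus (kind, direction, magnitude), tests whether
#' peak responses across trials are significantly higher than the mean
#' delta-F/F during the first second of the baseline period of the same
#' cell, with a one-tailed t test at alpha 0.05. Repeats within a trial are
#' averaged so that the paired test compares independent trial-level values;
#' an unpaired two-sample variant is available via `paired = FALSE`. Cells
#' with fewer than 2 trials are flagged untestable rather than tested.
#'
#' @param peaks Peak-response tibble from [extract_peaks()].
#' @param paired Pair peaks with their own trial's baseline (default) or use
#'   a two-sample test.
#' @param alpha Significance level.
#' @return Tibble with one row per (cell, stimulus): `n_trials`, `p`,
#'   `responsive`, `testable`.
#' @export
responsiveness_test <- function(peaks, paired = TRUE, alpha = 0.05) {
  one <- function(d) {
    bytrial <- d |>
      dplyr::group_by(trial_id) |>
      dplyr::summarise(peak = mean(peak_response),
                       base = mean(baseline_dff), .groups = "drop")
    n <- nrow(bytrial)
    if (n < 2) {
      return(tibble::tibble(n_trials = n, p = NA_real_,
                            responsive = NA, testable = FALSE))
    }
    if (paired) {
      diffs <- bytrial$peak - bytrial$base
      p <- if (sd(diffs) == 0) {
        if (mean(diffs) > 0) 0 else 1
      } else {
        t.test(bytrial$peak, bytrial$base, paired = TRUE,
               alternative = "greater")$p.value
      }
    } else {
      p <- if (sd(bytrial$peak) == 0 && sd(bytrial$base) == 0) {
        if (mean(bytrial$peak) > mean(bytrial$base)) 0 else 1
      } else {
        t.test(bytrial$peak, bytrial$base, alternative = "greater")$p.value
      }
    }
    tibble::tibble(n_trials = n, p = p, responsive = p < alpha,
                   testable = TRUE)
  }
  peaks |>
    dplyr::group_by(cell_id, stim_kind, stim_direction,
                    stim_magnitude_deg) |>
    dplyr::reframe(one(dplyr::pick(dplyr::everything())))
}

#' Coefficient of variation of per-trial peaks
#'
#' Sample standard deviation divided by the mean. Undefined (NA) when fewer
#' than 2 values are given or when the mean is numerically zero, in which
#' case downstream summaries should treat the cell as flagged rather than
#' zero-variability.
#'
#' @param x Numeric vector of per-trial peak responses for one cell.
#' @return A single numeric CV, or `NA`.
#' @export
#' @examples
#' trial_cv(c(1, 2, 3))  # sample SD 1, mean 2 -> 0.5
trial_cv <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) return(NA_real_)
  m <- mean(x)
  if (abs(m) < 1e-12 * max(1, sd(x))) return(NA_real_)
  sd(x) / m
}

#' Response dynamics during the eccentric hold
#'
#' For recordings made at the eccentric angle (anesthetized-baseline
#' normalization), summarizes each cell's hold dynamics: the time from hold
#' onset to the delta-F/F maximum, and the least-squares decay slope of
#' delta-F/F versus time from that peak to the end of the hold. Plateau-like
#' cells yield slopes near zero and late peaks; fast-decay cells yield
#' early peaks and negative slopes. Values are computed per (trial, repeat)
#' and averaged within cell.
#'
#' @param ntraces Normalized trace tibble (must use the
#'   anesthetized-baseline scheme, since trial-baseline windows are not
#'   comparable across orientations).
#' @param min_hold_s Minimum eccentric hold length (seconds).
#' @return Tibble with one row per cell: `time_to_peak_s`, `decay_slope`
#'   (delta-F/F per second), `n_events`.
#' @export
eccentric_dynamics <- function(ntraces, min_hold_s = 10) {
  check_trace_cols(ntraces)
  if (!"dff" %in% names(ntraces)) {
    abort_user("traces must be normalized first; see normalize_traces()")
  }
  if (any(ntraces$norm_scheme != "anesthetized_baseline")) {
    abort_user("eccentric dynamics require anesthetized-baseline ",
               "normalization (light path differs across orientations)")
  }
  if (any(ntraces$hold_s < min_hold_s)) {
    abort_user("eccentric hold shorter than ", min_hold_s,
               " s; dynamics are not identifiable")
  }
  tr <- ntraces$transition_ms / 1000
  event_dur <- 2 * tr + ntraces$hold_s + ntraces$response_s
  t_ecc <- ntraces$baseline_s + (ntraces$repeat_id - 1) * event_dur + tr
  t_return <- t_ecc + ntraces$hold_s
  hold_rows <- ntraces$repeat_id > 0 & ntraces$time_s >= t_ecc &
    ntraces$time_s < t_return
  one <- function(d) {
    i_pk <- which.max(d$dff)
    ttp <- d$time_s[i_pk] - d$t_ecc[1]
    tail_rows <- i_pk:nrow(d)
    slope <- if (length(tail_rows) < 2) {
      NA_real_
    } else {
      slope_fit(d$time_s[tail_rows], d$dff[tail_rows])$slope
    }
    tibble::tibble(time_to_peak_s = ttp, decay_slope = slope)
  }
  ntraces[hold_rows, ] |>
    dplyr::mutate(t_ecc = t_ecc[hold_rows]) |>
    dplyr::group_by(cell_id, trial_id, repeat_id) |>
    dplyr::reframe(one(dplyr::pick(dplyr::everything()))) |>
    dplyr::group_by(cell_id) |>
    dplyr::summarise(time_to_peak_s = mean(time_to_peak_s),
                     decay_slope = mean(decay_slope, na.rm = TRUE),
                     n_events = dplyr::n(), .groups = "drop")
}
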