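# Plain-file interfaces ----------------------------------------------------

#' Write / read a trace table as tidy CSV
#'
#' Columns: `fish_id, cell_id, session_id, age_dpf, trial_id, repeat_id,
#' stim_kind, stim_direction, stim_magnitude_deg, time_s, F` plus the
#' stimulus-timing provenance columns (`baseline_s, hold_s, response_s,
#' transition_ms`) needed to key analysis windows to the stimulus log.
#' Floats are written at full (round-trip) precision.
#'
#' @param traces Trace tibble.
#' @param path CSV path.
#' @return `path` (write) or the trace tibble (read).
#' @export
write_traceset <- function(traces, path) {
  check_trace_cols(traces)
  cols <- c("fish_id", "cell_id", "session_id", "age_dpf", "trial_id",
            "repeat_id", "stim_kind", "stim_direction", "stim_magnitude_deg",
            "time_s", "F", "baseline_s", "hold_s", "response_s",
            "transition_ms")
  readr::write_csv(traces[, cols], path)
  invisible(path)
}

#' @rdname write_traceset
#' @export
read_traceset <- function(path) {
  tr <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          fish_id = "c", cell_id = "c", session_id = "c",
                          trial_id = "c", stim_kind = "c",
                          stim_direction = "c"))
  check_trace_cols(tr)
  tr
}

#' Write simulation ground truth as JSON
#'
#' Stores the per-cell generative parameters together with the implied
#' measurement-level ground truth (slopes per direction and directionality
#' index of the noise-free forward model).
#'
#' @param sim A `tipm_sim` object from [simulate_experiment()].
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(sim, path) {
  stopifnot(inherits(sim, "tipm_sim"))
  truth <- list(neurons = sim$neurons, implied = sim$truth,
                params = sim$params)
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
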