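# End-to-end pipeline ------------------------------------------------------
#
# run_all() orchestrates simulate -> extract -> tune -> longitudinal -> qc.
# Stages communicate only through the documented CSV/JSON files in the
# output directory, so each stage can be re-run or tested from files, and a
# fixed seed makes the whole run byte-identical (no timestamps are written).

#' Default pipeline configuration
#'
#' Returns the demo configuration as a nested list: a 70-cell population
#' imaged at two ages with the standard step battery (10/20/30 degrees, both
#' directions, three trials per step size, two stimulus repeats per trial,
#' 15 s hold, 2.2 volumes/s), a 1000-shuffle longitudinal classifier, and a
#' small registration/geometry QC block. Override any entry via the YAML
#' file passed to [read_run_config()] or by editing the list.
#'
#' @return Nested configuration list.
#' @export
default_run_config <- function() {
  list(
    seed = 7,
    population = list(
      n_cells = 70, cells_per_fish = 7,
      slope_ipsi_mean = 0.07, slope_ipsi_sd = 0.06,
      slope_contra_mean = 0.02, slope_contra_sd = 0.02,
      phasic_sd = 0.35, plateau_fraction = 0.5,
      noise_sd = 0.35, utricle_scale = 1
    ),
    stimulus = list(
      step_magnitudes = c(10, 20, 30),
      impulse_magnitudes = numeric(0),
      baseline_s = 10, hold_s = 15, response_s = 10,
      trials_per_magnitude = 3, repeats_per_trial = 2,
      sample_rate_hz = 2.2
    ),
    development = list(
      age1_dpf = 4, age2_dpf = 7,
      p_increase_ipsi = 14 / 70, p_decrease_ipsi = 3 / 70,
      increase_amount = 0.15, decrease_amount = 0.05,
      contra_tuned_fraction = 24 / 70,
      p_decrease_contra_tuned = 11 / 24,
      p_increase_contra_nontuned = 8 / 46,
      contra_increase_amount = 0.05
    ),
    longitudinal = list(n_shuffles = 1000),
    qc = list(frame_shift_px = c(3, -2), frame_size = 64,
              pixel_size_um = 1, mount_dz_um = 7.2)
  )
}

#' Read a pipeline configuration from YAML
#'
#' Entries missing from the file fall back to [default_run_config()].
#'
#' @param path YAML file path.
#' @return Nested configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort_user("config file not found: ", path)
  user <- yaml::read_yaml(path)
  utils::modifyList(default_run_config(), user)
}

#' Run the full synthetic TIPM pipeline
#'
#' Simulates a two-age longitudinal imaging experiment, extracts
#' delta-F/F peak responses, summarizes per-cell tuning, classifies
#' developmental sensitivity changes against the shuffle null, and runs the
#' imaging/mounting QC. All stage outputs are plain CSV/JSON files under
#' `out_dir`; a manifest records every output file, row counts, and every
#' excluded cell with its reason. Given the same configuration and seed the
#' outputs are byte-identical across runs.
#'
#' @param config A configuration list ([default_run_config()]) or the path
#'   to a YAML file ([read_run_config()]).
#' @param out_dir Output directory (created if needed).
#' @return The manifest (also written to `manifest.json`), invisibly.
#' @export
run_all <- function(config = default_run_config(), out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  manifest <- list(seed = seed, stages = list())
  out <- function(...) file.path(out_dir, ...)

  cfg_path <- out("config_resolved.yaml")
  yaml::write_yaml(config, cfg_path)
  manifest$config_md5 <- unname(tools::md5sum(cfg_path))

  # -- stage 1: simulate --------------------------------------------------
  pop <- config$population
  stim <- config$stimulus
  dev <- config$development
  protocols <- step_protocols(magnitudes = stim$step_magnitudes,
                              baseline_s = stim$baseline_s,
                              hold_s = stim$hold_s,
                              response_s = stim$response_s)
  if (length(stim$impulse_magnitudes) > 0) {
    protocols <- dplyr::bind_rows(
      protocols,
      impulse_protocols(magnitudes = stim$impulse_magnitudes,
                        baseline_s = stim$baseline_s,
                        response_s = stim$response_s))
  }
  neurons1 <- simulate_neurons(
    n = pop$n_cells, cells_per_fish = pop$cells_per_fish,
    slope_ipsi_mean = pop$slope_ipsi_mean, slope_ipsi_sd = pop$slope_ipsi_sd,
    slope_contra_mean = pop$slope_contra_mean,
    slope_contra_sd = pop$slope_contra_sd,
    phasic_sd = pop$phasic_sd, plateau_fraction = pop$plateau_fraction,
    noise_sd = pop$noise_sd, utricle_scale = pop$utricle_scale,
    hold_s = stim$hold_s, seed = mix_seed(seed, 1))
  neurons2 <- develop_neurons(
    neurons1, p_increase_ipsi = dev$p_increase_ipsi,
    p_decrease_ipsi = dev$p_decrease_ipsi,
    increase_amount = dev$increase_amount,
    decrease_amount = dev$decrease_amount,
    contra_tuned_fraction = dev$contra_tuned_fraction,
    p_decrease_contra_tuned = dev$p_decrease_contra_tuned,
    p_increase_contra_nontuned = dev$p_increase_contra_nontuned,
    contra_increase_amount = dev$contra_increase_amount,
    hold_s = stim$hold_s, seed = mix_seed(seed, 2))
  run_sim <- function(neurons, age, tag) {
    simulate_experiment(neurons, protocols,
                        trials_per_magnitude = stim$trials_per_magnitude,
                        repeats_per_trial = stim$repeats_per_trial,
                        sample_rate_hz = stim$sample_rate_hz,
                        seed = mix_seed(seed, 10 + age),
                        age_dpf = age, session_id = tag)
  }
  sim1 <- run_sim(neurons1, dev$age1_dpf, "age1")
  sim2 <- run_sim(neurons2, dev$age2_dpf, "age2")
  write_traceset(sim1$traces, out("traces_age1.csv"))
  write_traceset(sim2$traces, out("traces_age2.csv"))
  write_ground_truth(sim1, out("ground_truth_age1.json"))
  write_ground_truth(sim2, out("ground_truth_age2.json"))
  manifest$stages$simulate <- list(
    outputs = c("traces_age1.csv", "traces_age2.csv",
                "ground_truth_age1.json", "ground_truth_age2.json"),
    n_cells = nrow(neurons1),
    n_trace_rows = c(age1 = nrow(sim1$traces), age2 = nrow(sim2$traces)),
    exclusions = list())

  # -- stage 2: extract ---------------------------------------------------
  peaks1 <- extract_peaks(normalize_traces(sim1$traces, "trial_baseline"))
  peaks2 <- extract_peaks(normalize_traces(sim2$traces, "trial_baseline"))
  readr::write_csv(peaks1, out("peaks_age1.csv"))
  readr::write_csv(peaks2, out("peaks_age2.csv"))
  manifest$stages$extract <- list(
    outputs = c("peaks_age1.csv", "peaks_age2.csv"),
    n_rows = c(age1 = nrow(peaks1), age2 = nrow(peaks2)),
    exclusions = list())

  # -- stage 3: tune ------------------------------------------------------
  nsh <- config$longitudinal$n_shuffles
  tuning1 <- tune_cells(peaks1, n_shuffles = nsh, seed = mix_seed(seed, 31))
  tuning2 <- tune_cells(peaks2, n_shuffles = nsh, seed = mix_seed(seed, 32))
  readr::write_csv(tuning1, out("tuning_age1.csv"))
  readr::write_csv(tuning2, out("tuning_age2.csv"))
  manifest$stages$tune <- list(
    outputs = c("tuning_age1.csv", "tuning_age2.csv"),
    n_rows = c(age1 = nrow(tuning1), age2 = nrow(tuning2)),
    exclusions = list())

  # -- stage 4: longitudinal ---------------------------------------------
  changes <- classify_population(peaks1, peaks2, n_shuffles = nsh,
                                 seed = mix_seed(seed, 41))
  labels <- early_tuned_labels(peaks1, n_shuffles = nsh,
                               seed = mix_seed(seed, 42))
  split <- early_tuned_split(changes, labels)
  corr <- change_correlation(changes)
  readr::write_csv(changes, out("changes.csv"))
  readr::write_csv(labels, out("early_tuned_labels.csv"))
  excl <- changes[!is.na(changes$excluded),
                  c("cell_id", "direction", "excluded")]
  counts <- changes |>
    dplyr::filter(is.na(excluded)) |>
    dplyr::count(direction, category)
  summary <- list(category_counts = counts,
                  ks_tests = split$tests,
                  change_correlation = corr)
  jsonlite::write_json(summary, out("longitudinal_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest$stages$longitudinal <- list(
    outputs = c("changes.csv", "early_tuned_labels.csv",
                "longitudinal_summary.json"),
    n_rows = nrow(changes),
    exclusions = lapply(seq_len(nrow(excl)), function(i) {
      list(cell_id = excl$cell_id[i], direction = excl$direction[i],
           reason = excl$excluded[i])
    }))

  # -- stage 5: qc --------------------------------------------------------
  qc_cfg <- config$qc
  pair <- generate_frame_pair(qc_cfg$frame_shift_px,
                              size = qc_cfg$frame_size,
                              seed = mix_seed(seed, 51))
  write_frame_pair(pair, out("frame_pair.tif"))
  fs <- frame_shift(pair$pre, pair$post,
                    pixel_size_um = qc_cfg$pixel_size_um)
  mount <- tibble::tibble(
    cell_id = "mauthner", hemisphere = c("left", "right"),
    x_um = c(-171.8 / 2, 171.8 / 2), y_um = 0,
    z_um = c(qc_cfg$mount_dz_um, 0))
  orient <- mount_orientation(mount)
  resp <- tuning1[, c("cell_id", "responsive30_ipsi")]
  names(resp)[2] <- "responsive"
  pos_cmp <- position_group_compare(
    neurons1[, c("cell_id", "x_um", "y_um", "z_um")], resp)
  qc_out <- list(
    frame_shift = list(true_shift_px = pair$shift_px,
                       recovered_shift_px = fs$shift_px,
                       dx_um = fs$dx_um, dy_um = fs$dy_um,
                       r_zero_shift = fs$r_zero_shift,
                       low_confidence = fs$low_confidence),
    mount = orient,
    position_comparison = pos_cmp)
  jsonlite::write_json(qc_out, out("qc.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest$stages$qc <- list(
    outputs = c("frame_pair.tif", "frame_pair.json", "qc.json"),
    exclusions = list())

  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
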