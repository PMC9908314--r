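# Synthetic neuron ground truth -------------------------------------------
#
# Each simulated cell carries the parameters of its response model:
#  * tonic gains (drive delta-F/F per degree of roll, one per direction),
#    with the ipsilateral gain additionally scaled by `utricle_scale` to
#    emulate loss of the utricular otolith;
#  * a phasic gain (peak delta-F/F of the transient evoked by each rapid
#    platform transition, independent of magnitude and direction);
#  * a hold decay class: "plateau" cells sustain their tonic drive for the
#    whole eccentric hold, "fast_decay" cells ramp it down linearly at
#    `hold_decay_rate` delta-F/F per second (floored at zero);
#  * indicator kernel taus, a baseline fluorescence level, and an additive
#    Gaussian noise SD expressed as a fraction of baseline fluorescence;
#  * a soma position (micrometers) relative to the ipsilateral Mauthner
#    lateral dendrite tip (+x lateral, +y rostral, +z dorsal).

NEURON_COLS <- c("cell_id", "fish_id", "hemisphere", "tonic_gain_ipsi",
                 "tonic_gain_contra", "phasic_gain", "decay_class",
                 "hold_decay_rate", "rise_tau_s", "decay_tau_s", "noise_sd",
                 "baseline_F", "utricle_scale", "x_um", "y_um", "z_um")

#' Validate a neuron ground-truth table
#'
#' @param neurons Tibble with one row per simulated cell.
#' @return The input, invisibly; errors name the offending cell.
#' @export
validate_neurons <- function(neurons) {
  missing_cols <- setdiff(NEURON_COLS, names(neurons))
  if (length(missing_cols) > 0) {
    abort_user("neuron table lacks columns: ",
               paste(missing_cols, collapse = ", "))
  }
  bad <- function(cond, what) {
    if (any(cond)) {
      abort_user("invalid neuron ground truth (", what, "): ",
                 paste(head(neurons$cell_id[cond], 3), collapse = ", "))
    }
  }
  bad(neurons$tonic_gain_ipsi < 0 | neurons$tonic_gain_contra < 0 |
        neurons$phasic_gain < 0, "gains must be >= 0")
  bad(neurons$noise_sd < 0, "noise_sd must be >= 0")
  bad(neurons$baseline_F <= 0, "baseline_F must be > 0")
  bad(neurons$utricle_scale < 0 | neurons$utricle_scale > 1,
      "utricle_scale must lie in [0, 1]")
  bad(!neurons$decay_class %in% c("plateau", "fast_decay"),
      "decay_class must be plateau or fast_decay")
  bad(neurons$hold_decay_rate < 0, "hold_decay_rate must be >= 0")
  bad(neurons$rise_tau_s <= 0 | neurons$decay_tau_s <= 0 |
        neurons$decay_tau_s <= neurons$rise_tau_s,
      "kernel taus must satisfy 0 < rise < decay")
  if (anyDuplicated(neurons$cell_id)) abort_user("duplicate cell_id values")
  invisible(neurons)
}

#' Simulate a population of vestibulospinal-like neurons
#'
#' Draws per-cell ground-truth parameters. Tuning strength is parameterized
#' in *measured-slope* units (delta-F/F per degree of the post-return peak
#' response, the unit in which roll sensitivity is reported); the
#' corresponding drive gains are obtained by dividing by the analytic
#' [readout_factor()] of the indicator kernel. Defaults emulate a population
#' with mean ipsilateral sensitivity 0.07 and contralateral sensitivity
#' 0.02 delta-F/F per degree, a mix of plateau and fast-decay hold dynamics,
#' and mostly weak, nondirectional phasic responses; cells with strong
#' phasic gains are placed more ventrally than the rest of the population.
#'
#' @param n Number of cells.
#' @param slope_ipsi_mean,slope_ipsi_sd Normal parameters of the ipsilateral
#'   sensitivity slope (delta-F/F per degree), truncated below at
#'   `slope_floor`.
#' @param slope_contra_mean,slope_contra_sd Same for the contralateral slope.
#' @param slope_floor Lower truncation for drawn slopes.
#' @param phasic_sd Half-normal SD of the phasic gain (peak delta-F/F per
#'   transition event).
#' @param plateau_fraction Fraction of cells with plateau hold dynamics.
#' @param hold_decay_frac_range For fast-decay cells, the uniform range of
#'   the fraction of the cell's own 10-degree ipsilateral tonic drive lost
#'   over a full hold; the per-cell absolute rate (delta-F/F per second) is
#'   scaled accordingly, so decay is visible without annihilating weak
#'   responses.
#' @param noise_sd Additive Gaussian noise SD, as a fraction of baseline
#'   fluorescence (so delta-F/F noise SD is approximately `noise_sd`).
#' @param baseline_F Baseline fluorescence level (arbitrary units).
#' @param rise_tau_s,decay_tau_s Indicator kernel time constants (seconds);
#'   defaults are literature-typical for a slow indicator such as GCaMP6s.
#' @param utricle_scale Multiplier in `[0, 1]` applied to the ipsilateral
#'   tonic gain only (1 = intact utricle; 0.1 emulates utricle-null larvae).
#' @param hold_s Eccentric hold used for the slope-to-gain conversion.
#' @param cells_per_fish Cells are assigned to fish in blocks of this size.
#' @param seed Integer seed; the draw is fully reproducible.
#' @return A neuron ground-truth tibble (see [validate_neurons()]).
#' @export
#' @examples
#' simulate_neurons(5, seed = 1)
simulate_neurons <- function(n,
                             slope_ipsi_mean = 0.07, slope_ipsi_sd = 0.06,
                             slope_contra_mean = 0.02, slope_contra_sd = 0.02,
                             slope_floor = 0.003,
                             phasic_sd = 0.35,
                             plateau_fraction = 0.5,
                             hold_decay_frac_range = c(0.2, 0.8),
                             noise_sd = 0.35,
                             baseline_F = 100,
                             rise_tau_s = 0.18, decay_tau_s = 1.8,
                             utricle_scale = 1,
                             hold_s = 15,
                             cells_per_fish = 7,
                             seed = 1) {
  stopifnot(n >= 1)
  rf <- readout_factor(rise_tau_s, decay_tau_s, hold_s)
  with_seed(mix_seed(seed, 101), {
    slope_ipsi <- pmax(rnorm(n, slope_ipsi_mean, slope_ipsi_sd), slope_floor)
    slope_contra <- pmax(rnorm(n, slope_contra_mean, slope_contra_sd),
                         slope_floor)
    phasic <- abs(rnorm(n, 0, phasic_sd))
    plateau <- runif(n) < plateau_fraction
    d_frac <- runif(n, hold_decay_frac_range[1], hold_decay_frac_range[2])
    d_rate <- ifelse(plateau, 0,
                     d_frac * (slope_ipsi / rf) * 10 / hold_s)
    # topography: strongly phasic cells sit more ventrally (z more negative)
    phasic_strong <- phasic > stats::median(phasic)
    x <- rnorm(n, 15, 8)
    y <- rnorm(n, 0, 15)
    z <- ifelse(phasic_strong, rnorm(n, -3.6, 7.0), rnorm(n, 2.2, 11.0))
    hemi <- sample(c("left", "right"), n, replace = TRUE)
    neurons <- tibble::tibble(
      cell_id = sprintf("c%04d", seq_len(n)),
      fish_id = sprintf("f%03d", (seq_len(n) - 1) %/% cells_per_fish + 1),
      hemisphere = hemi,
      tonic_gain_ipsi = slope_ipsi / rf,
      tonic_gain_contra = slope_contra / rf,
      phasic_gain = phasic,
      decay_class = ifelse(plateau, "plateau", "fast_decay"),
      hold_decay_rate = d_rate,
      rise_tau_s = rise_tau_s, decay_tau_s = decay_tau_s,
      noise_sd = noise_sd, baseline_F = baseline_F,
      utricle_scale = utricle_scale,
      x_um = x, y_um = y, z_um = z
    )
    validate_neurons(neurons)
    neurons
  })
}

#' Apply developmental sensitivity changes to a population
#'
#' Produces the older-age counterpart of a neuron table, emulating the
#' patterns observed in developing vestibulospinal populations between 4 and
#' 7 days post-fertilization. Ipsilateral changes are unconditional and
#' asymmetric toward increases (each cell increases with probability
#' `p_increase_ipsi`, decreases with `p_decrease_ipsi`). Contralateral
#' changes follow the observed conditional structure: only cells in the top
#' `contra_tuned_fraction` of contralateral sensitivity may decrease (with
#' probability `p_decrease_contra_tuned`, losing their contralateral tuning
#' down to `contra_floor`), and only the remaining non-tuned cells may
#' increase (with probability `p_increase_contra_nontuned`, by
#' `contra_increase_amount`). Change amounts are expressed in measured-slope
#' units and converted with [readout_factor()]; gains never go below zero.
#'
#' @param neurons Neuron table for the first age.
#' @param p_increase_ipsi,p_decrease_ipsi Per-cell probabilities of a true
#'   ipsilateral sensitivity increase/decrease.
#' @param increase_amount,decrease_amount Absolute ipsilateral slope change
#'   (delta-F/F per degree) applied to changing cells.
#' @param contra_tuned_fraction Fraction of cells (ranked by contralateral
#'   gain) treated as contralaterally tuned at the first age.
#' @param p_decrease_contra_tuned Probability that a contra-tuned cell loses
#'   its contralateral tuning.
#' @param p_increase_contra_nontuned Probability that a non-tuned cell gains
#'   contralateral sensitivity.
#' @param contra_increase_amount Slope gained by contralateral increasers
#'   (delta-F/F per degree).
#' @param contra_floor Residual slope of cells that lose their
#'   contralateral tuning.
#' @param hold_s Eccentric hold used for the slope-to-gain conversion.
#' @param seed Integer seed.
#' @return A neuron table of the same shape, with `true_change_ipsi` /
#'   `true_change_contra` columns recording the generative category.
#' @export
develop_neurons <- function(neurons,
                            p_increase_ipsi = 14 / 70,
                            p_decrease_ipsi = 3 / 70,
                            increase_amount = 0.15,
                            decrease_amount = 0.05,
                            contra_tuned_fraction = 24 / 70,
                            p_decrease_contra_tuned = 11 / 24,
                            p_increase_contra_nontuned = 8 / 46,
                            contra_increase_amount = 0.05,
                            contra_floor = 0.003,
                            hold_s = 15,
                            seed = 1) {
  validate_neurons(neurons)
  n <- nrow(neurons)
  with_seed(mix_seed(seed, 202), {
    u_i <- runif(n)
    ch_i <- ifelse(u_i < p_increase_ipsi, "increase",
                   ifelse(u_i < p_increase_ipsi + p_decrease_ipsi,
                          "decrease", "no_change"))
    tuned <- rank(neurons$tonic_gain_contra, ties.method = "first") >
      n * (1 - contra_tuned_fraction)
    u_c <- runif(n)
    ch_c <- ifelse(tuned & u_c < p_decrease_contra_tuned, "decrease",
                   ifelse(!tuned & u_c < p_increase_contra_nontuned,
                          "increase", "no_change"))
    out <- neurons
    rf <- readout_factor(out$rise_tau_s[1], out$decay_tau_s[1], hold_s)
    out$tonic_gain_ipsi <- pmax(
      out$tonic_gain_ipsi + (ch_i == "increase") * increase_amount / rf -
        (ch_i == "decrease") * decrease_amount / rf, 0)
    out$tonic_gain_contra <- ifelse(
      ch_c == "decrease", contra_floor / rf,
      out$tonic_gain_contra +
        (ch_c == "increase") * contra_increase_amount / rf)
    out$true_change_ipsi <- ch_i
    out$true_change_contra <- ch_c
    out$contra_tuned_age1 <- tuned
    out
  })
}
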