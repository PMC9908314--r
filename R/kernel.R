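# Calcium-indicator impulse kernel: causal double exponential
#
#   k(t) = (exp(-t / decay_tau) - exp(-t / rise_tau)) / (decay_tau - rise_tau)
#
# normalized to unit area, so a sustained drive of c delta-F/F converges to a
# fluorescence plateau of c, and a delta of area A produces a transient with
# peak A * kernel_peak(). Convolution is evaluated with two exact first-order
# recursions (zero-order hold), which is both fast and free of quadrature
# error accumulation.

check_taus <- function(rise_tau_s, decay_tau_s) {
  if (!is.finite(rise_tau_s) || !is.finite(decay_tau_s) ||
      rise_tau_s <= 0 || decay_tau_s <= 0) {
    abort_user("indicator kernel taus must be positive (got rise_tau_s = ",
               rise_tau_s, ", decay_tau_s = ", decay_tau_s, ")")
  }
  if (decay_tau_s <= rise_tau_s) {
    abort_user("decay_tau_s must exceed rise_tau_s")
  }
  invisible(TRUE)
}

kernel_value <- function(t, rise_tau_s, decay_tau_s) {
  (exp(-t / decay_tau_s) - exp(-t / rise_tau_s)) / (decay_tau_s - rise_tau_s)
}

# peak time and peak height of the unit-area kernel
kernel_peak <- function(rise_tau_s, decay_tau_s) {
  check_taus(rise_tau_s, decay_tau_s)
  t_peak <- rise_tau_s * decay_tau_s / (decay_tau_s - rise_tau_s) *
    log(decay_tau_s / rise_tau_s)
  list(t_peak = t_peak,
       k_max = kernel_value(t_peak, rise_tau_s, decay_tau_s))
}

# convolve a drive time series (vector, or matrix with one column per cell)
# with the unit-area kernel; exact zero-order-hold discretization
convolve_kernel <- function(drive, rise_tau_s, decay_tau_s, dt) {
  check_taus(rise_tau_s, decay_tau_s)
  stopifnot(dt > 0)
  a_d <- exp(-dt / decay_tau_s)
  a_r <- exp(-dt / rise_tau_s)
  u_d <- stats::filter(drive * (decay_tau_s * (1 - a_d)), a_d,
                       method = "recursive")
  u_r <- stats::filter(drive * (rise_tau_s * (1 - a_r)), a_r,
                       method = "recursive")
  out <- (u_d - u_r) / (decay_tau_s - rise_tau_s)
  out <- unclass(out)
  attr(out, "tsp") <- NULL
  if (is.matrix(drive)) {
    dim(out) <- dim(drive)
  } else {
    out <- as.vector(out)
  }
  out
}

# integral of G(t) = int_0^t k(u) du over [a, b], for the unit-area kernel
.int_G <- function(a, b, rise, decay) {
  ee <- function(tau) tau * (exp(-a / tau) - exp(-b / tau))
  (b - a) - (decay * ee(decay) - rise * ee(rise)) / (decay - rise)
}

#' Steady-state readout attenuation of the indicator kernel
#'
#' For a cell whose drive is a constant `c` held for `hold_s` seconds and then
#' switched off (the tonic component of a tilt step), the fluorescence decays
#' after the return to horizontal. The peak response is read out as the mean
#' delta-F/F over a window after the return, so the measured response is
#' `c * readout_factor(...)` rather than `c` itself. This analytic factor
#' links the simulator's tonic gain (drive delta-F/F per degree) to the slope
#' implied at the measurement stage, and is used to parameterize synthetic
#' populations in measured-slope units.
#'
#' @param rise_tau_s,decay_tau_s Indicator kernel time constants (seconds).
#' @param hold_s Duration of the eccentric hold (seconds).
#' @param window_s Length-2 numeric: readout window relative to the return
#'   time, default `c(0, 1)` (the first second after return).
#' @return The dimensionless attenuation factor in (0, 1).
#' @export
#' @examples
#' readout_factor(0.18, 1.8, 15)
readout_factor <- function(rise_tau_s = 0.18, decay_tau_s = 1.8, hold_s = 15,
                           window_s = c(0, 1)) {
  check_taus(rise_tau_s, decay_tau_s)
  stopifnot(hold_s > 0, length(window_s) == 2, diff(window_s) > 0)
  w0 <- window_s[1]
  w1 <- window_s[2]
  (.int_G(hold_s + w0, hold_s + w1, rise_tau_s, decay_tau_s) -
     .int_G(w0, w1, rise_tau_s, decay_tau_s)) / (w1 - w0)
}
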