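# Shared fixtures, built in code at test time.

# a single neuron with fully controlled parameters
quick_neuron <- function(cell_id = "n1", gain_ipsi = 0.1, gain_contra = 0.02,
                         phasic = 0, decay_class = "plateau", decay_rate = 0,
                         noise_sd = 0, baseline_F = 100, utricle = 1,
                         rise = 0.18, decay = 1.8) {
  tibble::tibble(
    cell_id = cell_id, fish_id = "f1", hemisphere = "left",
    tonic_gain_ipsi = gain_ipsi, tonic_gain_contra = gain_contra,
    phasic_gain = phasic, decay_class = decay_class,
    hold_decay_rate = decay_rate, rise_tau_s = rise, decay_tau_s = decay,
    noise_sd = noise_sd, baseline_F = baseline_F, utricle_scale = utricle,
    x_um = 0, y_um = 0, z_um = 0
  )
}

# a population with controlled gains (n rows of quick_neuron with variation)
quick_population <- function(n, gain_ipsi, gain_contra = 0.02, noise_sd = 0.1,
                             ...) {
  out <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    quick_neuron(cell_id = sprintf("n%04d", i),
                 gain_ipsi = if (length(gain_ipsi) > 1) gain_ipsi[i] else gain_ipsi,
                 gain_contra = if (length(gain_contra) > 1) gain_contra[i] else gain_contra,
                 noise_sd = noise_sd, ...)
  }))
  out$fish_id <- sprintf("f%03d", (seq_len(n) - 1) %/% 7 + 1)
  out
}

# hand-built minimal trace table: one cell, one trial, explicit F values
make_trace <- function(F, sample_rate_hz = 2.2, baseline_s = 10, hold_s = 15,
                       response_s = 10, repeats = 1, transition_ms = 5.3,
                       kind = "step", direction = "ipsi", magnitude = 30,
                       cell_id = "n1", trial_id = "tr1") {
  t_s <- (seq_along(F) - 1) / sample_rate_hz
  tr <- transition_ms / 1000
  event_dur <- 2 * tr + hold_s + response_s
  onsets <- baseline_s + (seq_len(repeats) - 1) * event_dur
  tibble::tibble(
    fish_id = "f1", cell_id = cell_id, session_id = "s01", age_dpf = 4,
    trial_id = trial_id, repeat_id = findInterval(t_s, onsets),
    stim_kind = kind, stim_direction = direction,
    stim_magnitude_deg = magnitude, time_s = t_s, F = F,
    baseline_s = baseline_s, hold_s = hold_s, response_s = response_s,
    transition_ms = transition_ms
  )
}

# independent OLS oracle via explicit normal equations on the design matrix
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  c(intercept = beta[1], slope = beta[2])
}

# brute-force normalized cross-correlation oracle: explicit double loop over
# lags with manual mean/SD normalization (independent of frame_shift())
ncc_oracle <- function(pre, post, max_lag) {
  nr <- nrow(pre); nc <- ncol(pre)
  best <- c(NA, NA); best_r <- -Inf
  for (ly in -max_lag:max_lag) {
    for (lx in -max_lag:max_lag) {
      rows <- max(1, 1 + ly):min(nr, nr + ly)
      cols <- max(1, 1 + lx):min(nc, nc + lx)
      a <- as.vector(pre[rows - ly, cols - lx])
      b <- as.vector(post[rows, cols])
      am <- mean(a); bm <- mean(b)
      den <- sqrt(sum((a - am)^2) * sum((b - bm)^2))
      if (den == 0) next
      r <- sum((a - am) * (b - bm)) / den
      if (r > best_r + 1e-12 ||
          (abs(r - best_r) <= 1e-12 &&
             lx^2 + ly^2 < sum(best^2))) {
        best_r <- r; best <- c(lx, ly)
      }
    }
  }
  list(shift = best, r = best_r)
}
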