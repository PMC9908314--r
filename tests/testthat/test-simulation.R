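test_that("plateau tonic drive is constant at gain times angle during the hold", {
  p <- stim_protocol("step", "ipsi", 30)
  w <- generate_waveform(p, dt = 1e-3)
  n <- quick_neuron(gain_ipsi = 0.1)
  d <- simulate_drive(w, n)
  mid <- d$time_s > p$baseline_s + 1 & d$time_s < p$baseline_s + 14
  expect_equal(unique(d$drive[mid]), 30 * 0.1)
  # baseline and response periods carry no drive
  expect_true(all(d$drive[d$time_s < p$baseline_s - 0.01] == 0))
})

test_that("utricle_scale zero silences the ipsilateral step response", {
  p <- stim_protocol("step", "ipsi", 30)
  w <- generate_waveform(p, dt = 1e-3)
  n <- quick_neuron(gain_ipsi = 0.1, gain_contra = 0.03, phasic = 0,
                    utricle = 0)
  d <- simulate_drive(w, n)
  expect_true(all(d$drive == 0))
  # contralateral responses are untouched
  wc <- generate_waveform(stim_protocol("step", "contra", 30), dt = 1e-3)
  dc <- simulate_drive(wc, n)
  expect_equal(max(dc$drive), 30 * 0.03)
})

test_that("fast-decay drive follows the closed-form linear decline", {
  p <- stim_protocol("step", "ipsi", 30, hold_s = 15)
  w <- generate_waveform(p, dt = 1e-3)
  n <- quick_neuron(gain_ipsi = 0.1, decay_class = "fast_decay",
                    decay_rate = 0.05)
  d <- simulate_drive(w, n)
  peak <- 30 * 0.1
  # closed form: drive(t) = peak - rate * (t - onset); the ramp clock starts
  # at the first eccentric sample (within dt + transition of baseline_s)
  for (t_probe in c(5, 10, 15)) {
    i <- which.min(abs(d$time_s - (p$baseline_s + t_probe)))
    expect_lt(abs(d$drive[i] - (peak - 0.05 * t_probe)), 0.01)
  }
})

test_that("rendered transients match the analytic kernel", {
  n <- quick_neuron()
  dt <- 1e-3
  tt <- seq(0, 20, by = dt)
  drv <- numeric(length(tt))
  drv[tt == 1] <- 1 / dt  # unit-area delta at t = 1 s
  drive <- tibble::tibble(time_s = tt, drive = drv)
  out <- render_fluorescence(drive, n, sample_rate_hz = 1000, seed = 1)
  dff <- out$F / n$baseline_F - 1
  kp <- tipm:::kernel_peak(n$rise_tau_s, n$decay_tau_s)
  expect_equal(max(dff), kp$k_max, tolerance = 0.01)
  expect_equal(out$time_s[which.max(dff)] - 1, kp$t_peak, tolerance = 0.01)
  # unit-area kernel: transient integrates to the delta's area
  expect_equal(sum(dff) * 1e-3, 1, tolerance = 0.01)
})

test_that("phasic events produce transients peaking at phasic_gain", {
  p <- stim_protocol("impulse", "ipsi", 30)
  w <- generate_waveform(p, dt = 5e-4)
  n <- quick_neuron(gain_ipsi = 0, gain_contra = 0, phasic = 0.5)
  d <- simulate_drive(w, n)
  out <- render_fluorescence(d, n, sample_rate_hz = 200, seed = 1)
  dff <- out$F / n$baseline_F - 1
  # impulse = two rapid transitions ~13 ms apart -> peak ~ 2 * phasic_gain
  expect_equal(max(dff), 2 * 0.5, tolerance = 0.02)
})

test_that("zero drive and zero noise render a constant baseline trace", {
  n <- quick_neuron(gain_ipsi = 0, gain_contra = 0)
  drive <- tibble::tibble(time_s = seq(0, 10, by = 0.005),
                          drive = rep(0, 2001))
  out <- render_fluorescence(drive, n, seed = 3)
  expect_equal(out$F, rep(100, length(out$F)))
  bad <- quick_neuron(rise = -1)
  expect_error(render_fluorescence(drive, bad), "tau")
})

test_that("simulation is bit-identical under a fixed seed", {
  neurons <- simulate_neurons(4, seed = 2)
  s1 <- simulate_experiment(neurons, step_protocols(magnitudes = 30),
                            trials_per_magnitude = 2, seed = 9)
  s2 <- simulate_experiment(neurons, step_protocols(magnitudes = 30),
                            trials_per_magnitude = 2, seed = 9)
  expect_identical(s1$traces, s2$traces)
  s3 <- simulate_experiment(neurons, step_protocols(magnitudes = 30),
                            trials_per_magnitude = 2, seed = 10)
  expect_false(identical(s1$traces$F, s3$traces$F))
})

test_that("adding trials never reshuffles earlier trials", {
  neurons <- simulate_neurons(3, seed = 2)
  protos <- step_protocols(magnitudes = c(10, 30), directions = "ipsi")
  s2 <- simulate_experiment(neurons, protos, trials_per_magnitude = 2,
                            seed = 9)
  s3 <- simulate_experiment(neurons, protos, trials_per_magnitude = 3,
                            seed = 9)
  shared <- s3$traces$trial_id %in% unique(s2$traces$trial_id)
  expect_identical(s3$traces$F[shared], s2$traces$F)
})

test_that("noise-free response is linear in the tonic gain", {
  protos <- step_protocols(magnitudes = c(10, 30), directions = "ipsi")
  n1 <- quick_neuron(gain_ipsi = 0.05)
  n2 <- quick_neuron(gain_ipsi = 0.10)
  s1 <- simulate_experiment(n1, protos, trials_per_magnitude = 1, seed = 1)
  s2 <- simulate_experiment(n2, protos, trials_per_magnitude = 1, seed = 1)
  d1 <- s1$traces$F / 100 - 1
  d2 <- s2$traces$F / 100 - 1
  expect_equal(d2, 2 * d1, tolerance = 1e-10)
  expect_equal(s2$truth$slope_implied_ipsi, 2 * s1$truth$slope_implied_ipsi,
               tolerance = 1e-8)
})

test_that("anesthetized mode suppresses response statistics to noise level", {
  neurons <- simulate_neurons(30, seed = 4)
  sim <- simulate_experiment(neurons, step_protocols(magnitudes = 30,
                                                     directions = "ipsi"),
                             seed = 6, anesthetized = TRUE)
  pk <- extract_peaks(normalize_traces(sim$traces, "trial_baseline"))
  m <- mean(pk$peak_response)
  sem <- sd(pk$peak_response) / sqrt(nrow(pk))
  expect_lt(abs(m), 3 * sem + 1e-12)
})

test_that("trace length matches duration times sample rate within one sample", {
  neurons <- quick_neuron()
  p <- stim_protocol("step", "ipsi", 30)
  sim <- simulate_experiment(neurons, p, trials_per_magnitude = 1,
                             repeats_per_trial = 2, seed = 1)
  ev <- protocol_event_times(p, 2)
  expected <- floor(attr(ev, "total_s") * 2.2) + 1
  expect_equal(nrow(sim$traces), expected)
})

test_that("the batch engine matches the compose path exactly", {
  n <- quick_neuron(gain_ipsi = 0.08, gain_contra = 0.02, phasic = 0.3,
                    decay_class = "fast_decay", decay_rate = 0.03,
                    noise_sd = 0.2)
  p <- stim_protocol("step", "ipsi", 20)
  sim <- simulate_experiment(n, p, trials_per_magnitude = 2,
                             repeats_per_trial = 2, seed = 42, dt = 5e-3)
  w <- generate_waveform(p, dt = 5e-3, repeats = 2)
  d <- simulate_drive(w, n)
  for (trial in 1:2) {
    manual <- render_fluorescence(d, n, sample_rate_hz = 2.2,
                                  seed = mix_seed(42, 1, 1, trial))
    got <- sim$traces$F[sim$traces$trial_id ==
                          sprintf("step_ipsi_20deg_tr%d", trial)]
    expect_equal(got, manual$F, tolerance = 1e-12)
  }
})

test_that("neuron population draws respect their declared bounds", {
  n <- simulate_neurons(300, seed = 8)
  expect_true(all(n$tonic_gain_ipsi >= 0))
  expect_true(all(n$phasic_gain >= 0))
  expect_true(all(n$hold_decay_rate[n$decay_class == "plateau"] == 0))
  expect_true(all(n$hold_decay_rate[n$decay_class == "fast_decay"] > 0))
  # slope-unit parameterization: implied mean ipsi slope near the target
  # (truncation at the floor lifts the mean slightly above 0.07)
  rf <- readout_factor(0.18, 1.8, 15)
  expect_lt(abs(mean(n$tonic_gain_ipsi) * rf - 0.07), 0.02)
  expect_error(validate_neurons(dplyr::mutate(n, utricle_scale = 2)),
               "utricle")
})

test_that("readout factor agrees with numeric integration of the kernel", {
  for (taus in list(c(0.18, 1.8), c(0.1, 1.0), c(0.3, 3))) {
    G <- function(t) {
      ifelse(t <= 0, 0,
             1 - (taus[2] * exp(-t / taus[2]) - taus[1] * exp(-t / taus[1])) /
               (taus[2] - taus[1]))
    }
    num <- stats::integrate(function(t) G(t) - G(t - 15), 15, 16)$value
    expect_equal(readout_factor(taus[1], taus[2], 15), num,
                 tolerance = 1e-8)
  }
})
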