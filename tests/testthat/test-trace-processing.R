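test_that("trial-baseline normalization divides by the last-5s baseline mean", {
  # constant F equal to F0 -> dff identically 0
  tr <- make_trace(rep(100, 80))
  n1 <- normalize_traces(tr, "trial_baseline")
  expect_true(all(n1$dff == 0))
  expect_true(all(n1$f0 == 100))
  # F = 2 F0 everywhere -> dff = 1 against an anesthetized baseline of F0
  n2 <- normalize_traces(tr |> dplyr::mutate(F = 200),
                         "anesthetized_baseline",
                         f0 = tibble::tibble(cell_id = "n1", f0 = 100))
  expect_true(all(n2$dff == 1))
  # F0 window is [baseline_s - 5, baseline_s): only those samples count
  f <- rep(100, 80)
  t_s <- (seq_along(f) - 1) / 2.2
  f[t_s >= 5 & t_s < 10] <- 120
  n3 <- normalize_traces(make_trace(f), "trial_baseline")
  expect_equal(unique(n3$f0), 120)
})

test_that("normalization errors name the offending trial or cell", {
  short <- make_trace(rep(100, 60), baseline_s = 3)
  expect_error(normalize_traces(short, "trial_baseline"), "tr1")
  neg <- make_trace(rep(-5, 80))
  expect_error(normalize_traces(neg, "trial_baseline"), "non-positive F0")
  tr <- make_trace(rep(100, 80))
  expect_error(normalize_traces(tr, "anesthetized_baseline"), "f0")
  expect_error(normalize_traces(tr, "anesthetized_baseline",
                                f0 = tibble::tibble(cell_id = "zz", f0 = 1)),
               "n1")
})

test_that("peak windows are the discretized first second after return", {
  # constant dff of 2 after the return -> peak 2; 0 elsewhere -> baseline 0
  t_s <- (0:79) / 2.2
  f <- rep(100, 80)
  t_ret <- 10 + 2 * 5.3 / 1000 + 15
  f[t_s >= t_ret] <- 300
  pk <- extract_peaks(normalize_traces(make_trace(f), "trial_baseline"))
  expect_equal(pk$peak_response, 2)
  expect_equal(pk$baseline_dff, 0)
  # at 2.2 volumes/s the 1 s window holds 2-3 samples; the mean equals the
  # hand-computed average of exactly those samples
  raw <- normalize_traces(make_trace(f), "trial_baseline")
  in_win <- raw$time_s >= t_ret & raw$time_s < t_ret + 1
  expect_true(sum(in_win) %in% 2:3)
  expect_equal(pk$peak_response, mean(raw$dff[in_win]))
  expect_equal(pk$n_samples, sum(in_win))
})

test_that("peak extraction is linear in dff", {
  neurons <- quick_neuron(gain_ipsi = 0.09, noise_sd = 0)
  sim <- simulate_experiment(neurons, step_protocols(magnitudes = 30,
                                                     directions = "ipsi"),
                             trials_per_magnitude = 1, seed = 1)
  nt <- normalize_traces(sim$traces, "trial_baseline")
  pk1 <- extract_peaks(nt)
  scaled <- sim$traces
  scaled$F <- nt$f0 * (1 + 3 * nt$dff)
  pk3 <- extract_peaks(normalize_traces(scaled, "trial_baseline"))
  expect_equal(pk3$peak_response, 3 * pk1$peak_response, tolerance = 1e-10)
})

test_that("both readout windows agree with the simulator forward model", {
  n <- quick_neuron(gain_ipsi = 0.1, noise_sd = 0)
  sim <- simulate_experiment(n, step_protocols(magnitudes = 30,
                                               directions = "ipsi"),
                             trials_per_magnitude = 1, seed = 1)
  f0 <- tibble::tibble(cell_id = "n1", f0 = 100)
  nt <- normalize_traces(sim$traces, "anesthetized_baseline", f0 = f0)
  ecc <- extract_peaks(nt, "eccentric_last_1s")
  ret <- extract_peaks(nt, "post_return_first_1s")
  # plateau cell: steady state at the eccentric angle = gain * angle
  expect_equal(ecc$peak_response[1], 0.1 * 30, tolerance = 0.01)
  # post-return readout equals the analytic step response of the unit-area
  # kernel evaluated at the window's actual sample times
  G <- function(t) {
    ifelse(t <= 0, 0,
           1 - (1.8 * exp(-t / 1.8) - 0.18 * exp(-t / 0.18)) / (1.8 - 0.18))
  }
  p <- stim_protocol("step", "ipsi", 30)
  ev <- protocol_event_times(p, 2)
  t_samp <- nt$time_s[nt$time_s >= ev$t_return[1] &
                        nt$time_s < ev$t_return[1] + 1]
  expected <- 0.1 * 30 * mean(G(t_samp - ev$t_eccentric[1]) -
                                G(t_samp - ev$t_return[1]))
  expect_equal(ret$peak_response[1], expected, tolerance = 0.01)
  # attenuation relative to the eccentric steady state is substantial but
  # bounded (slow indicator decay is what makes TIPM work)
  expect_gt(ret$peak_response[1] / ecc$peak_response[1], 0.6)
  expect_lt(ret$peak_response[1] / ecc$peak_response[1], 0.95)
})

test_that("responsiveness test is one-tailed, paired by trial", {
  # identical peaks and baselines -> never responsive
  pk <- dplyr::bind_rows(lapply(1:3, function(t) {
    tibble::tibble(fish_id = "f1", cell_id = "n1", session_id = "s",
                   age_dpf = 4, trial_id = paste0("t", t), repeat_id = 1:2,
                   stim_kind = "step", stim_direction = "ipsi",
                   stim_magnitude_deg = 30, peak_response = 1,
                   n_samples = 2, f0 = 100, baseline_dff = 1,
                   window = "post_return_first_1s")
  }))
  r <- responsiveness_test(pk)
  expect_false(r$responsive)
  expect_gte(r$p, 0.05)
  # strong synthetic response -> responsive
  neurons <- quick_neuron(gain_ipsi = 0.1, noise_sd = 0.1)
  sim <- simulate_experiment(neurons, step_protocols(magnitudes = 30,
                                                     directions = "ipsi"),
                             seed = 3)
  pk2 <- extract_peaks(normalize_traces(sim$traces, "trial_baseline"))
  r2 <- responsiveness_test(pk2)
  expect_true(r2$responsive)
  # single trial -> flagged untestable, not guessed
  r3 <- responsiveness_test(pk[pk$trial_id == "t1", ])
  expect_false(r3$testable)
  expect_true(is.na(r3$p))
  # two-sample variant exists and agrees on the strong case
  expect_true(responsiveness_test(pk2, paired = FALSE)$responsive)
})

test_that("trial CV matches hand computation and is scale invariant", {
  expect_equal(trial_cv(c(1, 2, 3)), 0.5)
  expect_equal(trial_cv(c(1, 2, 3) * 10), 0.5)
  expect_equal(trial_cv(rep(2, 5)), 0)
  expect_true(is.na(trial_cv(c(-1, 1))))
  expect_true(is.na(trial_cv(3)))
})

test_that("eccentric dynamics recover hold decay class and rate", {
  protos <- step_protocols(magnitudes = 30, directions = "ipsi")
  f0 <- tibble::tibble(cell_id = "n1", f0 = 100)
  # constructed flat hold -> decay slope exactly 0
  t_s <- (0:79) / 2.2
  flat <- rep(100, 80)
  t_ecc <- 10 + 5.3 / 1000
  flat[t_s >= t_ecc & t_s < t_ecc + 15] <- 300
  dyn_flat <- eccentric_dynamics(
    normalize_traces(make_trace(flat), "anesthetized_baseline", f0 = f0))
  expect_equal(dyn_flat$decay_slope, 0)
  # fast-decay cell with rate d: recovered slope ~ -d (kernel smoothing
  # leaves some curvature near the peak, so the match is approximate)
  d_true <- 0.08
  nf <- quick_neuron(gain_ipsi = 0.1, decay_class = "fast_decay",
                     decay_rate = d_true, noise_sd = 0.005)
  simf <- simulate_experiment(nf, protos, trials_per_magnitude = 2,
                              repeats_per_trial = 1, seed = 2)
  dyn_f <- eccentric_dynamics(normalize_traces(simf$traces,
                                               "anesthetized_baseline",
                                               f0 = f0))
  expect_lt(abs(dyn_f$decay_slope + d_true), 0.25 * d_true)
  expect_lt(dyn_f$time_to_peak_s, 8)
  # monotonically rising trace -> time-to-peak at the hold boundary
  t_s <- (0:79) / 2.2
  rising <- 100 + cumsum(rep(1, 80))
  ntr <- normalize_traces(make_trace(rising), "anesthetized_baseline",
                          f0 = f0)
  dyn_r <- eccentric_dynamics(ntr)
  expect_gt(dyn_r$time_to_peak_s, 14)
  # too-short holds and trial-baseline normalization are refused
  short <- make_trace(rep(100, 60), hold_s = 5)
  expect_error(eccentric_dynamics(
    normalize_traces(short, "anesthetized_baseline", f0 = f0)), "hold")
  expect_error(eccentric_dynamics(
    normalize_traces(make_trace(rep(100, 80)), "trial_baseline")),
    "anesthetized")
})

test_that("trial segments partition every sample exactly once", {
  n <- quick_neuron()
  sim <- simulate_experiment(n, stim_protocol("step", "ipsi", 30),
                             trials_per_magnitude = 1,
                             repeats_per_trial = 2, seed = 1)
  tr <- sim$traces
  ev <- protocol_event_times(stim_protocol("step", "ipsi", 30), 2)
  seg_expected <- findInterval(tr$time_s, ev$t_onset)
  expect_equal(tr$repeat_id, seg_expected)
  expect_setequal(unique(tr$repeat_id), 0:2)
})
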