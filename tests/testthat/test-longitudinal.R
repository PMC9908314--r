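# small synthetic peak tables for classifier tests
fake_peaks <- function(cell_id, slope, noise_sd = 0.05, n_trials = 3,
                       repeats = 2, direction = "ipsi", seed = 1,
                       age = 4, mags = c(10, 20, 30)) {
  set.seed(seed)
  rows <- list()
  for (m in mags) {
    for (t in seq_len(n_trials)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        fish_id = "f1", cell_id = cell_id, session_id = paste0("a", age),
        age_dpf = age, trial_id = sprintf("step_%s_%02ddeg_tr%d", direction,
                                          m, t),
        repeat_id = seq_len(repeats), stim_kind = "step",
        stim_direction = direction, stim_magnitude_deg = m,
        peak_response = slope * m + rnorm(repeats, sd = noise_sd),
        n_samples = 2, f0 = 100, baseline_dff = 0,
        window = "post_return_first_1s")
    }
  }
  dplyr::bind_rows(rows)
}

test_that("classification rule applies the +/- 2 SD cutoffs", {
  null <- list(null_mean = 0.01, null_sd = 0.005)
  expect_equal(classify_change(0.01, null)$category, "no_change")
  expect_equal(classify_change(0.01 + 3 * 0.005, null)$category, "increase")
  expect_equal(classify_change(0.01 - 3 * 0.005, null)$category, "decrease")
  expect_equal(classify_change(0.01 + 2 * 0.005, null)$category, "no_change")
})

test_that("zero-variance peaks give a degenerate but well-defined null", {
  mags <- rep(c(10, 20, 30), each = 2)
  null <- shuffle_null(mags, rep(1, 6), mags, rep(1, 6), n_shuffles = 50,
                       seed = 2)
  expect_equal(null$null_sd, 0)
  expect_true(all(null$delta == 0))
  cls <- classify_change(0, null)
  expect_equal(cls$category, "no_change")
})

test_that("the shuffle null is reproducible from its seed", {
  p1 <- fake_peaks("c1", 0.07, seed = 1)
  p2 <- fake_peaks("c1", 0.07, seed = 2, age = 7)
  args <- list(p1$stim_magnitude_deg, p1$peak_response,
               p2$stim_magnitude_deg, p2$peak_response,
               trial_age1 = p1$trial_id, trial_age2 = p2$trial_id)
  n1 <- do.call(shuffle_null, c(args, n_shuffles = 200, seed = 11))
  n2 <- do.call(shuffle_null, c(args, n_shuffles = 200, seed = 11))
  n3 <- do.call(shuffle_null, c(args, n_shuffles = 200, seed = 12))
  expect_identical(n1$delta, n2$delta)
  expect_false(identical(n1$delta, n3$delta))
})

test_that("observed slope change is invariant to trial order", {
  p1 <- fake_peaks("c1", 0.07, seed = 1)
  p2 <- fake_peaks("c1", 0.12, seed = 2, age = 7)
  ch_a <- classify_population(p1, p2, n_shuffles = 100, seed = 5)
  set.seed(3)
  ch_b <- classify_population(p1[sample(nrow(p1)), ], p2, n_shuffles = 100,
                              seed = 5)
  a <- ch_a[ch_a$direction == "ipsi", ]
  b <- ch_b[ch_b$direction == "ipsi", ]
  expect_equal(a$delta_slope, b$delta_slope, tolerance = 1e-12)
})

test_that("insufficient trials lead to explicit exclusion, not silence", {
  p1 <- fake_peaks("c1", 0.07, seed = 1, mags = 30)  # single magnitude
  p2 <- fake_peaks("c1", 0.07, seed = 2, age = 7)
  ch <- classify_population(p1, p2, n_shuffles = 50, seed = 5)
  expect_true(all(!is.na(ch$excluded[ch$cell_id == "c1"])))
  expect_true(all(is.na(ch$category[ch$cell_id == "c1"])))
})

test_that("population cutoffs classify a constructed change correctly", {
  # 20 stable cells and one whose sensitivity clearly doubles
  p1 <- dplyr::bind_rows(lapply(1:21, function(i) {
    fake_peaks(sprintf("c%02d", i), 0.07, seed = i)
  }))
  p2 <- dplyr::bind_rows(lapply(1:21, function(i) {
    fake_peaks(sprintf("c%02d", i), ifelse(i == 21, 0.20, 0.07),
               seed = 100 + i, age = 7)
  }))
  ch <- classify_population(p1, p2, n_shuffles = 300, seed = 9)
  ipsi <- ch[ch$direction == "ipsi", ]
  expect_equal(ipsi$category[ipsi$cell_id == "c21"], "increase")
  expect_gt(mean(ipsi$category[ipsi$cell_id != "c21"] == "no_change"), 0.8)
  # cutoffs are shared across cells within a direction
  expect_equal(length(unique(ipsi$cutoff_hi)), 1)
  # per-cell mode uses each cell's own null instead
  chp <- classify_population(p1, p2, n_shuffles = 300, seed = 9,
                             cutoff = "per_cell")
  expect_gt(length(unique(chp$cutoff_hi[chp$direction == "ipsi"])), 1)
})

test_that("early-tuned labels separate tuned from untuned cells", {
  p1 <- dplyr::bind_rows(
    lapply(1:6, function(i) fake_peaks(sprintf("t%d", i), 0.08, seed = i,
                                       direction = "contra")),
    lapply(1:6, function(i) fake_peaks(sprintf("u%d", i), 0.0, seed = 10 + i,
                                       direction = "contra")))
  lab <- early_tuned_labels(p1, n_shuffles = 300, seed = 4)
  contra <- lab[lab$direction == "contra", ]
  expect_true(all(contra$early_tuned[grepl("^t", contra$cell_id)]))
  expect_false(any(contra$early_tuned[grepl("^u", contra$cell_id)]))
})

test_that("developed populations reproduce the conditional contra pattern", {
  neurons1 <- simulate_neurons(60, seed = 91)
  neurons2 <- develop_neurons(neurons1, seed = 92)
  # generatively: only contra-tuned cells decrease, only non-tuned increase
  expect_true(all(neurons2$true_change_contra[!neurons2$contra_tuned_age1]
                  %in% c("increase", "no_change")))
  expect_true(all(neurons2$true_change_contra[neurons2$contra_tuned_age1]
                  %in% c("decrease", "no_change")))
  s1 <- simulate_experiment(neurons1, step_protocols(), seed = 93,
                            age_dpf = 4)
  s2 <- simulate_experiment(neurons2, step_protocols(), seed = 94,
                            age_dpf = 7)
  p1 <- extract_peaks(normalize_traces(s1$traces, "trial_baseline"))
  p2 <- extract_peaks(normalize_traces(s2$traces, "trial_baseline"))
  ch <- classify_population(p1, p2, n_shuffles = 400, seed = 95)
  lab <- early_tuned_labels(p1, n_shuffles = 400, seed = 96)
  sp <- early_tuned_split(ch, lab)
  g <- sp$groups[sp$groups$direction == "contra" & !is.na(sp$groups$early_tuned), ]
  # the classifier never assigns an increase to the early-tuned contra group
  expect_false(any(g$category[g$early_tuned] == "increase"))
  # and detects at least some of the constructed decreases
  expect_gt(sum(g$category[g$early_tuned] == "decrease"), 0)
})

test_that("group split comparisons behave at the boundaries", {
  changes <- tibble::tibble(
    cell_id = sprintf("c%02d", 1:20), direction = "contra",
    delta_slope = rep(c(-0.05, -0.05, 0.01, 0.01), 5),
    excluded = NA_character_)
  labels <- tibble::tibble(
    cell_id = sprintf("c%02d", 1:20), direction = "contra",
    early_tuned = rep(c(TRUE, FALSE, TRUE, FALSE), 5))
  # identical distributions in both groups -> KS statistic 0
  sp <- early_tuned_split(changes, labels)
  expect_equal(sp$tests$ks_stat[sp$tests$direction == "contra"], 0)
  # a tiny group is skipped with a reason
  labels2 <- labels
  labels2$early_tuned <- c(TRUE, rep(FALSE, 19))
  sp2 <- early_tuned_split(changes, labels2)
  expect_false(is.na(sp2$tests$skipped[1]))
})

test_that("change correlation handles perfect, anti, and undefined cases", {
  mk <- function(ipsi, contra) {
    tibble::tibble(cell_id = rep(sprintf("c%02d", seq_along(ipsi)), 2),
                   direction = rep(c("ipsi", "contra"), each = length(ipsi)),
                   delta_slope = c(ipsi, contra),
                   excluded = NA_character_)
  }
  v <- c(0.01, -0.02, 0.05, 0.03, -0.04)
  expect_equal(change_correlation(mk(v, v))$rho, 1)
  expect_equal(change_correlation(mk(v, -v))$rho, -1)
  expect_true(is.na(change_correlation(mk(v[1:2], v[1:2]))$rho))
})
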