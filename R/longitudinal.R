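# Longitudinal sensitivity-change classification --------------------------
#
# The question: did a cell's roll sensitivity (slope of peak delta-F/F vs
# step magnitude, per direction) change between two imaging ages? The
# classifier builds a permutation null per cell and direction: pool the
# (magnitude, peak) pairs from both ages, randomly reassign age labels
# (preserving per-age trial counts and the magnitude/peak pairing), refit a
# slope per pseudo-age, and record the slope difference. A change is called
# significant when the observed slope difference falls outside the null
# mean +/- 2 SD.

# permutation index matrix: each column one permutation of seq_len(n)
perm_matrix <- function(n, n_perm) {
  apply(matrix(runif(n * n_perm), n, n_perm), 2, order)
}

# collapse row-level (magnitude, peak, trial) data to per-trial sufficient
# statistics for OLS of peak ~ magnitude: trial magnitude x_t, number of
# response events r_t, and their peak sum sy_t. Any subset of trials then
# has n = sum r, Sx = sum r*x, Sxx = sum r*x^2, Sy = sum sy, Sxy = sum x*sy.
.trial_stats <- function(magnitude, peak, trial) {
  key <- as.character(trial)
  ux <- tapply(magnitude, key, function(v) v[1])
  list(x = as.vector(ux),
       r = as.vector(tapply(peak, key, length)),
       sy = as.vector(tapply(peak, key, sum)))
}

# column-wise OLS slopes from per-trial statistics selected by an index
# matrix I (trials x shuffles)
.slopes_from_stats <- function(x, r, sy, I) {
  X <- matrix(x[I], nrow(I))
  R <- matrix(r[I], nrow(I))
  SY <- matrix(sy[I], nrow(I))
  n <- colSums(R)
  sx <- colSums(R * X)
  sxx <- colSums(R * X * X) - sx^2 / n
  sxy <- colSums(X * SY) - sx * colSums(SY) / n
  out <- sxy / sxx
  out[sxx <= 0] <- NA_real_
  out
}

#' Permutation null for a between-age slope difference
#'
#' Pools one cell's trials (with their per-trial step magnitudes and peak
#' responses) from both ages in one direction, permutes the age labels of
#' whole trials (per-age trial counts, the magnitude/peak pairing, and the
#' grouping of repeated stimulus events within a trial are all preserved),
#' refits a slope per pseudo-age, and returns the distribution of slope
#' differences (pseudo-age2 minus pseudo-age1). Shuffling whole trials keeps
#' the null faithful to the trial-level correlation structure of the data
#' (repeats within a trial share the trial's baseline estimate).
#'
#' @param magnitude_age1,peak_age1 Per-event step magnitudes (degrees) and
#'   peak responses at the first age.
#' @param magnitude_age2,peak_age2 Same at the second age.
#' @param trial_age1,trial_age2 Trial identifiers grouping events into
#'   trials; by default every event is its own trial.
#' @param n_shuffles Number of permutations.
#' @param seed Integer seed; the null is reproducible.
#' @return List with `delta` (the vector of shuffled slope differences),
#'   `null_mean`, `null_sd`, `n_age1`, `n_age2` (trial counts).
#' @export
shuffle_null <- function(magnitude_age1, peak_age1,
                         magnitude_age2, peak_age2,
                         trial_age1 = NULL, trial_age2 = NULL,
                         n_shuffles = 1000, seed = 1) {
  stopifnot(length(peak_age1) == length(magnitude_age1),
            length(peak_age2) == length(magnitude_age2),
            n_shuffles >= 1)
  trial_age1 <- trial_age1 %||% paste0("a1_", seq_along(peak_age1))
  trial_age2 <- trial_age2 %||% paste0("a2_", seq_along(peak_age2))
  if (length(unique(magnitude_age1)) < 2 ||
      length(unique(magnitude_age2)) < 2) {
    abort_user("shuffle null needs trials at >= 2 magnitudes in both ages")
  }
  s1 <- .trial_stats(magnitude_age1, peak_age1, trial_age1)
  s2 <- .trial_stats(magnitude_age2, peak_age2, trial_age2)
  x <- c(s1$x, s2$x)
  r <- c(s1$r, s2$r)
  sy <- c(s1$sy, s2$sy)
  n1 <- length(s1$x)
  n2 <- length(s2$x)
  P <- with_seed(seed, perm_matrix(n1 + n2, n_shuffles))
  sl1 <- .slopes_from_stats(x, r, sy, P[seq_len(n1), , drop = FALSE])
  sl2 <- .slopes_from_stats(x, r, sy, P[n1 + seq_len(n2), , drop = FALSE])
  delta <- sl2 - sl1
  list(delta = delta,
       null_mean = mean(delta, na.rm = TRUE),
       null_sd = sd(delta, na.rm = TRUE),
       n_age1 = n1, n_age2 = n2)
}

#' Classify an observed slope change against its permutation null
#'
#' Applies the mean +/- 2 SD rule: `increase` when the observed difference
#' exceeds `null_mean + 2 * null_sd`, `decrease` when below
#' `null_mean - 2 * null_sd`, otherwise `no_change`. A degenerate null
#' (zero SD, e.g. from zero-variance peaks) collapses the cutoffs to a
#' point; the observed value then classifies as no_change unless it differs
#' from the null mean.
#'
#' @param delta_slope Observed slope difference (age2 minus age1),
#'   delta-F/F per degree.
#' @param null A null object from [shuffle_null()].
#' @return One-row tibble: `delta_slope`, `null_mean`, `null_sd`,
#'   `cutoff_lo`, `cutoff_hi`, `category`.
#' @export
classify_change <- function(delta_slope, null) {
  lo <- null$null_mean - 2 * null$null_sd
  hi <- null$null_mean + 2 * null$null_sd
  category <- if (!is.finite(delta_slope)) {
    NA_character_
  } else if (delta_slope > hi) {
    "increase"
  } else if (delta_slope < lo) {
    "decrease"
  } else {
    "no_change"
  }
  tibble::tibble(delta_slope = delta_slope, null_mean = null$null_mean,
                 null_sd = null$null_sd, cutoff_lo = lo, cutoff_hi = hi,
                 category = category)
}

.step_trials <- function(peaks) {
  dplyr::filter(peaks, stim_kind == "step",
                is.finite(peak_response), is.finite(stim_magnitude_deg))
}

#' Classify sensitivity changes for a whole population
#'
#' Runs [shuffle_null()] for every cell and direction present at both ages
#' and classifies each observed slope difference against the mean +/- 2 SD
#' cutoff. With `cutoff = "population"` (default) the cutoff per direction
#' is computed from the shuffled slope differences pooled across all cells —
#' one pair of cutoffs per direction for the whole population, the form in
#' which a single significance band can be drawn over the distribution of
#' per-cell changes. `cutoff = "per_cell"` instead uses each cell's own null
#' (note that with few trials a large true change inflates its own
#' permutation null, so per-cell cutoffs have very little power for exactly
#' the cells that change most). Cells that cannot be classified (absent at
#' one age, fewer than 2 magnitudes or 2 trials in a direction) are returned
#' with an `excluded` reason rather than dropped silently.
#'
#' @param peaks_age1,peaks_age2 Peak-response tibbles ([extract_peaks()])
#'   for the two ages; step trials are used.
#' @param n_shuffles Permutations per cell and direction.
#' @param seed Master seed; per-cell substreams are derived with
#'   [mix_seed()].
#' @param cutoff `"population"` or `"per_cell"` (see above).
#' @return Tibble with one row per (cell, direction): observed slopes per
#'   age, `delta_slope`, the null mean/SD behind the applied cutoff
#'   (`null_mean`, `null_sd`), `cutoff_lo`, `cutoff_hi`, the cell's own null
#'   summaries (`cell_null_mean`, `cell_null_sd`), `category`, `n_shuffles`,
#'   `seed`, and `excluded` (NA when classified).
#' @export
classify_population <- function(peaks_age1, peaks_age2,
                                n_shuffles = 1000, seed = 1,
                                cutoff = c("population", "per_cell")) {
  cutoff <- match.arg(cutoff)
  a1 <- .step_trials(peaks_age1)
  a2 <- .step_trials(peaks_age2)
  cells <- sort(union(unique(a1$cell_id), unique(a2$cell_id)))
  dirs <- c("ipsi", "contra")
  rows <- list()
  pooled <- list(ipsi = list(), contra = list())
  for (ci in seq_along(cells)) {
    for (di in seq_along(dirs)) {
      d1 <- a1[a1$cell_id == cells[ci] & a1$stim_direction == dirs[di], ]
      d2 <- a2[a2$cell_id == cells[ci] & a2$stim_direction == dirs[di], ]
      base <- tibble::tibble(cell_id = cells[ci], direction = dirs[di],
                             n_age1 = nrow(d1), n_age2 = nrow(d2))
      reason <- NA_character_
      if (nrow(d1) < 2 || nrow(d2) < 2) {
        reason <- "fewer than 2 trials at one age"
      } else if (length(unique(d1$stim_magnitude_deg)) < 2 ||
                 length(unique(d2$stim_magnitude_deg)) < 2) {
        reason <- "fewer than 2 step magnitudes at one age"
      }
      if (!is.na(reason)) {
        rows[[length(rows) + 1]] <- dplyr::bind_cols(
          base, tibble::tibble(slope_age1 = NA_real_, slope_age2 = NA_real_,
                               delta_slope = NA_real_,
                               cell_null_mean = NA_real_,
                               cell_null_sd = NA_real_,
                               excluded = reason))
        next
      }
      s1 <- slope_fit(d1$stim_magnitude_deg, d1$peak_response)$slope
      s2 <- slope_fit(d2$stim_magnitude_deg, d2$peak_response)$slope
      null <- shuffle_null(d1$stim_magnitude_deg, d1$peak_response,
                           d2$stim_magnitude_deg, d2$peak_response,
                           trial_age1 = d1$trial_id, trial_age2 = d2$trial_id,
                           n_shuffles = n_shuffles,
                           seed = mix_seed(seed, ci, di))
      pooled[[dirs[di]]][[length(pooled[[dirs[di]]]) + 1]] <- null$delta
      rows[[length(rows) + 1]] <- dplyr::bind_cols(
        base, tibble::tibble(slope_age1 = s1, slope_age2 = s2,
                             delta_slope = s2 - s1,
                             cell_null_mean = null$null_mean,
                             cell_null_sd = null$null_sd,
                             excluded = NA_character_))
    }
  }
  out <- dplyr::bind_rows(rows)
  out$null_mean <- NA_real_
  out$null_sd <- NA_real_
  if (cutoff == "population") {
    for (dir in dirs) {
      all_delta <- unlist(pooled[[dir]])
      if (length(all_delta) == 0) next
      sel <- out$direction == dir
      out$null_mean[sel] <- mean(all_delta, na.rm = TRUE)
      out$null_sd[sel] <- sd(all_delta, na.rm = TRUE)
    }
  } else {
    out$null_mean <- out$cell_null_mean
    out$null_sd <- out$cell_null_sd
  }
  out$cutoff_lo <- out$null_mean - 2 * out$null_sd
  out$cutoff_hi <- out$null_mean + 2 * out$null_sd
  out$category <- ifelse(
    !is.finite(out$delta_slope), NA_character_,
    ifelse(out$delta_slope > out$cutoff_hi, "increase",
           ifelse(out$delta_slope < out$cutoff_lo, "decrease", "no_change")))
  out$category[!is.na(out$excluded)] <- NA_character_
  out$n_shuffles <- n_shuffles
  out$seed <- seed
  out$cutoff_type <- cutoff
  out
}

#' Early-tuned labels from a within-age magnitude shuffle
#'
#' A cell is "early tuned" in a direction when its observed sensitivity
#' slope at the first age exceeds the mean + 2 SD of slopes refit after
#' shuffling magnitude labels among that age's trials. For the contralateral
#' direction this is the Early Contra Responder definition; the same rule
#' applied ipsilaterally gives the ipsilateral split.
#'
#' @param peaks_age1 Peak-response tibble at the first age (step trials).
#' @param n_shuffles Number of magnitude shuffles.
#' @param seed Master seed.
#' @param cutoff `"population"` (default; one cutoff per direction from the
#'   shuffled slopes pooled across cells) or `"per_cell"`.
#' @return Tibble with one row per (cell, direction): `slope`, the null
#'   summaries behind the applied cutoff (`null_mean`, `null_sd`,
#'   `cutoff_hi`), the cell's own null (`cell_null_mean`, `cell_null_sd`),
#'   `early_tuned`, and `excluded` reason (NA when labeled).
#' @export
early_tuned_labels <- function(peaks_age1, n_shuffles = 1000, seed = 1,
                               cutoff = c("population", "per_cell")) {
  cutoff <- match.arg(cutoff)
  a1 <- .step_trials(peaks_age1)
  cells <- sort(unique(a1$cell_id))
  dirs <- c("ipsi", "contra")
  rows <- list()
  pooled <- list(ipsi = list(), contra = list())
  for (ci in seq_along(cells)) {
    for (di in seq_along(dirs)) {
      d <- a1[a1$cell_id == cells[ci] & a1$stim_direction == dirs[di], ]
      base <- tibble::tibble(cell_id = cells[ci], direction = dirs[di])
      if (nrow(d) < 2 || length(unique(d$stim_magnitude_deg)) < 2) {
        rows[[length(rows) + 1]] <- dplyr::bind_cols(
          base, tibble::tibble(slope = NA_real_, cell_null_mean = NA_real_,
                               cell_null_sd = NA_real_,
                               excluded = "insufficient trials"))
        next
      }
      obs <- slope_fit(d$stim_magnitude_deg, d$peak_response)$slope
      st <- .trial_stats(d$stim_magnitude_deg, d$peak_response, d$trial_id)
      nt <- length(st$x)
      P <- with_seed(mix_seed(seed, 5000, ci, di),
                     perm_matrix(nt, n_shuffles))
      # permute the trial -> magnitude assignment among that age's trials;
      # each trial keeps its own peaks (and repeat count)
      X <- matrix(st$x[P], nt)
      n <- sum(st$r)
      sy_tot <- sum(st$sy)
      sx <- colSums(st$r * X)
      sxx <- colSums(st$r * X * X) - sx^2 / n
      sxy <- colSums(st$sy * X) - sx * sy_tot / n
      s <- sxy / sxx
      s[sxx <= 0] <- NA_real_
      pooled[[dirs[di]]][[length(pooled[[dirs[di]]]) + 1]] <- s
      rows[[length(rows) + 1]] <- dplyr::bind_cols(
        base, tibble::tibble(slope = obs,
                             cell_null_mean = mean(s, na.rm = TRUE),
                             cell_null_sd = sd(s, na.rm = TRUE),
                             excluded = NA_character_))
    }
  }
  out <- dplyr::bind_rows(rows)
  out$null_mean <- NA_real_
  out$null_sd <- NA_real_
  if (cutoff == "population") {
    for (dir in dirs) {
      all_s <- unlist(pooled[[dir]])
      if (length(all_s) == 0) next
      sel <- out$direction == dir
      out$null_mean[sel] <- mean(all_s, na.rm = TRUE)
      out$null_sd[sel] <- sd(all_s, na.rm = TRUE)
    }
  } else {
    out$null_mean <- out$cell_null_mean
    out$null_sd <- out$cell_null_sd
  }
  out$cutoff_hi <- out$null_mean + 2 * out$null_sd
  out$early_tuned <- ifelse(is.na(out$excluded),
                            out$slope > out$cutoff_hi, NA)
  out$cutoff_type <- cutoff
  out
}

#' Compare sensitivity-change distributions between early-tuned groups
#'
#' Splits the per-cell slope changes in each direction by the early-tuned
#' label at the first age and compares the two distributions with a
#' two-sample Kolmogorov-Smirnov test. Groups with fewer than 2 classified
#' cells are skipped with a reason.
#'
#' @param changes Classification tibble from [classify_population()].
#' @param labels Label tibble from [early_tuned_labels()].
#' @return List with `groups` (per-cell table with labels joined) and
#'   `tests` (per direction: group sizes, KS statistic, p, category counts,
#'   `skipped` reason).
#' @export
early_tuned_split <- function(changes, labels) {
  joined <- changes |>
    dplyr::filter(is.na(excluded)) |>
    dplyr::left_join(labels[, c("cell_id", "direction", "early_tuned")],
                     by = c("cell_id", "direction"))
  tests <- list()
  for (dir in unique(joined$direction)) {
    d <- joined[joined$direction == dir & !is.na(joined$early_tuned), ]
    g1 <- d$delta_slope[d$early_tuned]
    g0 <- d$delta_slope[!d$early_tuned]
    if (length(g1) < 2 || length(g0) < 2) {
      tests[[dir]] <- tibble::tibble(direction = dir, n_early = length(g1),
                                     n_nontuned = length(g0),
                                     ks_stat = NA_real_, p = NA_real_,
                                     skipped = "group with < 2 cells")
      next
    }
    kt <- suppressWarnings(ks.test(g1, g0))
    tests[[dir]] <- tibble::tibble(direction = dir, n_early = length(g1),
                                   n_nontuned = length(g0),
                                   ks_stat = unname(kt$statistic),
                                   p = kt$p.value, skipped = NA_character_)
  }
  list(groups = joined, tests = dplyr::bind_rows(tests))
}

#' Correlation of sensitivity changes across directions
#'
#' Pearson correlation between each cell's ipsilateral and contralateral
#' slope change, to ask whether development in the two directions is
#' coordinated.
#'
#' @param changes Classification tibble from [classify_population()].
#' @return One-row tibble: `rho`, `p`, `n` (NA when fewer than 3 paired
#'   cells).
#' @export
change_correlation <- function(changes) {
  wide <- changes |>
    dplyr::filter(is.na(excluded)) |>
    dplyr::select(cell_id, direction, delta_slope) |>
    tidyr::pivot_wider(names_from = direction, values_from = delta_slope)
  if (!all(c("ipsi", "contra") %in% names(wide))) {
    return(tibble::tibble(rho = NA_real_, p = NA_real_, n = 0L))
  }
  keep <- is.finite(wide$ipsi) & is.finite(wide$contra)
  n <- sum(keep)
  if (n < 3) {
    return(tibble::tibble(rho = NA_real_, p = NA_real_, n = n))
  }
  ct <- cor.test(wide$ipsi[keep], wide$contra[keep], method = "pearson")
  tibble::tibble(rho = unname(ct$estimate), p = ct$p.value, n = n)
}
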