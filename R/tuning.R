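# Directional and magnitude tuning ---------------------------------------

# closed-form OLS line fit y ~ x; returns slope, intercept, and standard
# errors. Used everywhere a line is fit (sensitivity slopes, hold decay,
# permutation nulls); identical to lm() to numerical precision but cheap
# enough to call millions of times.
slope_fit <- function(x, y) {
  n <- length(x)
  stopifnot(n == length(y), n >= 2)
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) {
    return(list(slope = NA_real_, intercept = NA_real_,
                slope_se = NA_real_, intercept_se = NA_real_, n = n))
  }
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  s2 <- if (n > 2) sum(resid^2) / (n - 2) else NA_real_
  list(slope = slope, intercept = intercept,
       slope_se = sqrt(s2 / sxx),
       intercept_se = sqrt(s2 * (1 / n + mean(x)^2 / sxx)),
       n = n)
}

# column-wise OLS slopes for matrices X, Y (one fit per column); NA where
# the predictor has zero variance
col_slopes <- function(X, Y) {
  n <- nrow(X)
  sx <- colSums(X)
  sy <- colSums(Y)
  sxx <- colSums(X * X) - sx^2 / n
  sxy <- colSums(X * Y) - sx * sy / n
  out <- sxy / sxx
  out[sxx <= 0] <- NA_real_
  out
}

#' Directionality index
#'
#' `(R_ipsi - R_contra) / (R_ipsi + R_contra)` computed from the mean peak
#' responses to 30-degree ipsilateral and contralateral steps. +1 indicates a
#' purely ipsilateral-preferring cell, 0 no preference. When the denominator
#' is not positive the index is undefined and `NA` is returned (never
#' clamped); callers should flag such cells.
#'
#' @param r_ipsi,r_contra Mean peak delta-F/F responses (vectorized).
#' @return Numeric vector of directionality indices with `NA` where
#'   undefined.
#' @export
#' @examples
#' directionality_index(3, 1)  # 0.5
directionality_index <- function(r_ipsi, r_contra) {
  denom <- r_ipsi + r_contra
  ifelse(is.finite(denom) & denom > 0, (r_ipsi - r_contra) / denom, NA_real_)
}

#' Roll-sensitivity slope of peak responses versus step magnitude
#'
#' Fits a line with two free parameters (slope and intercept) to the
#' individual per-trial peak responses pooled across all step magnitudes in
#' one direction. The slope, in delta-F/F per degree, is the cell's roll
#' sensitivity in that direction. Baseline (0 degree) points are not part of
#' the fit.
#'
#' @param magnitude_deg Step magnitudes of the individual trials (degrees).
#' @param peak_response Per-trial peak delta-F/F values.
#' @return A one-row tibble: `slope`, `intercept`, `slope_se`,
#'   `intercept_se`, `n`.
#' @export
#' @examples
#' sensitivity_slope(c(10, 20, 30, 10, 20, 30),
#'                   c(1, 2, 3, 1.1, 1.9, 3.2))
sensitivity_slope <- function(magnitude_deg, peak_response) {
  keep <- is.finite(magnitude_deg) & is.finite(peak_response)
  magnitude_deg <- magnitude_deg[keep]
  peak_response <- peak_response[keep]
  if (length(magnitude_deg) < 2) {
    abort_user("sensitivity slope needs at least 2 trials")
  }
  if (length(unique(magnitude_deg)) < 2) {
    abort_user("sensitivity slope needs trials at >= 2 distinct step ",
               "magnitudes (got only ", magnitude_deg[1], " deg)")
  }
  tibble::as_tibble(slope_fit(magnitude_deg, peak_response))
}

#' Per-cell tuning summary
#'
#' Aggregates a peak-response table into one row per cell: roll-sensitivity
#' slopes (with standard errors) per direction, the 30-degree directionality
#' index, the trial coefficient of variation for 30-degree ipsilateral
#' steps, responsiveness to the 30-degree step in each direction, and
#' optionally `tuned_*` flags marking cells whose slope exceeds the
#' mean + 2 SD of a within-age magnitude-shuffle null (see
#' [early_tuned_labels()]).
#'
#' @param peaks Peak-response tibble from [extract_peaks()] (step trials are
#'   used; other kinds are ignored for slopes/DI).
#' @param n_shuffles Shuffles for the tuned-cell null; 0 skips the flags.
#' @param seed Seed for the shuffle null.
#' @return Tibble with one row per cell.
#' @export
tune_cells <- function(peaks, n_shuffles = 1000, seed = 1) {
  steps <- dplyr::filter(peaks, stim_kind == "step")
  if (nrow(steps) == 0) abort_user("no step trials in the peak table")
  slope_one <- function(d) {
    if (length(unique(d$stim_magnitude_deg)) < 2) {
      return(tibble::tibble(slope = NA_real_, slope_se = NA_real_,
                            intercept = NA_real_, n = nrow(d)))
    }
    f <- slope_fit(d$stim_magnitude_deg, d$peak_response)
    tibble::tibble(slope = f$slope, slope_se = f$slope_se,
                   intercept = f$intercept, n = f$n)
  }
  slopes <- steps |>
    dplyr::group_by(cell_id, stim_direction) |>
    dplyr::reframe(slope_one(dplyr::pick(dplyr::everything()))) |>
    tidyr::pivot_wider(names_from = stim_direction,
                       values_from = c(slope, slope_se, intercept, n))
  at30 <- steps |>
    dplyr::filter(stim_magnitude_deg == 30) |>
    dplyr::group_by(cell_id, stim_direction) |>
    dplyr::summarise(mean_peak = mean(peak_response),
                     cv = trial_cv(peak_response), .groups = "drop")
  r30 <- at30 |>
    dplyr::select(cell_id, stim_direction, mean_peak) |>
    tidyr::pivot_wider(names_from = stim_direction,
                       values_from = mean_peak, names_prefix = "peak30_")
  cv30 <- at30 |>
    dplyr::filter(stim_direction == "ipsi") |>
    dplyr::select(cell_id, cv_30deg_ipsi = cv)
  resp <- responsiveness_test(steps) |>
    dplyr::filter(stim_magnitude_deg == 30) |>
    dplyr::select(cell_id, stim_direction, responsive) |>
    tidyr::pivot_wider(names_from = stim_direction,
                       values_from = responsive,
                       names_prefix = "responsive30_")
  out <- slopes |>
    dplyr::left_join(r30, by = "cell_id") |>
    dplyr::left_join(cv30, by = "cell_id") |>
    dplyr::left_join(resp, by = "cell_id")
  if (all(c("peak30_ipsi", "peak30_contra") %in% names(out))) {
    out$di <- directionality_index(out$peak30_ipsi, out$peak30_contra)
    out$di_defined <- is.finite(out$peak30_ipsi + out$peak30_contra) &
      (out$peak30_ipsi + out$peak30_contra) > 0
  }
  if (n_shuffles > 0) {
    lab <- early_tuned_labels(peaks, n_shuffles = n_shuffles, seed = seed)
    tuned <- lab |>
      dplyr::select(cell_id, direction, early_tuned) |>
      tidyr::pivot_wider(names_from = direction, values_from = early_tuned,
                        names_prefix = "tuned_")
    out <- dplyr::left_join(out, tuned, by = "cell_id")
  }
  out
}
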