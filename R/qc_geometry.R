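# Imaging-stability and mounting-geometry QC ------------------------------

#' Field-of-view shift between two frames by normalized cross-correlation
#'
#' Scans integer pixel lags and computes, at each lag, the Pearson
#' correlation between the overlapping regions of the two frames (zero-mean,
#' unit-variance per overlap: standard normalized cross-correlation). The
#' estimated shift is the argmax lag, with ties broken toward the smallest
#' lag magnitude; lags are limited to 50% overlap. Also reports the
#' correlation at zero lag (the frames' similarity without any shift), the
#' standard summary of acute field-of-view stability.
#'
#' The convention is `post[y, x] ~ pre[y - dy, x - dx]`: a positive `dx`
#' means the image content moved toward higher column indices.
#'
#' @param frame_pre,frame_post Equal-sized numeric matrices (>= 16 x 16).
#' @param pixel_size_um Pixel size for the micron conversion.
#' @param max_lag Maximum lag scanned per axis (default: half the smaller
#'   image dimension).
#' @param low_conf_r Peak correlations below this value flag the estimate as
#'   low confidence (e.g. structureless/noise frames).
#' @return List of class `tipm_frame_shift`: `shift_px` (`c(dx, dy)`),
#'   `dx_um`, `dy_um`, `r_zero_shift`, `r_peak`, `low_confidence`,
#'   `undefined` (constant input), and the full correlation matrix
#'   `r_matrix` (lags as dimnames).
#' @export
frame_shift <- function(frame_pre, frame_post, pixel_size_um = 1,
                        max_lag = NULL, low_conf_r = 0.3) {
  if (!is.matrix(frame_pre) || !is.matrix(frame_post) ||
      !all(dim(frame_pre) == dim(frame_post))) {
    abort_user("frames must be equal-sized matrices")
  }
  nr <- nrow(frame_pre)
  nc <- ncol(frame_pre)
  if (nr < 16 || nc < 16) abort_user("frames must be at least 16 x 16")
  if (sd(frame_pre) == 0 || sd(frame_post) == 0) {
    return(structure(list(shift_px = c(NA_integer_, NA_integer_),
                          dx_um = NA_real_, dy_um = NA_real_,
                          r_zero_shift = NA_real_, r_peak = NA_real_,
                          low_confidence = TRUE, undefined = TRUE,
                          r_matrix = NULL),
                     class = "tipm_frame_shift"))
  }
  max_lag <- max_lag %||% floor(min(nr, nc) / 2)
  lags <- -max_lag:max_lag
  nl <- length(lags)
  r_mat <- matrix(NA_real_, nl, nl, dimnames = list(ly = lags, lx = lags))
  for (iy in seq_len(nl)) {
    ly <- lags[iy]
    ry_post <- max(1, 1 + ly):min(nr, nr + ly)
    ry_pre <- ry_post - ly
    for (ix in seq_len(nl)) {
      lx <- lags[ix]
      cx_post <- max(1, 1 + lx):min(nc, nc + lx)
      cx_pre <- cx_post - lx
      a <- frame_pre[ry_pre, cx_pre]
      b <- frame_post[ry_post, cx_post]
      if (sd(a) == 0 || sd(b) == 0) next
      r_mat[iy, ix] <- cor(as.vector(a), as.vector(b))
    }
  }
  r_peak <- max(r_mat, na.rm = TRUE)
  cand <- which(r_mat >= r_peak - 1e-12, arr.ind = TRUE)
  cly <- lags[cand[, 1]]
  clx <- lags[cand[, 2]]
  ord <- order(clx^2 + cly^2, abs(clx), abs(cly), clx, cly)
  best <- ord[1]
  shift <- c(clx[best], cly[best])
  structure(list(shift_px = shift,
                 dx_um = shift[1] * pixel_size_um,
                 dy_um = shift[2] * pixel_size_um,
                 r_zero_shift = r_mat[max_lag + 1, max_lag + 1],
                 r_peak = r_peak,
                 low_confidence = r_peak < low_conf_r,
                 undefined = FALSE,
                 r_matrix = r_mat),
            class = "tipm_frame_shift")
}

#' @export
print.tipm_frame_shift <- function(x, ...) {
  if (isTRUE(x$undefined)) {
    cat("<tipm_frame_shift> undefined (constant frame)\n")
  } else {
    cat(sprintf("<tipm_frame_shift> shift (%d, %d) px, r0 = %.3f, peak r = %.3f%s\n",
                x$shift_px[1], x$shift_px[2], x$r_zero_shift, x$r_peak,
                if (x$low_confidence) " [low confidence]" else ""))
  }
  invisible(x)
}

#' Mounting roll angle from a bilateral depth difference
#'
#' The roll of a mounted fish is estimated from the depth (z) difference
#' between the left and right Mauthner lateral dendrite tips, divided by the
#' average mediolateral distance between them, via the arctangent:
#' `atan(dz / x_ref)` in degrees, signed by the z difference.
#'
#' @param dz_um Bilateral depth difference in micrometers (vectorized).
#' @param x_ref_um Mediolateral reference distance in micrometers
#'   (default 171.8, the population-average landmark separation).
#' @return Roll angle(s) in degrees.
#' @export
#' @examples
#' roll_angle(7.2)  # about 2.4 degrees
roll_angle <- function(dz_um, x_ref_um = 171.8) {
  if (!is.finite(x_ref_um) || x_ref_um <= 0) {
    abort_user("x_ref_um must be positive")
  }
  atan(dz_um / x_ref_um) * 180 / pi
}

#' Read a landmark/cell position table
#'
#' Expects CSV columns `cell_id`, `hemisphere`, `x_um`, `y_um`, `z_um` in
#' absolute stack coordinates, including one reference row per hemisphere
#' with `cell_id = "mauthner"` marking the lateral dendrite tip. The sign
#' convention is +x lateral, +y rostral, +z dorsal (ventral cells have
#' negative relative z).
#'
#' @param path CSV file path.
#' @return Tibble of positions.
#' @export
read_positions <- function(path) {
  pos <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("cell_id", "hemisphere", "x_um", "y_um", "z_um")
  missing_cols <- setdiff(need, names(pos))
  if (length(missing_cols) > 0) {
    abort_user("position table lacks columns: ",
               paste(missing_cols, collapse = ", "))
  }
  pos
}

#' Cell positions relative to the hemisphere's Mauthner landmark
#'
#' Subtracts, per hemisphere, the Mauthner lateral dendrite reference
#' position from every cell in that hemisphere, converting absolute stack
#' coordinates to landmark-relative coordinates.
#'
#' @param positions Tibble from [read_positions()] (reference rows have
#'   `cell_id = "mauthner"`).
#' @return Tibble of cells with relative `x_um`, `y_um`, `z_um`.
#' @export
relative_positions <- function(positions) {
  refs <- positions[positions$cell_id == "mauthner", ]
  if (nrow(refs) == 0) {
    abort_user("no 'mauthner' reference rows in the position table")
  }
  cells <- positions[positions$cell_id != "mauthner", ]
  out <- list()
  for (h in unique(cells$hemisphere)) {
    r <- refs[refs$hemisphere == h, ]
    if (nrow(r) != 1) {
      abort_user("hemisphere '", h, "' needs exactly one mauthner reference")
    }
    d <- cells[cells$hemisphere == h, ]
    d$x_um <- d$x_um - r$x_um
    d$y_um <- d$y_um - r$y_um
    d$z_um <- d$z_um - r$z_um
    out[[h]] <- d
  }
  dplyr::bind_rows(out)
}

#' Mounting orientation from bilateral landmarks
#'
#' Computes the roll angle of a mount from the z difference between the left
#' and right Mauthner references (left minus right).
#'
#' @param positions Tibble with the two `"mauthner"` reference rows.
#' @param x_ref_um Mediolateral reference distance (micrometers).
#' @return One-row tibble: `dz_um`, `x_ref_um`, `roll_deg`.
#' @export
mount_orientation <- function(positions, x_ref_um = 171.8) {
  refs <- positions[positions$cell_id == "mauthner", ]
  zl <- refs$z_um[refs$hemisphere == "left"]
  zr <- refs$z_um[refs$hemisphere == "right"]
  if (length(zl) != 1 || length(zr) != 1) {
    abort_user("need exactly one mauthner reference per hemisphere")
  }
  dz <- zl - zr
  tibble::tibble(dz_um = dz, x_ref_um = x_ref_um,
                 roll_deg = roll_angle(dz, x_ref_um))
}

#' Compare soma positions between responsive and nonresponsive cells
#'
#' Per axis (mediolateral, rostrocaudal, dorsoventral), reports group means
#' and SDs and an unpaired t test between responsive and nonresponsive
#' cells. Axes with fewer than 2 cells in either group are skipped with a
#' reason rather than tested.
#'
#' @param positions Tibble of landmark-relative cell positions with columns
#'   `cell_id`, `x_um`, `y_um`, `z_um`.
#' @param responsive Logical vector (or tibble with `cell_id` +
#'   `responsive`) marking responsive cells.
#' @return Tibble with one row per axis: group sizes, means, SDs, mean
#'   difference (responsive minus nonresponsive), `t`, `p`, `skipped`.
#' @export
position_group_compare <- function(positions, responsive) {
  if (is.data.frame(responsive)) {
    m <- match(positions$cell_id, responsive$cell_id)
    responsive <- responsive$responsive[m]
  }
  stopifnot(length(responsive) == nrow(positions))
  keep <- !is.na(responsive)
  positions <- positions[keep, ]
  responsive <- responsive[keep]
  rows <- list()
  for (ax in c("x_um", "y_um", "z_um")) {
    v <- positions[[ax]]
    g1 <- v[responsive]
    g0 <- v[!responsive]
    base <- tibble::tibble(axis = ax, n_responsive = length(g1),
                           n_nonresponsive = length(g0),
                           mean_responsive = if (length(g1)) mean(g1) else NA_real_,
                           sd_responsive = if (length(g1) > 1) sd(g1) else NA_real_,
                           mean_nonresponsive = if (length(g0)) mean(g0) else NA_real_,
                           sd_nonresponsive = if (length(g0) > 1) sd(g0) else NA_real_)
    if (length(g1) < 2 || length(g0) < 2) {
      rows[[ax]] <- dplyr::bind_cols(base, tibble::tibble(
        mean_diff = NA_real_, t = NA_real_, p = NA_real_,
        skipped = "group with < 2 cells"))
      next
    }
    tt <- t.test(g1, g0)
    rows[[ax]] <- dplyr::bind_cols(base, tibble::tibble(
      mean_diff = mean(g1) - mean(g0), t = unname(tt$statistic),
      p = tt$p.value, skipped = NA_character_))
  }
  dplyr::bind_rows(rows)
}
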