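# Synthetic frame pairs for registration QC -------------------------------

#' Generate a synthetic pre/post frame pair with a known shift
#'
#' Renders a smooth scene of Gaussian blobs (soma-like structures) on a
#' larger canvas and crops two equal windows offset by the requested integer
#' shift, so that the second frame equals the first translated by
#' `(dx, dy)` with fresh content entering at the edges. Independent Gaussian
#' noise is added to each frame. The convention matches [frame_shift()]:
#' `post[y, x] = pre[y - dy, x - dx]` with x along columns and y along rows.
#'
#' @param shift_px Integer `c(dx, dy)` ground-truth shift in pixels.
#' @param size Frame side length in pixels.
#' @param n_blobs Number of Gaussian blobs in the scene; 0 gives pure noise.
#' @param noise_sd Gaussian noise SD relative to the unit-normalized scene.
#' @param seed Integer seed.
#' @return List of class `tipm_frame_pair`: `pre`, `post` (matrices in
#'   `[0, 1]`), `shift_px`, `size`, `seed`.
#' @export
#' @examples
#' pair <- generate_frame_pair(c(3, -2), seed = 1)
#' frame_shift(pair$pre, pair$post)$shift_px
generate_frame_pair <- function(shift_px = c(0, 0), size = 64, n_blobs = 40,
                                noise_sd = 0.02, seed = 1) {
  stopifnot(length(shift_px) == 2, size >= 16)
  dx <- as.integer(round(shift_px[1]))
  dy <- as.integer(round(shift_px[2]))
  if (max(abs(c(dx, dy))) >= size) {
    abort_user("shift must be smaller than the frame size")
  }
  margin <- max(16, abs(dx), abs(dy))
  big <- size + 2 * margin
  with_seed(mix_seed(seed, 31), {
    scene <- matrix(0, big, big)
    if (n_blobs > 0) {
      xs <- runif(n_blobs, 1, big)
      ys <- runif(n_blobs, 1, big)
      ss <- runif(n_blobs, 1.5, 4)
      amp <- runif(n_blobs, 0.5, 1)
      gx <- seq_len(big)
      for (b in seq_len(n_blobs)) {
        scene <- scene + amp[b] *
          (exp(-(gx - ys[b])^2 / (2 * ss[b]^2)) %o%
             exp(-(gx - xs[b])^2 / (2 * ss[b]^2)))
      }
      scene <- scene / max(scene)
    }
    rows <- margin + seq_len(size)
    cols <- margin + seq_len(size)
    pre <- scene[rows, cols]
    post <- scene[rows - dy, cols - dx]
    if (noise_sd > 0) {
      pre <- pre + matrix(rnorm(size^2, 0, noise_sd), size, size)
      post <- post + matrix(rnorm(size^2, 0, noise_sd), size, size)
    }
    lo <- min(pre, post)
    hi <- max(pre, post)
    pre <- (pre - lo) / (hi - lo)
    post <- (post - lo) / (hi - lo)
    structure(list(pre = pre, post = post, shift_px = c(dx, dy),
                   size = size, seed = seed),
              class = "tipm_frame_pair")
  })
}

#' Write / read a frame pair as a two-page TIFF with a JSON sidecar
#'
#' The first page is the pre-stimulus frame, the second the post-stimulus
#' frame; the sidecar records the ground-truth shift.
#'
#' @param pair A `tipm_frame_pair` from [generate_frame_pair()].
#' @param tif_path Path for the 2-page 32-bit float TIFF.
#' @param json_path Optional sidecar path (default: `tif_path` with a
#'   `.json` extension).
#' @return `tif_path`, invisibly.
#' @export
write_frame_pair <- function(pair, tif_path, json_path = NULL) {
  json_path <- json_path %||% sub("\\.tiff?$", ".json", tif_path)
  tiff::writeTIFF(list(pair$pre, pair$post), tif_path,
                  bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(shift_px = pair$shift_px, size = pair$size,
                            seed = pair$seed),
                       json_path, auto_unbox = TRUE, digits = NA)
  invisible(tif_path)
}

#' @rdname write_frame_pair
#' @export
read_frame_pair <- function(tif_path, json_path = NULL) {
  pages <- tiff::readTIFF(tif_path, all = TRUE)
  if (length(pages) < 2) abort_user("expected a 2-page TIFF")
  meta <- NULL
  json_path <- json_path %||% sub("\\.tiff?$", ".json", tif_path)
  if (file.exists(json_path)) meta <- jsonlite::read_json(json_path)
  structure(list(pre = pages[[1]], post = pages[[2]],
                 shift_px = if (!is.null(meta)) unlist(meta$shift_px) else NULL,
                 size = nrow(pages[[1]]), seed = meta$seed),
            class = "tipm_frame_pair")
}
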