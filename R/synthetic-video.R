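#' Optical/detector parameters for rendered fields
#'
#' @param pixel_size Pixel size in um/px.
#' @param shape Integer length-2, image size in px (rows, cols).
#' @param psf_sigma Gaussian point-spread-function SD in um.
#' @param photons_per_spot Expected photon count per spot per frame.
#' @param background Mean background level in counts/px (Poisson when noise
#'   is on).
#' @param read_noise_sd Gaussian read noise SD in counts.
#' @return A `field_params` list.
#' @export
field_params <- function(pixel_size = 0.1,
                         shape = c(256, 256),
                         psf_sigma = 0.15,
                         photons_per_spot = 5000,
                         background = 100,
                         read_noise_sd = 5) {
  assert_number(pixel_size, "pixel_size", lower = .Machine$double.eps)
  stopifnot(length(shape) == 2, all(shape >= 8))
  assert_number(psf_sigma, "psf_sigma", lower = .Machine$double.eps)
  assert_number(photons_per_spot, "photons_per_spot", lower = 0)
  assert_number(background, "background", lower = 0)
  assert_number(read_noise_sd, "read_noise_sd", lower = 0)
  structure(
    list(pixel_size = pixel_size, shape = as.integer(shape),
         psf_sigma = psf_sigma, photons_per_spot = photons_per_spot,
         background = background, read_noise_sd = read_noise_sd),
    class = "field_params"
  )
}

# add one spot's pixel-integrated Gaussian (total flux = amplitude, up to
# tails outside the frame) to `frame`; cx, cy in pixel-edge units
add_gaussian_spot <- function(frame, cx, cy, sigma_px, amplitude) {
  nr <- nrow(frame); nc <- ncol(frame)
  w <- ceiling(5 * sigma_px)
  cols <- max(1L, floor(cx - w)):min(nc, ceiling(cx + w))
  rows <- max(1L, floor(cy - w)):min(nr, ceiling(cy + w))
  if (!length(cols) || !length(rows)) return(frame)
  fx <- pnorm(cols, cx, sigma_px) - pnorm(cols - 1, cx, sigma_px)
  fy <- pnorm(rows, cy, sigma_px) - pnorm(rows - 1, cy, sigma_px)
  frame[rows, cols] <- frame[rows, cols] + amplitude * outer(fy, fx)
  frame
}

#' Render trajectories into a synthetic fluorescence video
#'
#' Each spot is drawn as a 2-D Gaussian of SD `psf_sigma` integrated over the
#' pixel grid, with per-frame amplitude drawn from
#' `Poisson(photons_per_spot)`; Poisson background and Gaussian read noise
#' are added. With `noise = FALSE` amplitudes and background are
#' deterministic (useful for flux-conservation checks). Tracks whose
#' positions fall outside the field are clipped to the border and flagged in
#' the metadata (`clipped = TRUE`) with a warning.
#'
#' @param tracks Track tibble (as from [simulate_tracks()]), coordinates in um.
#' @param field A [field_params()] object.
#' @param seed Integer seed.
#' @param noise If `FALSE`, render noiselessly.
#' @return An [image_stack()] with calibration metadata (`seed`, `clipped`).
#' @export
render_video <- function(tracks, field, seed = NULL, noise = TRUE) {
  stopifnot(inherits(field, "field_params"))
  dt <- attr(tracks, "dt") %||% NA_real_
  ps <- field$pixel_size
  nr <- field$shape[1]; nc <- field$shape[2]
  frames_idx <- sort(unique(tracks$frame))
  if (length(frames_idx) == 0) frames_idx <- 1L  # empty track set: one background frame
  clipped <- FALSE
  stack <- with_seed_or_stream(seed, {
    arr <- array(0, c(length(frames_idx), nr, nc))
    for (ti in seq_along(frames_idx)) {
      fr <- matrix(0, nr, nc)
      sp <- tracks[tracks$frame == frames_idx[ti], , drop = FALSE]
      if (nrow(sp)) {
        cx <- sp$x_um / ps
        cy <- sp$y_um / ps
        if (any(cx < 0 | cx > nc | cy < 0 | cy > nr)) {
          clipped <- TRUE
          cx <- pmin(pmax(cx, 0), nc)
          cy <- pmin(pmax(cy, 0), nr)
        }
        amp <- if (noise) rpois(nrow(sp), field$photons_per_spot)
               else rep(field$photons_per_spot, nrow(sp))
        sigma_px <- field$psf_sigma / ps
        for (s in seq_len(nrow(sp))) {
          fr <- add_gaussian_spot(fr, cx[s], cy[s], sigma_px, amp[s])
        }
      }
      bg <- if (noise) matrix(rpois(nr * nc, field$background), nr, nc)
            else matrix(field$background, nr, nc)
      rd <- if (noise && field$read_noise_sd > 0)
              matrix(rnorm(nr * nc, 0, field$read_noise_sd), nr, nc)
            else 0
      arr[ti, , ] <- fr + bg + rd
    }
    arr
  })
  if (clipped) warn("some track positions fell outside the field and were clipped")
  image_stack(stack, pixel_size = ps, dt = dt,
              metadata = list(seed = seed, clipped = clipped,
                              photons_per_spot = field$photons_per_spot,
                              background = field$background,
                              read_noise_sd = field$read_noise_sd))
}
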