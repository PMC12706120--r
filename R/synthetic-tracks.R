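#' Parameters of the two-pool lysosome motility model
#'
#' Lysosomes in live cells fall into a stationary (perinuclear) pool and a
#' mobile (peripheral) pool. The generator models the stationary pool as pure
#' Brownian motion with diffusion coefficient `d_stationary` and the mobile
#' pool as a persistent random walk (von Mises heading increments with
#' concentration `persistence_kappa`, directed speed `speed_mobile`)
#' superposed on Brownian diffusion with coefficient `d_mobile`.
#'
#' @param p_mobile Fraction of tracks drawn from the mobile pool, in \[0, 1\].
#' @param d_stationary Diffusion coefficient of the stationary pool (um^2/s).
#' @param d_mobile Diffusion coefficient superposed on mobile tracks (um^2/s).
#' @param speed_mobile Directed speed of the mobile pool (um/s).
#' @param persistence_kappa von Mises concentration (>= 0) of step-to-step
#'   heading changes; 0 gives an uncorrelated heading each frame, `Inf` a
#'   perfectly straight (ballistic) path. The default 50 makes the heading
#'   decorrelation time ~ `persistence_kappa * dt` = 0.5 s at the default
#'   frame interval, the scale of directed lysosomal runs.
#' @param dt Frame interval in seconds.
#' @param n_frames Number of frames per track (>= 2); 100 frames matches a
#'   typical fast live-cell acquisition.
#' @param field_size Numeric length-2, field extent in um (width, height).
#' @return A `motility_params` list.
#' @export
#' @examples
#' motility_params(p_mobile = 0, d_stationary = 0.05)
motility_params <- function(p_mobile = 0.5,
                            d_stationary = 1e-4,
                            d_mobile = 0.005,
                            speed_mobile = 1,
                            persistence_kappa = 50,
                            dt = 0.01,
                            n_frames = 100,
                            field_size = c(30, 30)) {
  assert_number(p_mobile, "p_mobile", 0, 1)
  assert_number(d_stationary, "d_stationary", 0)
  assert_number(d_mobile, "d_mobile", 0)
  assert_number(speed_mobile, "speed_mobile", 0)
  if (!is.numeric(persistence_kappa) || length(persistence_kappa) != 1 ||
      is.na(persistence_kappa) || persistence_kappa < 0) {
    abort("`persistence_kappa` must be a single number >= 0 (Inf allowed)")
  }
  assert_number(dt, "dt", lower = .Machine$double.eps)
  n_frames <- assert_count(n_frames, "n_frames", lower = 2)
  stopifnot(is.numeric(field_size), length(field_size) == 2, all(field_size > 0))
  structure(
    list(p_mobile = p_mobile, d_stationary = d_stationary,
         d_mobile = d_mobile, speed_mobile = speed_mobile,
         persistence_kappa = persistence_kappa, dt = dt,
         n_frames = n_frames, field_size = as.numeric(field_size)),
    class = "motility_params"
  )
}

#' Simulate lysosome trajectories from the two-pool motility model
#'
#' Each track is drawn from the mobile pool with probability
#' `params$p_mobile`. Mobile steps are `speed_mobile * dt` along a heading
#' that evolves by von Mises increments, plus an isotropic Gaussian diffusion
#' step of per-axis standard deviation `sqrt(2 * d_mobile * dt)`. Stationary
#' tracks take pure diffusion steps with `d_stationary`. Initial positions are
#' uniform over the field interior (10% margin), initial headings uniform on
#' \[0, 2*pi).
#'
#' @param params A [motility_params()] object.
#' @param n_tracks Number of tracks to simulate (>= 1).
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return A tibble with columns `track_id`, `frame` (1-based), `x_um`,
#'   `y_um`, `label` (`"mobile"`/`"stationary"`), carrying attributes `dt`
#'   (seconds) and `seed`.
#' @export
#' @examples
#' tr <- simulate_tracks(motility_params(p_mobile = 0), n_tracks = 3, seed = 1)
#' head(tr)
simulate_tracks <- function(params, n_tracks, seed = NULL) {
  stopifnot(inherits(params, "motility_params"))
  n_tracks <- assert_count(n_tracks, "n_tracks")
  out <- with_seed_or_stream(seed, {
    nf <- params$n_frames
    margin <- 0.1 * params$field_size
    labels <- ifelse(runif(n_tracks) < params$p_mobile, "mobile", "stationary")
    tracks <- vector("list", n_tracks)
    for (i in seq_len(n_tracks)) {
      x0 <- runif(1, margin[1], params$field_size[1] - margin[1])
      y0 <- runif(1, margin[2], params$field_size[2] - margin[2])
      if (labels[i] == "mobile") {
        dtheta <- rvonmises(nf - 1, 0, params$persistence_kappa)
        theta <- runif(1, 0, 2 * pi) + cumsum(c(0, dtheta[-(nf - 1)]))
        sddiff <- sqrt(2 * params$d_mobile * params$dt)
        dx <- params$speed_mobile * params$dt * cos(theta) + rnorm(nf - 1, 0, sddiff)
        dy <- params$speed_mobile * params$dt * sin(theta) + rnorm(nf - 1, 0, sddiff)
      } else {
        sddiff <- sqrt(2 * params$d_stationary * params$dt)
        dx <- rnorm(nf - 1, 0, sddiff)
        dy <- rnorm(nf - 1, 0, sddiff)
      }
      tracks[[i]] <- tibble::tibble(
        track_id = i,
        frame = seq_len(nf),
        x_um = x0 + cumsum(c(0, dx)),
        y_um = y0 + cumsum(c(0, dy)),
        label = labels[i]
      )
    }
    dplyr::bind_rows(tracks)
  })
  attr(out, "dt") <- params$dt
  attr(out, "seed") <- seed
  out
}
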