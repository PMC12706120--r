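#' Mobility classification rule
#'
#' A track is immobile when its displacement is strictly below
#' `immobile_threshold` (default 0.2 um, the standard live-cell rule:
#' displacement < 0.2 um defines immobile, so exactly 0.2 um is mobile).
#' `displacement_basis` chooses the displacement measure: net (start to end,
#' default) or the maximum distance from the origin over the track.
#'
#' @param immobile_threshold Threshold in um (> 0).
#' @param displacement_basis `"net"` or `"max"`.
#' @return A `mobility_rule` list.
#' @export
mobility_rule <- function(immobile_threshold = 0.2,
                          displacement_basis = c("net", "max")) {
  assert_number(immobile_threshold, "immobile_threshold",
                lower = .Machine$double.eps)
  structure(list(immobile_threshold = immobile_threshold,
                 displacement_basis = match.arg(displacement_basis)),
            class = "mobility_rule")
}

check_track_xy <- function(x, y) {
  if (length(x) < 2 || length(y) != length(x)) {
    abort("a track needs >= 2 samples with equal-length x and y")
  }
}

#' Per-track geometric statistics
#'
#' `path_length()` is the summed step length, `net_displacement()` the
#' start-to-end distance, and `straightness()` their ratio (1 for ballistic
#' motion, 0 for a closed loop; defined as 0 when the path length is 0).
#'
#' @param x,y Coordinates in um (>= 2 samples).
#' @return A length-1 numeric.
#' @export
path_length <- function(x, y) {
  check_track_xy(x, y)
  sum(sqrt(diff(x)^2 + diff(y)^2))
}

#' @rdname path_length
#' @export
net_displacement <- function(x, y) {
  check_track_xy(x, y)
  sqrt((x[length(x)] - x[1])^2 + (y[length(y)] - y[1])^2)
}

#' @rdname path_length
#' @export
straightness <- function(x, y) {
  p <- path_length(x, y)
  if (p == 0) return(0)
  net_displacement(x, y) / p
}

#' Mean velocity of a track
#'
#' Path length divided by track duration, with duration
#' `(n_samples - 1) * dt`.
#'
#' @param x,y Coordinates in um.
#' @param dt Frame interval in seconds.
#' @return Mean velocity in um/s.
#' @export
mean_velocity <- function(x, y, dt) {
  if (missing(dt) || is.null(dt) || is.na(dt)) abort("`dt` is required")
  check_track_xy(x, y)
  path_length(x, y) / ((length(x) - 1) * dt)
}

#' Mean squared displacement of a track
#'
#' `mode = "from_origin"` (default) returns the per-track scalar: the mean
#' over samples 2..N of the squared distance from the first position — one
#' MSD value per track. `mode = "time_averaged"` returns the standard
#' time-averaged curve `MSD(tau) = mean_i ||r(i+tau) - r(i)||^2` at the
#' requested integer lags.
#'
#' @param x,y Coordinates in um.
#' @param mode `"from_origin"` or `"time_averaged"`.
#' @param lags Integer lags (frames) for the time-averaged curve; defaults
#'   to `1:(n-1)`.
#' @return A scalar (from_origin) or a tibble `lag`, `msd` (time_averaged).
#' @export
msd <- function(x, y, mode = c("from_origin", "time_averaged"), lags = NULL) {
  mode <- match.arg(mode)
  check_track_xy(x, y)
  n <- length(x)
  if (mode == "from_origin") {
    return(mean((x[-1] - x[1])^2 + (y[-1] - y[1])^2))
  }
  if (is.null(lags)) lags <- seq_len(n - 1)
  if (any(lags < 1 | lags >= n)) abort("lags must be in [1, n_samples - 1]")
  vals <- vapply(lags, function(l) {
    i <- seq_len(n - l)
    mean((x[i + l] - x[i])^2 + (y[i + l] - y[i])^2)
  }, numeric(1))
  tibble::tibble(lag = as.integer(lags), msd = vals)
}

#' Classify displacements as mobile/immobile
#'
#' @param displacement Numeric displacement(s) in um, computed on the rule's
#'   basis.
#' @param rule A [mobility_rule()].
#' @return Logical: `TRUE` = mobile (displacement >= threshold).
#' @export
classify_mobility <- function(displacement, rule = mobility_rule()) {
  stopifnot(inherits(rule, "mobility_rule"))
  displacement >= rule$immobile_threshold
}

#' Net-displacement angles of a track set
#'
#' Per track, the direction of the start-to-end displacement,
#' `atan2(dy, dx)` mapped to \[0, 360) degrees counterclockwise from +x.
#' With `flip_y = TRUE` the y axis is negated first, so that "up" in image
#' (row/col) coordinates maps to 90 degrees. Tracks with zero net
#' displacement have no defined angle and are excluded; their count is
#' reported in the `n_excluded` attribute.
#'
#' @param tracks Track tibble (`track_id`, `frame`, `x_um`, `y_um`).
#' @param flip_y Negate y before computing angles (image coordinates).
#' @return Tibble `track_id`, `angle_deg`, with attribute `n_excluded`.
#' @export
displacement_angles <- function(tracks, flip_y = FALSE) {
  out <- tracks |>
    dplyr::arrange(.data$track_id, .data$frame) |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(
      dx = dplyr::last(.data$x_um) - dplyr::first(.data$x_um),
      dy = dplyr::last(.data$y_um) - dplyr::first(.data$y_um),
      n = dplyr::n(), .groups = "drop"
    )
  if (any(out$n < 2)) abort("all tracks need >= 2 samples")
  if (flip_y) out$dy <- -out$dy
  zero <- out$dx == 0 & out$dy == 0
  ang <- (atan2(out$dy, out$dx) * 180 / pi) %% 360
  res <- tibble::tibble(track_id = out$track_id[!zero],
                        angle_deg = ang[!zero])
  attr(res, "n_excluded") <- sum(zero)
  res
}

#' Compute the full per-track motility table
#'
#' One row per track: sample count, duration, path length, net displacement,
#' straightness, mean velocity, from-origin MSD, displacement angle, and the
#' mobile/immobile classification under `rule`.
#'
#' @param tracks Track tibble (`track_id`, `frame`, `x_um`, `y_um`),
#'   `dt` taken from the attribute unless given.
#' @param dt Frame interval in seconds.
#' @param rule A [mobility_rule()].
#' @param flip_y Passed to [displacement_angles()].
#' @return Tibble of per-track metrics (`angle_deg` is `NA` for zero net
#'   displacement).
#' @export
track_metrics <- function(tracks, dt = attr(tracks, "dt"),
                          rule = mobility_rule(), flip_y = FALSE) {
  if (is.null(dt) || is.na(dt)) abort("`dt` (frame interval) is required")
  tracks <- dplyr::arrange(tracks, .data$track_id, .data$frame)
  out <- tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(
      n_samples = dplyr::n(),
      path_length_um = path_length(.data$x_um, .data$y_um),
      net_displacement_um = net_displacement(.data$x_um, .data$y_um),
      max_displacement_um = sqrt(max(
        (.data$x_um - .data$x_um[1])^2 + (.data$y_um - .data$y_um[1])^2)),
      msd_um2 = msd(.data$x_um, .data$y_um, "from_origin"),
      dx = dplyr::last(.data$x_um) - dplyr::first(.data$x_um),
      dy = dplyr::last(.data$y_um) - dplyr::first(.data$y_um),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      duration_s = (.data$n_samples - 1) * dt,
      straightness = ifelse(.data$path_length_um > 0,
                            .data$net_displacement_um / .data$path_length_um, 0),
      mean_velocity_um_s = .data$path_length_um / .data$duration_s,
      angle_deg = ifelse(.data$dx == 0 & .data$dy == 0, NA_real_,
                         (atan2(if (flip_y) -.data$dy else .data$dy,
                                .data$dx) * 180 / pi) %% 360),
      mobile = classify_mobility(
        if (rule$displacement_basis == "net") .data$net_displacement_um
        else .data$max_displacement_um, rule)
    ) |>
    dplyr::select("track_id", "n_samples", "duration_s", "path_length_um",
                  "net_displacement_um", "max_displacement_um",
                  "straightness", "mean_velocity_um_s", "msd_um2",
                  "angle_deg", "mobile")
  out
}

#' Ensemble time-averaged MSD and diffusion-coefficient fit
#'
#' Averages the per-track time-averaged MSD over all tracks at the given
#' lags and fits `MSD(tau) = 4 D tau` (2-D Brownian motion) by least squares
#' through the origin.
#'
#' @param tracks Track tibble; `dt` from attribute unless given.
#' @param lags Integer lags (frames), default 1:10.
#' @param dt Frame interval (s).
#' @return A list: `msd` (tibble `lag`, `tau_s`, `msd`), `d_fit` (um^2/s).
#' @export
ensemble_msd <- function(tracks, lags = 1:10, dt = attr(tracks, "dt")) {
  if (is.null(dt) || is.na(dt)) abort("`dt` (frame interval) is required")
  tracks <- dplyr::arrange(tracks, .data$track_id, .data$frame)
  per <- tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::group_map(~ {
      l <- lags[lags < nrow(.x)]
      if (!length(l)) return(NULL)
      msd(.x$x_um, .x$y_um, "time_averaged", lags = l)
    })
  curve <- dplyr::bind_rows(per) |>
    dplyr::group_by(.data$lag) |>
    dplyr::summarise(msd = mean(.data$msd), .groups = "drop") |>
    dplyr::mutate(tau_s = .data$lag * dt)
  d_fit <- sum(curve$msd * curve$tau_s) / (4 * sum(curve$tau_s^2))
  list(msd = dplyr::select(curve, "lag", "tau_s", "msd"), d_fit = d_fit)
}
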