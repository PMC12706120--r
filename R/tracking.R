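#' Particle-linking parameters
#'
#' @param max_link_distance Hard gate on per-frame displacement (um/frame);
#'   across a closed gap of g frames the gate scales to
#'   `(g + 1) * max_link_distance`.
#' @param max_gap Maximum number of missed frames bridged (0 disables gap
#'   closing; positions across gaps are not interpolated).
#' @param min_track_length Minimum number of samples for a track to be kept.
#' @return A `link_params` list.
#' @export
link_params <- function(max_link_distance = 0.5, max_gap = 0,
                        min_track_length = 5) {
  assert_number(max_link_distance, "max_link_distance",
                lower = .Machine$double.eps)
  max_gap <- assert_count(max_gap, "max_gap", lower = 0)
  min_track_length <- assert_count(min_track_length, "min_track_length",
                                   lower = 1)
  structure(list(max_link_distance = max_link_distance, max_gap = max_gap,
                 min_track_length = min_track_length),
            class = "link_params")
}

# maximum-weight bipartite matching between point sets a (n1 x 2) and b
# (n2 x 2) with per-pair gates; maximises match count first, then minimises
# summed squared distance. Returns for each row of b the matched row of a
# (or NA).
match_points <- function(a, b, gate) {
  n1 <- nrow(a); n2 <- nrow(b)
  if (n1 == 0 || n2 == 0) return(rep(NA_integer_, n2))
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  gate2 <- if (length(gate) == 1) matrix(gate^2, n1, n2) else
    matrix(gate^2, n1, n2)
  ok <- d2 <= gate2
  if (!any(ok)) return(rep(NA_integer_, n2))
  M <- max(gate2) * (min(n1, n2) + 1) + 1
  idx <- which(ok, arr.ind = TRUE)
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, n1), rep(TRUE, n2)),
    edges = as.vector(t(cbind(idx[, 1], n1 + idx[, 2])))
  )
  w <- M - d2[idx]
  m <- igraph::max_bipartite_match(g, weights = w)$matching
  out <- m[n1 + seq_len(n2)]
  ifelse(is.na(out), NA_integer_, as.integer(out))
}

#' Link per-frame detections into trajectories
#'
#' For each frame, detections are assigned one-to-one to open track ends by
#' exact maximum-weight bipartite matching that maximises the number of
#' links within the distance gate and, among those, minimises the summed
#' squared displacement. Unmatched detections start new tracks; tracks
#' unmatched for more than `max_gap` frames are closed; tracks shorter than
#' `min_track_length` samples are dropped.
#'
#' @param spots Spot tibble (`frame`, `x_um`, `y_um`, optionally
#'   `intensity`), sorted or not; calibration `dt` is taken from the tibble's
#'   `dt` attribute unless given.
#' @param params A [link_params()].
#' @param dt Frame interval in seconds (required for downstream motility).
#' @return Track tibble: `track_id`, `frame`, `x_um`, `y_um`, `intensity`,
#'   with attribute `dt`.
#' @export
link_spots <- function(spots, params = link_params(), dt = attr(spots, "dt")) {
  if (is.null(dt) || is.na(dt)) abort("`dt` (frame interval) is required")
  if (!all(c("frame", "x_um", "y_um") %in% names(spots))) {
    abort("`spots` needs columns frame, x_um, y_um")
  }
  spots <- dplyr::arrange(spots, .data$frame)
  if (!"intensity" %in% names(spots)) spots$intensity <- NA_real_
  frames <- if (nrow(spots)) seq(min(spots$frame), max(spots$frame)) else integer()
  tracks <- list()      # closed + growing: list of data frames
  open_idx <- integer() # indices into `tracks` of open tracks
  last_frame <- integer(); last_xy <- matrix(numeric(), 0, 2)
  for (f in frames) {
    det <- spots[spots$frame == f, , drop = FALSE]
    n_open <- length(open_idx)
    match <- rep(NA_integer_, nrow(det))
    if (n_open && nrow(det)) {
      elapsed <- f - last_frame
      usable <- which(elapsed <= params$max_gap + 1)
      if (length(usable)) {
        a <- last_xy[usable, , drop = FALSE]
        b <- cbind(det$x_um, det$y_um)
        # per-candidate gate: scale by elapsed frames (rows of the cost)
        d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
        gates <- (params$max_link_distance * elapsed[usable])^2
        ok <- sweep(d2, 1, gates, "<=")
        if (any(ok)) {
          idx <- which(ok, arr.ind = TRUE)
          M <- max(gates) * (min(nrow(a), nrow(b)) + 1) + 1
          g <- igraph::make_bipartite_graph(
            types = c(rep(FALSE, nrow(a)), rep(TRUE, nrow(b))),
            edges = as.vector(t(cbind(idx[, 1], nrow(a) + idx[, 2])))
          )
          m <- igraph::max_bipartite_match(g, weights = M - d2[idx])$matching
          mm <- m[nrow(a) + seq_len(nrow(b))]
          match <- ifelse(is.na(mm), NA_integer_, usable[as.integer(mm)])
        }
      }
    }
    new_open <- integer(); new_last_frame <- integer(); new_xy <- NULL
    taken <- rep(FALSE, n_open)
    for (j in seq_len(nrow(det))) {
      row <- list(frame = det$frame[j], x_um = det$x_um[j], y_um = det$y_um[j],
                  intensity = det$intensity[j])
      if (!is.na(match[j])) {
        ti <- open_idx[match[j]]
        tracks[[ti]] <- rbind(tracks[[ti]], as.data.frame(row))
        taken[match[j]] <- TRUE
        new_open <- c(new_open, ti)
      } else {
        tracks[[length(tracks) + 1]] <- as.data.frame(row)
        ti <- length(tracks)
        new_open <- c(new_open, ti)
      }
      new_last_frame <- c(new_last_frame, f)
      new_xy <- rbind(new_xy, c(det$x_um[j], det$y_um[j]))
    }
    # keep unmatched-but-still-within-gap tracks open
    for (k in seq_len(n_open)) {
      if (!taken[k] && (f - last_frame[k]) <= params$max_gap) {
        new_open <- c(new_open, open_idx[k])
        new_last_frame <- c(new_last_frame, last_frame[k])
        new_xy <- rbind(new_xy, last_xy[k, ])
      }
    }
    open_idx <- new_open
    last_frame <- new_last_frame
    last_xy <- if (is.null(new_xy)) matrix(numeric(), 0, 2) else new_xy
  }
  keep <- vapply(tracks, nrow, integer(1)) >= params$min_track_length
  tracks <- tracks[keep]
  out <- if (length(tracks)) {
    dplyr::bind_rows(purrr::imap(tracks, function(tr, i) {
      tibble::tibble(track_id = i, frame = tr$frame, x_um = tr$x_um,
                     y_um = tr$y_um, intensity = tr$intensity)
    }))
  } else {
    tibble::tibble(track_id = integer(), frame = integer(), x_um = numeric(),
                   y_um = numeric(), intensity = numeric())
  }
  attr(out, "dt") <- dt
  out
}

#' Evaluate linked tracks against ground-truth trajectories
#'
#' Matches detections to truth positions frame by frame (optimal matching
#' within `match_radius`) and scores (i) per-frame detection recall and
#' precision and (ii) track identity accuracy: the fraction of truth links
#' (consecutive-frame pairs within a truth track) whose two endpoints are
#' matched to samples of one and the same linked track.
#'
#' @param truth Truth track tibble (`track_id`, `frame`, `x_um`, `y_um`).
#' @param tracks Linked track tibble ([link_spots()]).
#' @param match_radius Matching radius in um.
#' @return A list (class `tracking_eval`): `recall`, `precision`,
#'   `identity_accuracy`, `n_truth_spots`, `n_detected_spots`,
#'   `n_truth_links`, `n_correct_links`.
#' @export
evaluate_tracking <- function(truth, tracks, match_radius) {
  assert_number(match_radius, "match_radius", lower = .Machine$double.eps)
  frames <- sort(unique(truth$frame))
  n_truth <- nrow(truth); n_det <- nrow(tracks)
  matched_truth <- 0L
  # per (frame, truth track) -> linked track id
  map <- list()
  for (f in frames) {
    tr <- truth[truth$frame == f, , drop = FALSE]
    de <- tracks[tracks$frame == f, , drop = FALSE]
    m <- match_points(cbind(tr$x_um, tr$y_um), cbind(de$x_um, de$y_um),
                      match_radius)
    matched_truth <- matched_truth + sum(!is.na(m))
    for (j in seq_along(m)) {
      if (!is.na(m[j])) {
        map[[paste(f, tr$track_id[m[j]], sep = "_")]] <- de$track_id[j]
      }
    }
  }
  # truth links
  n_links <- 0L; n_correct <- 0L
  for (id in unique(truth$track_id)) {
    tf <- sort(truth$frame[truth$track_id == id])
    for (k in seq_len(length(tf) - 1)) {
      if (tf[k + 1] != tf[k] + 1) next
      n_links <- n_links + 1L
      a <- map[[paste(tf[k], id, sep = "_")]]
      b <- map[[paste(tf[k + 1], id, sep = "_")]]
      if (!is.null(a) && !is.null(b) && a == b) n_correct <- n_correct + 1L
    }
  }
  structure(list(
    recall = if (n_truth) matched_truth / n_truth else 0,
    precision = if (n_det) matched_truth / n_det else 0,
    identity_accuracy = if (n_links) n_correct / n_links else NA_real_,
    n_truth_spots = n_truth, n_detected_spots = n_det,
    n_truth_links = n_links, n_correct_links = n_correct
  ), class = "tracking_eval")
}

#' @export
print.tracking_eval <- function(x, ...) {
  cat(sprintf(paste0("<tracking_eval> recall %.3f, precision %.3f, ",
                     "identity accuracy %s (%d/%d links)\n"),
              x$recall, x$precision,
              ifelse(is.na(x$identity_accuracy), "NA",
                     sprintf("%.3f", x$identity_accuracy)),
              x$n_correct_links, x$n_truth_links))
  invisible(x)
}
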