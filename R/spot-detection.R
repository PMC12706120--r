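#' Spot-detection parameters
#'
#' Defaults follow the live-cell lysosome imaging protocol: median filter of
#' pixel radius 2, rolling-ball background of radius 5 px, bright-spot
#' diameter 0.6 um. `threshold_k` (the detector's only free threshold) is the
#' number of robust noise SDs a local maximum of the scale-normalised
#' Laplacian-of-Gaussian response must exceed; the noise floor is
#' `1.4826 * MAD` of the preprocessed frame.
#'
#' @param median_radius Disk radius of the median filter, px (>= 1).
#' @param ball_radius Rolling-ball (grayscale opening) radius, px (>= 1).
#' @param spot_diameter Expected spot diameter, um (> 0).
#' @param threshold_k Detection threshold in noise SD multiples.
#' @return A `detection_params` list.
#' @export
detection_params <- function(median_radius = 2, ball_radius = 5,
                             spot_diameter = 0.6, threshold_k = 5) {
  median_radius <- assert_count(median_radius, "median_radius")
  ball_radius <- assert_count(ball_radius, "ball_radius")
  assert_number(spot_diameter, "spot_diameter", lower = .Machine$double.eps)
  assert_number(threshold_k, "threshold_k", lower = 0)
  structure(list(median_radius = median_radius, ball_radius = ball_radius,
                 spot_diameter = spot_diameter, threshold_k = threshold_k),
            class = "detection_params")
}

# grayscale erosion/dilation with a disk structuring element (replicate border)
disk_erode <- function(m, radius) {
  off <- disk_offsets(radius)
  out <- m
  for (k in seq_len(nrow(off))) {
    if (off$di[k] == 0 && off$dj[k] == 0) next
    out <- pmin(out, shift_replicate(m, off$di[k], off$dj[k]))
  }
  out
}

disk_dilate <- function(m, radius) {
  off <- disk_offsets(radius)
  out <- m
  for (k in seq_len(nrow(off))) {
    if (off$di[k] == 0 && off$dj[k] == 0) next
    out <- pmax(out, shift_replicate(m, off$di[k], off$dj[k]))
  }
  out
}

disk_median <- function(m, radius) {
  off <- disk_offsets(radius)
  vecs <- lapply(seq_len(nrow(off)), function(k) {
    as.vector(shift_replicate(m, off$di[k], off$dj[k]))
  })
  matrix(stack_median(vecs), nrow(m), ncol(m))
}

#' Preprocess a frame: disk median then rolling-ball background subtraction
#'
#' Applies a median filter with a disk kernel of radius
#' `params$median_radius`, estimates the background by grayscale opening
#' (erosion then dilation) with a disk of radius `params$ball_radius`, and
#' subtracts it. The result is clamped at 0.
#'
#' @param frame 2-D numeric matrix of finite intensities.
#' @param params A [detection_params()].
#' @return Matrix of the same shape, everywhere >= 0.
#' @export
preprocess_frame <- function(frame, params = detection_params()) {
  stopifnot(is.matrix(frame), all(is.finite(frame)))
  if (min(dim(frame)) < 2 * params$ball_radius + 1) {
    abort("frame smaller than 2 * ball_radius + 1 in one dimension")
  }
  med <- disk_median(frame, params$median_radius)
  bg <- disk_dilate(disk_erode(med, params$ball_radius), params$ball_radius)
  pmax(med - bg, 0)
}

# separable Gaussian blur with replicate padding
gaussian_blur <- function(m, sigma) {
  w <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-w):w)^2 / (2 * sigma^2))
  k <- k / sum(k)
  conv1 <- function(mat) {
    # along rows (first index), replicate-padded
    nr <- nrow(mat)
    out <- matrix(0, nr, ncol(mat))
    for (o in (-w):w) {
      idx <- pmin(pmax(seq_len(nr) + o, 1L), nr)
      out <- out + k[o + w + 1] * mat[idx, , drop = FALSE]
    }
    out
  }
  t(conv1(t(conv1(m))))
}

# scale-normalised Laplacian-of-Gaussian response (positive at bright blobs)
log_response <- function(m, sigma) {
  g <- gaussian_blur(m, sigma)
  lap <- shift_replicate(g, 1, 0) + shift_replicate(g, -1, 0) +
    shift_replicate(g, 0, 1) + shift_replicate(g, 0, -1) - 4 * g
  -sigma^2 * lap
}

# half-max connected component around (r0, c0) within a square window
halfmax_mask <- function(m, r0, c0, win) {
  nr <- nrow(m); nc <- ncol(m)
  rows <- max(1L, r0 - win):min(nr, r0 + win)
  cols <- max(1L, c0 - win):min(nc, c0 + win)
  sub <- m[rows, cols, drop = FALSE] >= m[r0, c0] / 2
  lab <- EBImage::bwlabel(sub)
  keep <- lab == lab[which(rows == r0), which(cols == c0)]
  list(rows = rows, cols = cols, mask = keep & sub)
}

#' Detect lysosome-scale bright spots in a calibrated stack
#'
#' Per frame: preprocess ([preprocess_frame()]), compute the
#' scale-normalised Laplacian-of-Gaussian response at
#' `sigma_px = (spot_diameter / pixel_size) / (2 * sqrt(2))`, find local
#' maxima above `threshold_k * 1.4826 * MAD(preprocessed frame)`, refine each
#' to sub-pixel position by 3x3 quadratic interpolation, and build the binary
#' object as the above-half-max connected region of the preprocessed frame
#' around the maximum. Intensity is the mean of the *original* frame over
#' that mask; area is the mask area. Ties between equal neighbouring maxima
#' are broken towards the lowest (row, col).
#'
#' @param stack An [image_stack()] (or a single matrix plus `pixel_size`).
#' @param params A [detection_params()].
#' @param pixel_size Pixel size in um/px, required if `stack` is a matrix.
#' @return A spot tibble: `frame`, `x_um`, `y_um`, `x_px`, `y_px` (0-based
#'   sub-pixel indices), `intensity`, `area_um2`, `cell_id` (`NA` until
#'   [assign_rois()]); attributes `pixel_size` and `dt` carry calibration.
#' @export
detect_spots <- function(stack, params = detection_params(), pixel_size = NULL) {
  if (is.matrix(stack)) {
    if (is.null(pixel_size)) abort("`pixel_size` required for a bare matrix")
    stack <- image_stack(stack, pixel_size)
  }
  stopifnot(inherits(stack, "image_stack"))
  ps <- stack$pixel_size
  if (params$spot_diameter < 2 * ps) abort("diameter below Nyquist (< 2 px)")
  sigma_px <- (params$spot_diameter / ps) / (2 * sqrt(2))
  win <- max(2L, ceiling(params$spot_diameter / ps))
  nt <- dim(stack$frames)[1]
  res <- vector("list", nt)
  for (t in seq_len(nt)) {
    fr <- stack$frames[t, , ]
    pre <- preprocess_frame(fr, params)
    resp <- log_response(pre, sigma_px)
    thr <- params$threshold_k * 1.4826 * mad(as.vector(pre), constant = 1)
    nr <- nrow(resp); nc <- ncol(resp)
    inner <- matrix(FALSE, nr, nc)
    inner[2:(nr - 1), 2:(nc - 1)] <- TRUE
    is_max <- resp > thr & inner
    for (o in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                   c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))) {
      is_max <- is_max & resp >= shift_replicate(resp, o[1], o[2])
    }
    idx <- which(is_max, arr.ind = TRUE)
    if (nrow(idx) > 1) {
      # plateau tie-break: drop any candidate with an equal-valued candidate
      # neighbour at lower (row, col)
      ord <- order(idx[, 1], idx[, 2])
      idx <- idx[ord, , drop = FALSE]
      keep <- rep(TRUE, nrow(idx))
      for (a in seq_len(nrow(idx))[-1]) {
        for (b in seq_len(a - 1)) {
          if (keep[b] && abs(idx[a, 1] - idx[b, 1]) <= 1 &&
              abs(idx[a, 2] - idx[b, 2]) <= 1 &&
              resp[idx[a, , drop = FALSE]] == resp[idx[b, , drop = FALSE]]) {
            keep[a] <- FALSE
          }
        }
      }
      idx <- idx[keep, , drop = FALSE]
    }
    if (nrow(idx) == 0) { res[t] <- list(NULL); next }
    rows <- numeric(nrow(idx)); cols <- numeric(nrow(idx))
    inten <- numeric(nrow(idx)); area <- numeric(nrow(idx))
    for (s in seq_len(nrow(idx))) {
      r0 <- idx[s, 1]; c0 <- idx[s, 2]
      # 3x3 quadratic sub-pixel refinement on the LoG response
      dr <- 0.5 * (resp[r0 - 1, c0] - resp[r0 + 1, c0]) /
        (resp[r0 - 1, c0] - 2 * resp[r0, c0] + resp[r0 + 1, c0])
      dc <- 0.5 * (resp[r0, c0 - 1] - resp[r0, c0 + 1]) /
        (resp[r0, c0 - 1] - 2 * resp[r0, c0] + resp[r0, c0 + 1])
      if (!is.finite(dr) || abs(dr) > 1) dr <- 0
      if (!is.finite(dc) || abs(dc) > 1) dc <- 0
      rows[s] <- r0 + dr; cols[s] <- c0 + dc
      hm <- halfmax_mask(pre, r0, c0, win)
      inten[s] <- mean(fr[hm$rows, hm$cols][hm$mask])
      area[s] <- sum(hm$mask) * ps^2
    }
    res[[t]] <- tibble::tibble(
      frame = t,
      x_um = (cols - 1 + 0.5) * ps,
      y_um = (rows - 1 + 0.5) * ps,
      x_px = cols - 1, y_px = rows - 1,
      intensity = inten, area_um2 = area, cell_id = NA_integer_
    )
  }
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) {
    out <- tibble::tibble(frame = integer(), x_um = numeric(), y_um = numeric(),
                          x_px = numeric(), y_px = numeric(),
                          intensity = numeric(), area_um2 = numeric(),
                          cell_id = NA_integer_[0])
  }
  attr(out, "pixel_size") <- ps
  attr(out, "dt") <- stack$dt
  out
}

#' Per-cell regions of interest
#'
#' A labelled mask assigning each pixel to a cell (positive integer label) or
#' to no cell (0), with physical calibration.
#'
#' @param mask Integer matrix of labels (0 = outside all cells); labels must
#'   be contiguous `1..n`.
#' @param pixel_size Pixel size, um/px.
#' @param nucleus_mask Optional logical matrix marking nucleus pixels (used
#'   by [per_cell_ratio()] to exclude nuclei from cytoplasmic means).
#' @return A `cell_rois` object with per-cell areas in um^2.
#' @export
cell_rois <- function(mask, pixel_size, nucleus_mask = NULL) {
  stopifnot(is.matrix(mask), all(mask >= 0), all(mask == round(mask)))
  assert_number(pixel_size, "pixel_size", lower = .Machine$double.eps)
  labs <- sort(unique(mask[mask > 0]))
  if (length(labs) && !identical(as.integer(labs), seq_along(labs))) {
    abort("ROI labels must be contiguous positive integers 1..n")
  }
  areas <- vapply(labs, function(l) sum(mask == l) * pixel_size^2, numeric(1))
  structure(list(mask = mask, pixel_size = pixel_size,
                 areas_um2 = setNames(areas, labs),
                 nucleus_mask = nucleus_mask),
            class = "cell_rois")
}

#' @export
print.cell_rois <- function(x, ...) {
  cat(sprintf("<cell_rois> %d cell(s), %d x %d px, %.4g um/px\n",
              length(x$areas_um2), nrow(x$mask), ncol(x$mask), x$pixel_size))
  invisible(x)
}

#' Assign detected spots to per-cell ROIs
#'
#' Each spot gets the label of the ROI containing its centre; spots outside
#' all ROIs get `cell_id = 0`.
#'
#' @param spots Spot tibble from [detect_spots()].
#' @param rois A [cell_rois()] over the same field.
#' @return The spot tibble with `cell_id` filled.
#' @export
assign_rois <- function(spots, rois) {
  stopifnot(inherits(rois, "cell_rois"))
  if (nrow(spots) == 0) return(spots)
  r <- floor(spots$y_um / rois$pixel_size) + 1
  c <- floor(spots$x_um / rois$pixel_size) + 1
  if (any(r < 1 | r > nrow(rois$mask) | c < 1 | c > ncol(rois$mask))) {
    abort("spot coordinates outside the ROI mask: geometry mismatch")
  }
  spots$cell_id <- as.integer(rois$mask[cbind(r, c)])
  spots
}

#' Per-cell and field-level spot summaries
#'
#' Reproduces the standard per-cell readouts: spot count, spots per unit
#' cell area, summed spot area, mean spot intensity, and cell area, plus a
#' field-level row (`level = "field"`, `cell_id = NA`) totalling all spots
#' (including those outside ROIs) with total cell area.
#'
#' @param spots Spot tibble with `cell_id` assigned ([assign_rois()]).
#' @param rois A [cell_rois()].
#' @return Tibble: `level`, `cell_id`, `n_spots`, `spots_per_um2`,
#'   `total_spot_area_um2`, `mean_spot_intensity`, `cell_area_um2`.
#' @export
summarize_spots <- function(spots, rois) {
  stopifnot(inherits(rois, "cell_rois"))
  labs <- as.integer(names(rois$areas_um2))
  per_cell <- purrr::map(labs, function(l) {
    sp <- spots[!is.na(spots$cell_id) & spots$cell_id == l, , drop = FALSE]
    tibble::tibble(
      level = "cell", cell_id = l, n_spots = nrow(sp),
      spots_per_um2 = nrow(sp) / rois$areas_um2[[as.character(l)]],
      total_spot_area_um2 = sum(sp$area_um2),
      mean_spot_intensity = if (nrow(sp)) mean(sp$intensity) else NA_real_,
      cell_area_um2 = rois$areas_um2[[as.character(l)]]
    )
  })
  tot_area <- sum(rois$areas_um2)
  field <- tibble::tibble(
    level = "field", cell_id = NA_integer_, n_spots = nrow(spots),
    spots_per_um2 = if (tot_area > 0) nrow(spots) / tot_area else NA_real_,
    total_spot_area_um2 = sum(spots$area_um2),
    mean_spot_intensity = if (nrow(spots)) mean(spots$intensity) else NA_real_,
    cell_area_um2 = tot_area
  )
  dplyr::bind_rows(c(per_cell, list(field)))
}
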