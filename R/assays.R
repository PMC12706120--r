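#' Segment cells from the nuclei channel
#'
#' Nuclei are found by Otsu thresholding of the (normalised) nuclei channel,
#' hole filling, and watershed splitting of touching nuclei on the distance
#' transform. Cell territories are grown from the nucleus seeds by
#' nearest-seed expansion (Voronoi propagation) capped at `max_radius_um`
#' from the nucleus boundary. With no nucleus detected an empty ROI set is
#' returned with a warning.
#'
#' @param img A [multi_channel_image()].
#' @param max_radius_um Territory cap: maximum distance from the nucleus
#'   (um, default 30).
#' @param min_nucleus_area_px Discard nucleus fragments below this size.
#' @return A [cell_rois()] whose `nucleus_mask` marks nucleus pixels.
#' @export
segment_cells <- function(img, max_radius_um = 30, min_nucleus_area_px = 20) {
  stopifnot(inherits(img, "multi_channel_image"))
  nuc <- img$nuclei
  rng <- range(nuc)
  if (rng[2] <= rng[1]) {
    warn("blank nuclei channel: no cells segmented")
    return(cell_rois(matrix(0L, nrow(nuc), ncol(nuc)), img$pixel_size))
  }
  norm <- (nuc - rng[1]) / (rng[2] - rng[1])
  thr <- EBImage::otsu(EBImage::Image(norm))
  bin <- norm > thr
  bin <- EBImage::fillHull(bin)
  dmap <- EBImage::distmap(bin)
  labels <- EBImage::watershed(dmap, tolerance = 1)
  labels <- EBImage::imageData(labels)
  # drop tiny fragments, relabel contiguously
  keep <- which(tabulate(labels[labels > 0]) >= min_nucleus_area_px)
  if (length(keep) == 0) {
    warn("no nucleus detected")
    return(cell_rois(matrix(0L, nrow(nuc), ncol(nuc)), img$pixel_size))
  }
  relab <- integer(max(labels))
  relab[keep] <- seq_along(keep)
  nl <- matrix(0L, nrow(nuc), ncol(nuc))
  nz <- labels > 0
  nl[nz] <- relab[labels[nz]]
  # Voronoi expansion from nuclei, capped at max_radius_um from the nucleus
  vor <- EBImage::imageData(EBImage::propagate(
    EBImage::Image(matrix(0, nrow(nuc), ncol(nuc))), seeds = nl, lambda = 1e8))
  dist_to_nuc <- EBImage::imageData(EBImage::distmap(nl == 0))
  territory <- vor
  territory[dist_to_nuc * img$pixel_size > max_radius_um] <- 0L
  cell_rois(matrix(as.integer(territory), nrow(nuc), ncol(nuc)),
            img$pixel_size, nucleus_mask = nl > 0)
}

# most frequent intensity (histogram mode on a fine grid)
intensity_mode <- function(x) {
  d <- density(x, n = 512)
  d$x[which.max(d$y)]
}

#' Per-cell two-channel ratio quantification (DQ-BSA readout)
#'
#' For each cell territory (nucleus pixels excluded when known), computes
#' background-corrected mean intensities of the uptake and degraded-probe
#' channels and their ratio `degraded / uptake` — the per-cell
#' proteolysis-per-endocytosis readout. Cells whose corrected uptake is
#' not positive are excluded (counted in the summary). Background per
#' channel: image mode (default) or rolling-ball (grayscale opening,
#' radius 25 px) evaluated per pixel.
#'
#' @param img A [multi_channel_image()].
#' @param rois A [cell_rois()] (e.g. [segment_cells()]).
#' @param background `"mode"` or `"rolling_ball"`.
#' @return A list: `cells` (tibble `cell_id`, `mean_uptake`,
#'   `mean_degraded`, `ratio`, `cell_area_um2`) and `summary` (tibble
#'   `mean_ratio`, `mean_uptake`, `mean_degraded`, `n_cells`,
#'   `n_excluded`).
#' @export
per_cell_ratio <- function(img, rois, background = c("mode", "rolling_ball")) {
  stopifnot(inherits(img, "multi_channel_image"), inherits(rois, "cell_rois"))
  background <- match.arg(background)
  if (!all(dim(img$uptake) == dim(rois$mask))) abort("geometry mismatch")
  if (background == "mode") {
    up_bg <- intensity_mode(as.vector(img$uptake))
    dq_bg <- intensity_mode(as.vector(img$degraded))
    up_corr <- img$uptake - up_bg
    dq_corr <- img$degraded - dq_bg
  } else {
    up_corr <- img$uptake - disk_dilate(disk_erode(img$uptake, 25), 25)
    dq_corr <- img$degraded - disk_dilate(disk_erode(img$degraded, 25), 25)
  }
  labs <- as.integer(names(rois$areas_um2))
  cyto <- rois$mask
  if (!is.null(rois$nucleus_mask)) cyto[rois$nucleus_mask] <- 0L
  rows <- purrr::map(labs, function(l) {
    px <- cyto == l
    tibble::tibble(cell_id = l,
                   mean_uptake = mean(up_corr[px]),
                   mean_degraded = mean(dq_corr[px]),
                   cell_area_um2 = rois$areas_um2[[as.character(l)]])
  }) |> dplyr::bind_rows()
  rows$ratio <- ifelse(rows$mean_uptake > 0,
                       rows$mean_degraded / rows$mean_uptake, NA_real_)
  ok <- !is.na(rows$ratio)
  list(
    cells = rows[ok, ],
    summary = tibble::tibble(
      mean_ratio = mean(rows$ratio[ok]),
      mean_uptake = mean(rows$mean_uptake[ok]),
      mean_degraded = mean(rows$mean_degraded[ok]),
      n_cells = sum(ok), n_excluded = sum(!ok)
    )
  )
}

#' Cathepsin activity from plate-reader fluorescence
#'
#' Duplicate wells are averaged per sample and condition; activity is
#' blank-corrected fluorescence normalised to incubation time and protein
#' amount, `(F - F_blank) / (minutes * mg)` in RFU/min/mg. The
#' inhibitor-corrected specific activity subtracts the inhibited control's
#' activity. Negative corrected activities are reported as 0 and flagged.
#'
#' @param table Tibble with columns `sample`, `condition`
#'   (`sample`/`inhibited`/`blank`), `rfu`, `minutes`, `mg` (as produced by
#'   [simulate_platereader()] or read from a plate CSV).
#' @return Tibble: `sample`, `activity_rfu_min_mg`,
#'   `inhibited_activity_rfu_min_mg`, `specific_activity_rfu_min_mg`,
#'   `clamped` (TRUE when a negative value was reported as 0).
#' @export
cathepsin_activity <- function(table) {
  need <- c("sample", "condition", "rfu", "minutes", "mg")
  if (!all(need %in% names(table))) {
    abort(paste("plate table needs columns:", paste(need, collapse = ", ")))
  }
  blanks <- table[table$condition == "blank", , drop = FALSE]
  if (nrow(blanks) == 0) abort("no blank wells in plate table")
  f_blank <- mean(blanks$rfu)
  samp <- table[table$condition != "blank", , drop = FALSE]
  if (any(!is.finite(samp$mg) | samp$mg <= 0)) abort("`mg` must be > 0")
  if (any(samp$minutes <= 0)) abort("`minutes` must be > 0")
  agg <- samp |>
    dplyr::group_by(.data$sample, .data$condition) |>
    dplyr::summarise(rfu = mean(.data$rfu), minutes = .data$minutes[1],
                     mg = .data$mg[1], .groups = "drop") |>
    dplyr::mutate(activity = (.data$rfu - f_blank) / (.data$minutes * .data$mg))
  wide <- tidyr::pivot_wider(
    dplyr::select(agg, "sample", "condition", "activity"),
    names_from = "condition", values_from = "activity",
    names_prefix = "act_")
  if (!"act_inhibited" %in% names(wide)) wide$act_inhibited <- 0
  wide$act_inhibited[is.na(wide$act_inhibited)] <- 0
  clamped <- wide$act_sample < 0 | (wide$act_sample - wide$act_inhibited) < 0
  tibble::tibble(
    sample = wide$sample,
    activity_rfu_min_mg = pmax(wide$act_sample, 0),
    inhibited_activity_rfu_min_mg = wide$act_inhibited,
    specific_activity_rfu_min_mg = pmax(wide$act_sample - wide$act_inhibited, 0),
    clamped = clamped
  )
}
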