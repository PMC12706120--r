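#' Construct a calibrated image stack
#'
#' Thin container for a time-lapse (or single-frame) intensity stack together
#' with its physical calibration. Frames are stored as a 3-D array indexed
#' `(frame, row, col)`; physical coordinates follow the pixel-centre
#' convention: the centre of pixel index `k` (0-based) lies at
#' `(k + 0.5) * pixel_size` um, so the x coordinate maps to columns and y to
#' rows.
#'
#' @param frames 3-D numeric array `(t, row, col)` or a single 2-D matrix.
#' @param pixel_size Pixel size in um/px (> 0).
#' @param dt Frame interval in seconds (> 0 for time-lapse).
#' @param metadata Free-form named list.
#' @return An `image_stack` object.
#' @export
image_stack <- function(frames, pixel_size, dt = NA_real_, metadata = list()) {
  if (is.matrix(frames)) frames <- array(frames, c(1, nrow(frames), ncol(frames)))
  stopifnot(is.array(frames), length(dim(frames)) == 3, dim(frames)[1] >= 1)
  assert_number(pixel_size, "pixel_size", lower = .Machine$double.eps)
  if (!is.na(dt)) assert_number(dt, "dt", lower = .Machine$double.eps)
  structure(
    list(frames = frames, pixel_size = pixel_size, dt = dt, metadata = metadata),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<image_stack> %d frame(s), %d x %d px, %.4g um/px, dt = %s s\n",
              d[1], d[2], d[3], x$pixel_size,
              if (is.na(x$dt)) "NA" else format(x$dt)))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$frames)

#' Write / read an image stack as multi-page TIFF with a JSON sidecar
#'
#' Intensities are scaled to the TIFF 16-bit range on write and restored on
#' read using the scale recorded in the sidecar (`<path>.json`), which also
#' stores `pixel_size_um`, `dt_s` and any metadata.
#'
#' @param stack An [image_stack()].
#' @param path Output TIFF path.
#' @return `write_image_stack` returns `path` invisibly; `read_image_stack`
#'   returns an [image_stack()].
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  mx <- max(stack$frames, 1e-12)
  pages <- lapply(seq_len(dim(stack$frames)[1]),
                  function(t) stack$frames[t, , ] / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  sidecar <- list(pixel_size_um = stack$pixel_size, dt_s = stack$dt,
                  scale = mx, metadata = stack$metadata)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  sc <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  frames <- array(0, c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (t in seq_along(pages)) frames[t, , ] <- pages[[t]] * sc$scale
  image_stack(frames, pixel_size = sc$pixel_size_um,
              dt = if (is.null(sc$dt_s) || is.na(sc$dt_s)) NA_real_ else sc$dt_s,
              metadata = as.list(sc$metadata))
}
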