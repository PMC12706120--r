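#' Multi-channel still image (nuclei + two probe channels)
#'
#' Container for a DQ-BSA style acquisition: a nuclear counterstain channel
#' used for segmentation, a total-uptake channel (fluid-phase BSA tracer) and
#' a degraded-probe channel (dye-quenched BSA that fluoresces only after
#' lysosomal proteolysis).
#'
#' @param nuclei,uptake,degraded 2-D numeric matrices of equal shape.
#' @param pixel_size Pixel size in um/px.
#' @return A `multi_channel_image` object.
#' @export
multi_channel_image <- function(nuclei, uptake, degraded, pixel_size) {
  stopifnot(is.matrix(nuclei), is.matrix(uptake), is.matrix(degraded),
            all(dim(nuclei) == dim(uptake)), all(dim(nuclei) == dim(degraded)),
            all(is.finite(nuclei)), all(is.finite(uptake)), all(is.finite(degraded)))
  assert_number(pixel_size, "pixel_size", lower = .Machine$double.eps)
  structure(list(nuclei = nuclei, uptake = uptake, degraded = degraded,
                 pixel_size = pixel_size),
            class = "multi_channel_image")
}

#' @export
print.multi_channel_image <- function(x, ...) {
  cat(sprintf("<multi_channel_image> %d x %d px, %.4g um/px (nuclei/uptake/degraded)\n",
              nrow(x$nuclei), ncol(x$nuclei), x$pixel_size))
  invisible(x)
}

#' Simulate a DQ-BSA endocytosis/proteolysis field with per-cell ground truth
#'
#' Places `n_cells` non-overlapping round cells (nucleus disk + cytoplasmic
#' annulus). The uptake channel mean over each cell's cytoplasm is
#' proportional to `endocytosis_scale` and the degraded channel mean to
#' `endocytosis_scale * proteolysis_scale`, so the per-cell degraded/uptake
#' ratio recovers `proteolysis_scale`. Per-cell lognormal variability and
#' Gaussian pixel noise are added on top; channel backgrounds equal
#' `field$background`.
#'
#' @param n_cells Number of cells (>= 1).
#' @param endocytosis_scale Mean uptake-channel signal above background (a.u.).
#' @param proteolysis_scale Ratio of degraded to uptake signal (a.u.).
#' @param field A [field_params()]; `shape` and `pixel_size` set the geometry.
#' @param seed Integer seed.
#' @param cell_cv Per-cell lognormal coefficient of variation of the uptake
#'   signal (the same per-cell factor multiplies both probe channels).
#' @param nucleus_radius_um,cell_radius_um Nucleus and cell radii in um.
#' @return A list with `image` (a [multi_channel_image()]) and `truth`
#'   (tibble: `cell_id`, `cx_px`, `cy_px`, `uptake_mean`, `degraded_mean`
#'   — true above-background cytoplasmic channel means).
#' @export
simulate_dqbsa_field <- function(n_cells, endocytosis_scale, proteolysis_scale,
                                 field = field_params(pixel_size = 0.25,
                                                      shape = c(640, 640),
                                                      background = 50,
                                                      read_noise_sd = 3),
                                 seed = NULL, cell_cv = 0.2,
                                 nucleus_radius_um = 3, cell_radius_um = 7) {
  n_cells <- assert_count(n_cells, "n_cells")
  assert_number(endocytosis_scale, "endocytosis_scale", lower = 0)
  assert_number(proteolysis_scale, "proteolysis_scale", lower = 0)
  ps <- field$pixel_size
  nr <- field$shape[1]; nc <- field$shape[2]
  r_cell <- cell_radius_um / ps
  r_nuc <- nucleus_radius_um / ps
  with_seed_or_stream(seed, {
    # dart-throwing placement of non-overlapping cells
    centres <- matrix(NA_real_, 0, 2)
    tries <- 0L
    while (nrow(centres) < n_cells) {
      tries <- tries + 1L
      if (tries > 200L * n_cells) {
        abort("field too small to place `n_cells` non-overlapping cells")
      }
      cand <- c(runif(1, r_cell + 1, nr - r_cell - 1),
                runif(1, r_cell + 1, nc - r_cell - 1))
      if (nrow(centres) == 0 ||
          all(sqrt(rowSums(sweep(centres, 2, cand)^2)) > 2 * r_cell + 2)) {
        centres <- rbind(centres, cand)
      }
    }
    rowg <- matrix(seq_len(nr), nr, nc)
    colg <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    nuclei <- matrix(0, nr, nc)
    uptake <- matrix(0, nr, nc)
    degraded <- matrix(0, nr, nc)
    sdlog <- sqrt(log(1 + cell_cv^2))
    cell_factor <- exp(rnorm(n_cells, -sdlog^2 / 2, sdlog))
    truth <- vector("list", n_cells)
    for (i in seq_len(n_cells)) {
      d2 <- (rowg - centres[i, 1])^2 + (colg - centres[i, 2])^2
      nuc <- d2 <= r_nuc^2
      cyto <- d2 <= r_cell^2 & !nuc
      up_mean <- endocytosis_scale * cell_factor[i]
      dq_mean <- up_mean * proteolysis_scale
      nuclei[nuc] <- 1000
      uptake[cyto] <- up_mean
      degraded[cyto] <- dq_mean
      truth[[i]] <- tibble::tibble(cell_id = i,
                                   cy_px = centres[i, 1], cx_px = centres[i, 2],
                                   uptake_mean = up_mean, degraded_mean = dq_mean)
    }
    bg <- field$background
    noise <- function(m) m + bg + matrix(rnorm(nr * nc, 0, field$read_noise_sd), nr, nc)
    img <- multi_channel_image(noise(nuclei), noise(uptake), noise(degraded), ps)
    list(image = img, truth = dplyr::bind_rows(truth))
  })
}
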