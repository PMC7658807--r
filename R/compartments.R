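#' Segment bright particles in an intensity image
#'
#' Thresholds the image (pixels strictly above the threshold are
#' foreground), labels connected components, and discards components
#' smaller than `min_area`. This is the binary-mask half of the standard
#' particle-analysis workflow for BFA compartments: intensity statistics
#' are measured afterwards on the original image via [particle_stats()].
#'
#' @param image numeric matrix.
#' @param threshold `"otsu"` (default) or a fixed numeric value; the value
#'   used is attached to the result as attribute `threshold_used`.
#' @param min_area minimum particle area in pixels (default 4, suppressing
#'   single-pixel noise).
#' @param connectivity 8 (default; corner-touching pixels join) or 4.
#' @return Integer label matrix with contiguous labels from 1 (0 =
#'   background) and attributes `threshold_used`, `min_area`,
#'   `connectivity`. An empty foreground gives an all-zero matrix.
#' @export
segment_particles <- function(image, threshold = "otsu", min_area = 4,
                              connectivity = 8) {
  check_matrix2d(image)
  th <- if (identical(threshold, "otsu")) otsu_threshold(image) else {
    if (!is_number(threshold)) abort("'threshold' must be \"otsu\" or a number")
    threshold
  }
  fg <- image > th
  lab <- label_components(fg, connectivity = connectivity)
  if (max(lab) > 0L && min_area > 1) {
    sizes <- tabulate(lab[lab > 0])
    lab[lab > 0][sizes[lab[lab > 0]] < min_area] <- 0L
    lab <- relabel_raster_order(lab)
  }
  structure(lab, threshold_used = th, min_area = min_area,
            connectivity = connectivity)
}

#' Per-particle area and mean intensity
#'
#' Measures each labeled particle on the original intensity image (never on
#' the binary mask): pixel area, mean intensity, and centroid.
#'
#' @param labels integer label matrix from [segment_particles()].
#' @param image the original intensity image, same dimensions.
#' @param pixel_size optional pixel edge length in micrometers; adds an
#'   `area_um2` column.
#' @return A `particle_table` data frame with columns `particle_id`,
#'   `area_px`, (`area_um2`,) `mean_intensity`, `centroid_row`,
#'   `centroid_col`; attributes `n_particles` and `threshold_used` (carried
#'   over from the label matrix when present).
#' @export
particle_stats <- function(labels, image, pixel_size = NULL) {
  check_matrix2d(image)
  if (!all(dim(labels) == dim(image))) {
    abort("label matrix dimensions (%s) differ from image (%s)",
          paste(dim(labels), collapse = "x"), paste(dim(image), collapse = "x"))
  }
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) == 0L) {
    tab <- data.frame(particle_id = integer(0), area_px = integer(0),
                      mean_intensity = numeric(0), centroid_row = numeric(0),
                      centroid_col = numeric(0))
  } else {
    idx <- which(labels > 0)
    lab <- labels[idx]
    rows <- (idx - 1L) %% nrow(labels) + 1L
    cols <- (idx - 1L) %/% nrow(labels) + 1L
    tab <- data.frame(
      particle_id = ids,
      area_px = as.integer(tabulate(lab)[ids]),
      mean_intensity = as.numeric(tapply(image[idx], lab, mean)[as.character(ids)]),
      centroid_row = as.numeric(tapply(rows, lab, mean)[as.character(ids)]),
      centroid_col = as.numeric(tapply(cols, lab, mean)[as.character(ids)])
    )
  }
  if (!is.null(pixel_size)) {
    tab$area_um2 <- tab$area_px * pixel_size^2
  }
  attr(tab, "n_particles") <- nrow(tab)
  attr(tab, "threshold_used") <- attr(labels, "threshold_used")
  class(tab) <- c("particle_table", "data.frame")
  tab
}

#' Quantify particles in one image
#'
#' Convenience wrapper chaining [segment_particles()] and
#' [particle_stats()], optionally restricted to a cell mask (pixels outside
#' the mask are treated as background before labeling).
#'
#' @inheritParams segment_particles
#' @param cell_mask optional logical matrix restricting the analysis.
#' @param pixel_size optional pixel edge length in micrometers.
#' @return A `particle_table` (see [particle_stats()]).
#' @export
quantify_particles <- function(image, threshold = "otsu", min_area = 4,
                               connectivity = 8, cell_mask = NULL,
                               pixel_size = NULL) {
  if (!is.null(cell_mask)) {
    mask <- resolve_mask(cell_mask, dim(image))
    masked <- image
    masked[!mask] <- min(image)
    labels <- segment_particles(masked, threshold = threshold,
                                min_area = min_area,
                                connectivity = connectivity)
  } else {
    labels <- segment_particles(image, threshold = threshold,
                                min_area = min_area,
                                connectivity = connectivity)
  }
  particle_stats(labels, image, pixel_size = pixel_size)
}
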