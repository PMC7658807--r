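#' Simulate a field of bright bodies with known ground truth
#'
#' Generates a single-channel image of non-overlapping filled disks on a
#' uniform background — a stand-in for BFA-compartment images — together
#' with a truth table giving the exact rasterized pixel area and mean
#' intensity of every body. A disk covers the pixels whose integer centers
#' satisfy `(x - cx)^2 + (y - cy)^2 <= r^2`; each disk carries one uniform
#' intensity drawn from `intensity_range`, so its true mean intensity on
#' the noiseless image is that value exactly.
#'
#' @param image_size integer `c(height, width)` in pixels.
#' @param n_bodies number of disks (0 gives a blank image and empty table).
#' @param radius_range numeric `c(min, max)` disk radius in pixels (>= 1).
#' @param intensity_range numeric `c(min, max)` per-disk intensity.
#' @param background uniform background intensity (should be well below
#'   `intensity_range` for segmentation to see the bodies).
#' @param noise_sigma additive Gaussian noise.
#' @param min_gap minimum edge-to-edge separation between disks in pixels
#'   (default 2, so bodies stay distinct under 8-connectivity labeling).
#' @param max_tries placement attempts per body before giving up; an
#'   infeasible packing raises an error.
#' @param seed integer seed (pure function of arguments).
#' @return A list with `image` (numeric matrix) and `truth` (data frame:
#'   `body_id`, `center_row`, `center_col`, `radius`, `area_px`,
#'   `mean_intensity`).
#' @export
make_bfa_image <- function(image_size = c(128, 128),
                           n_bodies = 12,
                           radius_range = c(3, 8),
                           intensity_range = c(100, 200),
                           background = 10,
                           noise_sigma = 0,
                           min_gap = 2,
                           max_tries = 200L,
                           seed = 1L) {
  if (length(image_size) != 2L || !all(vapply(image_size, is_count, logical(1)))) {
    abort("'image_size' must be two positive integers c(height, width)")
  }
  if (!is.numeric(n_bodies) || n_bodies < 0 || n_bodies != floor(n_bodies)) {
    abort("'n_bodies' must be a non-negative integer")
  }
  if (length(radius_range) != 2L || radius_range[1] < 1 ||
      radius_range[1] > radius_range[2]) {
    abort("'radius_range' must be c(min, max) with min >= 1")
  }
  h <- image_size[1]; w <- image_size[2]
  if (2 * radius_range[2] + 2 > min(h, w)) {
    abort("largest disk (radius %.1f) does not fit the %dx%d image",
          radius_range[2], h, w)
  }

  withr::local_preserve_seed()
  set.seed(as.integer(seed))

  img <- matrix(background, h, w)
  truth <- data.frame(body_id = integer(0), center_row = integer(0),
                      center_col = integer(0), radius = numeric(0),
                      area_px = integer(0), mean_intensity = numeric(0))
  centers <- matrix(numeric(0), 0, 2)
  radii <- numeric(0)

  for (i in seq_len(n_bodies)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      r <- runif(1, radius_range[1], radius_range[2])
      margin <- ceiling(r) + 1
      cy <- sample.int(h - 2 * margin, 1L) + margin
      cx <- sample.int(w - 2 * margin, 1L) + margin
      if (nrow(centers) > 0) {
        dist <- sqrt((centers[, 1] - cy)^2 + (centers[, 2] - cx)^2)
        if (any(dist < radii + r + min_gap)) next
      }
      placed <- TRUE
      break
    }
    if (!placed) {
      abort("could not place body %d of %d after %d tries: packing infeasible for this image size",
            i, n_bodies, max_tries)
    }
    centers <- rbind(centers, c(cy, cx))
    radii <- c(radii, r)
    val <- runif(1, intensity_range[1], intensity_range[2])
    disk <- disk_pixels(h, w, cy, cx, r)
    img[disk] <- val
    truth <- rbind(truth, data.frame(
      body_id = i, center_row = cy, center_col = cx, radius = r,
      area_px = sum(disk), mean_intensity = val))
  }

  if (noise_sigma > 0) {
    img <- img + matrix(rnorm(h * w, 0, noise_sigma), h, w)
  }
  list(image = img, truth = truth)
}

# logical mask of the rasterized disk: integer pixel centers within radius
disk_pixels <- function(h, w, cy, cx, r) {
  R <- matrix(seq_len(h), h, w)
  C <- matrix(seq_len(w), h, w, byrow = TRUE)
  (R - cy)^2 + (C - cx)^2 <= r^2
}
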