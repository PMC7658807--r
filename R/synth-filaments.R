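#' Simulate a remodeling filament-network time-lapse
#'
#' Generates a single-cell time-lapse of an actin-like filament network with
#' known ground truth, the stand-in for confocal acquisition of a cytoskeleton
#' reporter line (the study design this emulates images one cell every 2.5 s
#' over a 60 s course). Filaments are continuous-coordinate line segments
#' rasterized with anti-aliasing and optionally blurred to mimic optics.
#' Between frames each filament (bundle, when `bundling_factor > 1`; bundle
#' members share a path by construction) is independently replaced by a new
#' random filament with probability `remodeling_rate`; `remodeling_rate = 0`
#' reproduces a pharmacologically frozen (actin-stabilized) control.
#'
#' @param image_size integer vector `c(height, width)` in pixels.
#' @param n_filaments number of filaments (bundles count their members).
#' @param length_range numeric `c(min, max)` filament length in pixels; must
#'   not exceed the image diagonal.
#' @param width filament width in pixels (anti-aliased profile; optics blur
#'   sigma is `width / 2` when `blur = TRUE`).
#' @param remodeling_rate probability in `[0, 1]` that a filament is replaced
#'   by a new random one at each frame transition.
#' @param bundling_factor integer >= 1; number of co-localized filaments per
#'   bundle, so bundled pixels carry about `bundling_factor`-fold intensity.
#' @param noise_sigma standard deviation of additive Gaussian intensity noise.
#' @param n_frames number of frames (>= 2).
#' @param frame_interval seconds between frames (metadata).
#' @param blur apply Gaussian optics blur of sigma `width / 2` after
#'   rasterization.
#' @param seed integer seed; the generator is a pure function of its
#'   arguments including the seed (the caller's RNG state is untouched).
#' @return A list with `stack` (a [timelapse_stack]) and `truth` (a list with
#'   `remodeling_rate`, `bundling_factor`, `n_bundles`).
#' @examples
#' sim <- make_filament_timelapse(image_size = c(64, 64), n_filaments = 10,
#'                                remodeling_rate = 0.3, n_frames = 5, seed = 1)
#' framewise_dynamics(sim$stack)
#' @export
make_filament_timelapse <- function(image_size = c(128, 128),
                                    n_filaments = 30,
                                    length_range = c(30, 80),
                                    width = 2,
                                    remodeling_rate = 0.2,
                                    bundling_factor = 1L,
                                    noise_sigma = 0.02,
                                    n_frames = 25,
                                    frame_interval = 2.5,
                                    blur = TRUE,
                                    seed = 1L) {
  if (length(image_size) != 2L || !all(vapply(image_size, is_count, logical(1)))) {
    abort("'image_size' must be two positive integers c(height, width)")
  }
  if (!is_count(n_filaments)) abort("'n_filaments' must be a positive integer")
  if (!is_count(n_frames) || n_frames < 2) abort("'n_frames' must be >= 2")
  if (!is_number(remodeling_rate) || remodeling_rate < 0 || remodeling_rate > 1) {
    abort("'remodeling_rate' must lie in [0, 1]")
  }
  if (!is_count(bundling_factor)) abort("'bundling_factor' must be an integer >= 1")
  if (!is_number(width) || width <= 0) abort("'width' must be positive")
  if (!is_number(noise_sigma) || noise_sigma < 0) abort("'noise_sigma' must be >= 0")
  if (length(length_range) != 2L || any(length_range <= 0) ||
      length_range[1] > length_range[2]) {
    abort("'length_range' must be c(min, max) with 0 < min <= max")
  }
  h <- image_size[1]; w <- image_size[2]
  diagonal <- sqrt(h^2 + w^2)
  if (length_range[2] > diagonal) {
    abort("maximum filament length %.1f exceeds the image diagonal %.1f",
          length_range[2], diagonal)
  }

  withr::local_preserve_seed()
  set.seed(as.integer(seed))

  n_bundles <- as.integer(ceiling(n_filaments / bundling_factor))
  amplitude <- as.numeric(bundling_factor)  # co-localized members sum
  bundles <- replicate(n_bundles, sample_filament(h, w, length_range),
                       simplify = FALSE)

  frames <- vector("list", n_frames)
  base <- NULL  # rendered noiseless frame, reused while no filament turns over
  for (t in seq_len(n_frames)) {
    if (t > 1L) {
      replace <- runif(n_bundles) < remodeling_rate
      if (any(replace)) {
        bundles[replace] <- replicate(sum(replace),
                                      sample_filament(h, w, length_range),
                                      simplify = FALSE)
        base <- NULL
      }
    }
    if (is.null(base)) {
      base <- render_filaments(h, w, bundles, width, amplitude, blur)
    }
    noise <- matrix(rnorm(h * w, 0, noise_sigma), h, w)
    frames[[t]] <- base + noise
  }

  stack <- timelapse_stack(frames, frame_interval = frame_interval,
                           cell_id = sprintf("sim_seed%d", as.integer(seed)),
                           condition = sprintf("p=%g", remodeling_rate))
  list(stack = stack,
       truth = list(remodeling_rate = remodeling_rate,
                    bundling_factor = bundling_factor,
                    n_bundles = n_bundles))
}

# one random filament: uniform center, angle and length
sample_filament <- function(h, w, length_range) {
  len <- runif(1, length_range[1], length_range[2])
  cx <- runif(1, 1, w); cy <- runif(1, 1, h)
  th <- runif(1, 0, pi)
  list(x0 = cx - len / 2 * cos(th), y0 = cy - len / 2 * sin(th),
       x1 = cx + len / 2 * cos(th), y1 = cy + len / 2 * sin(th))
}

render_filaments <- function(h, w, bundles, width, amplitude, blur) {
  img <- matrix(0, h, w)
  for (b in bundles) {
    img <- add_segment(img, b$x0, b$y0, b$x1, b$y1, width / 2, amplitude)
  }
  if (blur) {
    img <- EBImage::imageData(EBImage::gblur(EBImage::Image(img),
                                             sigma = width / 2))
  }
  img
}

# additively rasterize one anti-aliased segment; pixel centers at integer
# (col = x, row = y) coordinates, coverage ramps linearly over the last pixel
add_segment <- function(img, x0, y0, x1, y1, half_width, amplitude) {
  h <- nrow(img); w <- ncol(img)
  pad <- half_width + 1.5
  rmin <- max(1L, floor(min(y0, y1) - pad)); rmax <- min(h, ceiling(max(y0, y1) + pad))
  cmin <- max(1L, floor(min(x0, x1) - pad)); cmax <- min(w, ceiling(max(x0, x1) + pad))
  if (rmin > rmax || cmin > cmax) return(img)
  rows <- rmin:rmax; cols <- cmin:cmax
  nr <- length(rows); nc <- length(cols)
  R <- matrix(rows, nr, nc)
  C <- matrix(cols, nr, nc, byrow = TRUE)
  vx <- x1 - x0; vy <- y1 - y0
  l2 <- vx^2 + vy^2
  tt <- if (l2 > 0) pmin(1, pmax(0, ((C - x0) * vx + (R - y0) * vy) / l2)) else 0
  d <- sqrt((C - (x0 + tt * vx))^2 + (R - (y0 + tt * vy))^2)
  cov <- pmin(1, pmax(0, half_width + 0.5 - d))
  img[rows, cols] <- img[rows, cols] + amplitude * cov
  img
}
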