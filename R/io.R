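#' Read a grayscale TIFF as a stack or image
#'
#' Reads a single-channel multi-page TIFF with no implicit rescaling:
#' integer TIFFs come back as their stored integer values, float TIFFs as
#' stored. Multi-channel (RGB) input is rejected with instructions to split
#' channels first.
#'
#' @param path TIFF file path.
#' @param kind `"timelapse"` (returns a [timelapse_stack], >= 2 pages
#'   required), `"zstack"` (list of slice matrices), or `"image"` (single
#'   matrix; a multi-page file errors).
#' @param frame_interval seconds between frames (timelapse metadata).
#' @param cell_mask optional logical matrix or path to a mask TIFF
#'   (non-zero = inside cell).
#' @param ... further labels passed to [timelapse_stack()]
#'   (`cell_id`, `genotype`, `condition`).
#' @return Depending on `kind`: a `timelapse_stack`, a list of matrices,
#'   or a matrix. The stored bit depth is attached as attribute
#'   `bits_per_sample` where the reader reports it.
#' @export
read_image_stack <- function(path, kind = c("timelapse", "zstack", "image"),
                             frame_interval = 2.5, cell_mask = NULL, ...) {
  kind <- match.arg(kind)
  if (!file.exists(path)) abort("file not found: %s", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  bad <- which(vapply(pages, function(p) length(dim(p)) != 2L, logical(1)))
  if (length(bad) > 0L) {
    abort("page %d of '%s' is multi-channel; split channels and re-save as grayscale",
          bad[1L], path)
  }
  bits <- attr(pages[[1L]], "bits.per.sample")
  pages <- lapply(pages, function(p) {
    m <- unclass(p)
    attributes(m) <- list(dim = dim(p))
    m
  })
  if (is.character(cell_mask)) {
    cell_mask <- read_image_stack(cell_mask, kind = "image") != 0
  }
  out <- switch(kind,
    timelapse = {
      if (length(pages) < 2L) {
        abort("'%s' has %d page(s); a time-lapse needs at least 2 frames",
              path, length(pages))
      }
      timelapse_stack(pages, frame_interval = frame_interval,
                      cell_mask = cell_mask, ...)
    },
    zstack = pages,
    image = {
      if (length(pages) != 1L) {
        abort("'%s' has %d pages; expected a single-page image", path,
              length(pages))
      }
      pages[[1L]]
    })
  attr(out, "bits_per_sample") <- bits
  out
}

#' Write frames as a multi-page grayscale TIFF
#'
#' Intensities must already lie in `[0, 1]`; they are stored at the
#' requested bit depth (16-bit quantizes to 65535 levels and round-trips
#' bit-exactly through [read_image_stack()]; 32-bit stores IEEE floats).
#'
#' @param frames a matrix, list of matrices, or [timelapse_stack].
#' @param path output path.
#' @param bits 16 (default) or 32 bits per sample.
#' @export
write_image_stack <- function(frames, path, bits = 16L) {
  if (inherits(frames, "timelapse_stack")) frames <- frames$frames
  if (is.matrix(frames)) frames <- list(frames)
  rng <- range(unlist(lapply(frames, range)))
  if (rng[1] < 0 || rng[2] > 1) {
    abort("intensities must lie in [0, 1] before writing (found range %.3g..%.3g); rescale explicitly",
          rng[1], rng[2])
  }
  if (!bits %in% c(16L, 32L)) abort("'bits' must be 16 or 32")
  tiff::writeTIFF(frames, path, bits.per.sample = bits)
  invisible(path)
}

#' Read FRAP traces from a CSV file
#'
#' Expects columns `time` and `intensity`, optionally
#' `reference_intensity` (unbleached-region trace for acquisition-bleaching
#' correction) and `trace_id` for multi-trace files.
#'
#' @param path CSV path.
#' @param n_prebleach pre-bleach scans per trace.
#' @return A list of [frap_trace] objects (named by `trace_id` when
#'   present), each carrying its reference vector as attribute
#'   `reference`.
#' @export
read_frap_csv <- function(path, n_prebleach = 3) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time", "intensity") %in% names(tab))) {
    abort("'%s' needs columns time, intensity", path)
  }
  split_by <- if ("trace_id" %in% names(tab)) tab$trace_id else
    rep("trace1", nrow(tab))
  lapply(split(tab, split_by), function(d) {
    d <- d[order(d$time), , drop = FALSE]
    tr <- frap_trace(d$time, d$intensity, n_prebleach = n_prebleach)
    if ("reference_intensity" %in% names(d)) {
      attr(tr, "reference") <- d$reference_intensity
    }
    tr
  })
}

#' Summarize dynamics results as a per-cell table
#'
#' @param results a `dynamics_result` or list of them.
#' @return Data frame with one row per cell: `cell_id`, `genotype`,
#'   `condition`, `n_frames`, `stack_correlation`, `stack_difference`,
#'   `difference_mode`.
#' @export
dynamics_table <- function(results) {
  if (inherits(results, "dynamics_result")) results <- list(results)
  do.call(rbind, lapply(results, function(r) data.frame(
    cell_id = r$cell_id, genotype = r$genotype, condition = r$condition,
    n_frames = r$n_frames, stack_correlation = r$stack_correlation,
    stack_difference = r$stack_difference, difference_mode = r$difference_mode)))
}

#' Summarize FRAP fits as a table
#'
#' @param fits a `frap_fit` or list of them (names become `trace_id`).
#' @return Data frame with one row per trace: mobile fraction, halftime,
#'   rate, floor, plateau, fit quality, convergence.
#' @export
frap_table <- function(fits) {
  if (inherits(fits, "frap_fit")) fits <- list(fits)
  ids <- names(fits)
  if (is.null(ids)) ids <- sprintf("trace%d", seq_along(fits))
  do.call(rbind, Map(function(f, id) data.frame(
    trace_id = id, mobile_fraction = f$mobile_fraction, t_half_min = f$t_half,
    rate_per_min = f$rate, f0 = f$f0, plateau = f$plateau,
    r_squared = f$r_squared, converged = f$converged,
    note = ifelse(is.na(f$warning), "", f$warning)), fits, ids))
}
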