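#' Construct a time-lapse stack of a single cell
#'
#' A time-lapse stack is the unit of analysis for actin-dynamics metrics:
#' an ordered set of equally shaped single-plane grayscale frames from one
#' cell, acquired at a fixed interval, with an optional binary cell mask
#' restricting all pixel statistics to the cell area.
#'
#' @param frames list of numeric matrices of identical dimensions, in
#'   acquisition order; at least two frames.
#' @param frame_interval acquisition interval in seconds (metadata).
#' @param cell_mask optional logical matrix of the same dimensions with at
#'   least two `TRUE` pixels; `NULL` means the whole frame is analyzed.
#' @param cell_id,genotype,condition free-text labels carried into results.
#' @return An object of class `timelapse_stack`.
#' @seealso [framewise_dynamics()], [make_filament_timelapse()]
#' @export
timelapse_stack <- function(frames, frame_interval = 2.5, cell_mask = NULL,
                            cell_id = "cell", genotype = NA_character_,
                            condition = NA_character_) {
  if (!is.list(frames) || length(frames) < 2L) {
    abort("a time-lapse stack needs at least 2 frames (got %d)",
          length(frames))
  }
  lapply(frames, check_matrix2d, name = "frames[[i]]")
  dims <- dim(frames[[1L]])
  ok <- vapply(frames, function(f) all(dim(f) == dims), logical(1))
  if (!all(ok)) {
    abort("all frames must share dimensions %s; frame %d differs",
          paste(dims, collapse = "x"), which(!ok)[1L])
  }
  if (!is_number(frame_interval) || frame_interval <= 0) {
    abort("'frame_interval' must be a positive number (seconds)")
  }
  if (!is.null(cell_mask)) {
    cell_mask <- resolve_mask(cell_mask, dims)
    if (sum(cell_mask) < 2L) abort("cell_mask must select at least 2 pixels")
  }
  structure(
    list(frames = frames, frame_interval = frame_interval,
         cell_mask = cell_mask, cell_id = cell_id, genotype = genotype,
         condition = condition),
    class = "timelapse_stack"
  )
}

#' @export
print.timelapse_stack <- function(x, ...) {
  d <- dim(x$frames[[1L]])
  cat(sprintf("<timelapse_stack> %s: %d frames of %dx%d, interval %.3g s%s\n",
              x$cell_id, length(x$frames), d[1], d[2], x$frame_interval,
              if (is.null(x$cell_mask)) "" else
                sprintf(", mask %d px", sum(x$cell_mask))))
  invisible(x)
}

#' @export
length.timelapse_stack <- function(x) length(x$frames)
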