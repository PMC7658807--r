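#' Two-dimensional correlation between two frames
#'
#' Pearson correlation over the (optionally masked) pixels of two equally
#' shaped intensity matrices — the frame-to-frame similarity statistic used
#' to quantify cytoskeletal remodeling. Symmetric in its arguments and
#' invariant under positive affine intensity transforms of either frame.
#'
#' @param a,b numeric matrices of identical dimensions.
#' @param mask optional logical matrix selecting the pixels to compare
#'   (e.g. a cell mask); `NULL` compares all pixels.
#' @return The correlation coefficient in `[-1, 1]`.
#' @details A selection with zero intensity variance in either frame has no
#'   defined correlation and raises an error rather than returning 0.
#' @export
corr2d <- function(a, b, mask = NULL) {
  check_matrix2d(a); check_matrix2d(b)
  if (!all(dim(a) == dim(b))) {
    abort("frame dimensions differ: %s vs %s",
          paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x"))
  }
  sel <- resolve_mask(mask, dim(a))
  va <- a[sel]; vb <- b[sel]
  if (length(va) < 2L) abort("at least 2 pixels must be selected")
  if (var(va) == 0 || var(vb) == 0) {
    abort("correlation undefined: selected pixels have zero intensity variance")
  }
  cor(va, vb)
}

#' Mean absolute per-pixel difference between two frames
#'
#' Mean over the (optionally masked) pixels of `|a - b|`, in intensity units
#' per pixel. Zero exactly when the two frames agree on the selection.
#'
#' @inheritParams corr2d
#' @param squared use the mean squared difference instead of the mean
#'   absolute difference.
#' @return Non-negative difference per pixel.
#' @export
mean_abs_diff <- function(a, b, mask = NULL, squared = FALSE) {
  check_matrix2d(a); check_matrix2d(b)
  if (!all(dim(a) == dim(b))) {
    abort("frame dimensions differ: %s vs %s",
          paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x"))
  }
  sel <- resolve_mask(mask, dim(a))
  d <- (a - b)[sel]
  if (length(d) < 1L) abort("at least 1 pixel must be selected")
  if (squared) mean(d^2) else mean(abs(d))
}

#' All-pairs frame correlation and difference of a time-lapse stack
#'
#' For every frame i the statistic is the mean of [corr2d()] (and of
#' [mean_abs_diff()]) between frame i and every other frame j != i; the
#' stack-level summaries are the unweighted means of the per-frame values.
#' A static network scores correlation 1 and difference 0; the faster the
#' remodeling, the lower the correlation and the larger the difference.
#'
#' @param stack a [timelapse_stack].
#' @param difference `"absolute"` (default) or `"squared"` per-pixel
#'   difference; the choice is recorded in the result.
#' @param normalize_frames divide each frame by its mean intensity before
#'   computing differences (correlation is unaffected by linear scaling);
#'   recorded in the result.
#' @param lag_profile also return mean correlation/difference as a function
#'   of frame separation (an interval-resolved view of the same pair matrix).
#' @return A `dynamics_result` list: `per_frame_correlation`,
#'   `per_frame_difference`, `stack_correlation`, `stack_difference`,
#'   `n_frames`, labels, the difference mode, and optionally `by_lag`.
#' @export
framewise_dynamics <- function(stack, difference = c("absolute", "squared"),
                               normalize_frames = FALSE, lag_profile = FALSE) {
  if (!inherits(stack, "timelapse_stack")) {
    abort("'stack' must be a timelapse_stack object")
  }
  difference <- match.arg(difference)
  n <- length(stack$frames)
  sel <- resolve_mask(stack$cell_mask, dim(stack$frames[[1L]]))
  pix <- vapply(stack$frames, function(f) f[sel], numeric(sum(sel)))

  sds <- apply(pix, 2L, sd)
  if (any(sds == 0)) {
    abort("frame %d has zero intensity variance under the mask; correlation undefined",
          which(sds == 0)[1L])
  }

  cmat <- cor(pix)
  per_corr <- (rowSums(cmat) - 1) / (n - 1)

  dpix <- if (normalize_frames) sweep(pix, 2L, colMeans(pix), "/") else pix
  dmat <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      d <- dpix[, i] - dpix[, j]
      dmat[i, j] <- dmat[j, i] <-
        if (difference == "absolute") mean(abs(d)) else mean(d^2)
    }
  }
  per_diff <- rowSums(dmat) / (n - 1)

  res <- list(
    per_frame_correlation = per_corr,
    per_frame_difference = per_diff,
    stack_correlation = mean(per_corr),
    stack_difference = mean(per_diff),
    n_frames = n,
    cell_id = stack$cell_id, genotype = stack$genotype,
    condition = stack$condition,
    difference_mode = difference,
    frames_normalized = normalize_frames
  )
  if (lag_profile) {
    lag <- abs(outer(seq_len(n), seq_len(n), "-"))
    off <- lag > 0
    res$by_lag <- data.frame(
      lag = seq_len(n - 1L),
      seconds = seq_len(n - 1L) * stack$frame_interval,
      correlation = as.numeric(tapply(cmat[off], lag[off], mean)),
      difference = as.numeric(tapply(dmat[off], lag[off], mean))
    )
  }
  class(res) <- "dynamics_result"
  res
}

#' @export
print.dynamics_result <- function(x, ...) {
  cat(sprintf(
    "<dynamics_result> %s: %d frames, stack correlation %.4f, stack %s difference %.4g\n",
    x$cell_id, x$n_frames, x$stack_correlation, x$difference_mode,
    x$stack_difference))
  invisible(x)
}

#' RGB overlay of three time points
#'
#' Min-max scales three selected frames to `[0, 1]` and assigns them to the
#' red, green and blue channels. In a static cell the three channels
#' coincide and the overlay is gray-to-white; moving structures appear as
#' colored fringes. A constant frame (zero intensity range) maps to an
#' all-zero channel.
#'
#' @param stack a [timelapse_stack].
#' @param indices three frame indices (R, G, B), not necessarily distinct.
#' @return A `height x width x 3` numeric array in `[0, 1]`.
#' @export
overlay_rgb <- function(stack, indices) {
  if (!inherits(stack, "timelapse_stack")) {
    abort("'stack' must be a timelapse_stack object")
  }
  if (length(indices) != 3L || any(indices != floor(indices))) {
    abort("'indices' must be three frame indices")
  }
  n <- length(stack$frames)
  if (any(indices < 1 | indices > n)) {
    abort("frame index out of range 1..%d", n)
  }
  scale01 <- function(m) {
    r <- range(m)
    if (r[1] == r[2]) return(matrix(0, nrow(m), ncol(m)))
    (m - r[1]) / (r[2] - r[1])
  }
  d <- dim(stack$frames[[1L]])
  out <- array(0, c(d[1], d[2], 3L))
  for (k in 1:3) out[, , k] <- scale01(stack$frames[[indices[k]]])
  out
}
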