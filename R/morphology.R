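# Shared binary-image primitives: thresholding, connected-component
# labeling and morphological thinning.

#' Otsu threshold of an intensity image
#'
#' Computes the Otsu threshold on a 256-bin histogram of the min-max scaled
#' image and returns it on the original intensity scale. Pixels strictly
#' above the threshold are foreground throughout the package.
#'
#' @param x numeric matrix.
#' @return A single threshold value on the scale of `x`. For a constant
#'   image the threshold equals that constant (empty foreground).
#' @export
otsu_threshold <- function(x) {
  check_matrix2d(x)
  r <- range(x)
  if (r[1] == r[2]) return(r[1])
  scaled <- (x - r[1]) / (r[2] - r[1])
  th <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1), levels = 256L)
  r[1] + th * (r[2] - r[1])
}

#' Label connected components with 8-connectivity
#'
#' Pixels touching edge- or corner-wise belong to the same component (the
#' convention of the common particle-analysis workflow); `connectivity = 4`
#' restricts to edge neighbors. Labels are contiguous integers from 1 in
#' raster order of first appearance.
#'
#' @param binary logical (or 0/1 numeric) matrix.
#' @param connectivity 8 (default) or 4.
#' @return Integer matrix of labels, 0 = background.
#' @export
label_components <- function(binary, connectivity = 8) {
  check_matrix2d(binary * 1)
  if (!connectivity %in% c(4, 8)) abort("'connectivity' must be 4 or 8")
  b <- matrix(as.numeric(binary != 0), nrow(binary), ncol(binary))
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(b)))
  storage.mode(lab) <- "integer"
  if (connectivity == 8 && max(lab) > 1L) {
    lab <- merge_diagonal_labels(lab)
  }
  relabel_raster_order(lab)
}

# union-find merge of 4-connected labels that touch diagonally
merge_diagonal_labels <- function(lab) {
  n <- max(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  h <- nrow(lab); w <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-h, -w]), as.vector(lab[-1, -1])),  # down-right
    cbind(as.vector(lab[-h, -1]), as.vector(lab[-1, -w]))   # down-left
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  for (k in seq_len(nrow(pairs))) {
    a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(n), find, integer(1))
  out <- lab
  out[lab > 0] <- root[lab[lab > 0]]
  out
}

# renumber labels 1..k in raster (column-major) order of first appearance
relabel_raster_order <- function(lab) {
  ids <- unique(lab[lab > 0])
  if (length(ids) == 0L) return(lab)
  map <- integer(max(ids))
  map[ids] <- seq_along(ids)
  lab[lab > 0] <- map[lab[lab > 0]]
  lab
}

#' Remove connected components smaller than a pixel count
#'
#' @param binary logical matrix.
#' @param min_px minimum component size in pixels to keep.
#' @return Logical matrix with small components cleared.
#' @export
remove_small_objects <- function(binary, min_px) {
  if (min_px <= 1) return(binary != 0)
  lab <- label_components(binary, connectivity = 8)
  if (max(lab) == 0L) return(binary != 0)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_px)
  matrix(lab %in% keep, nrow(binary), ncol(binary))
}

#' Thin a binary image to a one-pixel-wide skeleton
#'
#' Zhang-Suen iterative thinning: border pixels are peeled in two
#' alternating sub-iterations, preserving connectivity and line ends, until
#' the image stops changing. The result is idempotent under re-thinning.
#'
#' @param binary logical (or 0/1 numeric) matrix.
#' @return Logical matrix, the unit-width skeleton (a subset of the input
#'   foreground).
#' @export
thin_binary <- function(binary) {
  b <- matrix(binary != 0, nrow(binary), ncol(binary))
  if (!any(b)) return(b)
  sh <- function(m, dr, dc) {
    h <- nrow(m); w <- ncol(m)
    out <- matrix(FALSE, h, w)
    rs <- max(1, 1 + dr):min(h, h + dr)
    cs <- max(1, 1 + dc):min(w, w + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      # neighbors clockwise from north: P2..P9
      p2 <- sh(b, 1, 0);  p3 <- sh(b, 1, -1); p4 <- sh(b, 0, -1)
      p5 <- sh(b, -1, -1); p6 <- sh(b, -1, 0); p7 <- sh(b, -1, 1)
      p8 <- sh(b, 0, 1);  p9 <- sh(b, 1, 1)
      bsum <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
           (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      if (step == 1L) {
        cond <- !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      del <- b & bsum >= 2 & bsum <= 6 & a == 1 & cond
      if (any(del)) {
        b[del] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  b
}
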