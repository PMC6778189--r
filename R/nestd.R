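## symmetric (mirror, border-duplicating) 1-pixel padding
pad_symmetric <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  m[c(1L, seq_len(nr), nr), c(1L, seq_len(nc), nc)]
}

## stack the 9 values of each pixel's 3x3 neighborhood as an (nr*nc) x 9 matrix
neigh_stack3 <- function(m) {
  p <- pad_symmetric(m)
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr * nc, 9L)
  k <- 1L
  for (dc in 0:2) for (dr in 0:2) {
    out[, k] <- as.vector(p[dr + seq_len(nr), dc + seq_len(nc)])
    k <- k + 1L
  }
  out
}

#' Local entropy map (3x3 neighborhood)
#'
#' For each pixel, the Shannon entropy in bits of the gray-level histogram
#' of its 3x3 neighborhood; equal values share a histogram bin, so the map
#' is invariant to any relabeling that preserves level distinctness.
#' Borders use symmetric padding (border pixels mirrored outward).
#'
#' @param slice Numeric matrix of (typically discretized) gray levels,
#'   at least 3x3.
#' @return Matrix of the same dimension, entropy in bits (0 to log2(9)).
#' @export
local_entropy <- function(slice) {
  if (!is.matrix(slice) || nrow(slice) < 3L || ncol(slice) < 3L)
    stop("'slice' must be a matrix of at least 3 x 3")
  A <- neigh_stack3(slice)
  H <- numeric(nrow(A))
  for (jj in 1:9) {
    cnt <- rowSums(A == A[, jj])  # multiplicity of column jj's value
    H <- H - log2(cnt / 9) / 9
  }
  matrix(H, nrow(slice), ncol(slice))
}

#' Local standard-deviation map (3x3 neighborhood)
#'
#' Per-pixel standard deviation of the 3x3 neighborhood with symmetric
#' padding. The sample (n-1) convention is the default.
#'
#' @param slice Numeric matrix, at least 3x3.
#' @param type `"sample"` (divide by 8) or `"population"` (divide by 9).
#' @return Matrix of the same dimension, nonnegative.
#' @export
local_std <- function(slice, type = c("sample", "population")) {
  if (!is.matrix(slice) || nrow(slice) < 3L || ncol(slice) < 3L)
    stop("'slice' must be a matrix of at least 3 x 3")
  type <- match.arg(type)
  A <- neigh_stack3(slice)
  mu <- rowMeans(A)
  ss <- rowSums(A * A) - 9 * mu^2
  v <- pmax(ss, 0) / if (type == "sample") 8 else 9
  matrix(sqrt(v), nrow(slice), ncol(slice))
}

## min-max normalize to [0,1]; constant maps become all-zero
minmax01 <- function(m) {
  rg <- range(m)
  if (rg[2] == rg[1]) return(array(0, dim(m)))
  (m - rg[1]) / (rg[2] - rg[1])
}

#' NESTD maps for one slice
#'
#' The normalized entropy-to-standard-deviation difference (NESTD) map: the
#' slice is cropped to a rectangular box enclosing the organ plus margin,
#' quantized to `n_levels` gray levels over the box intensity range, and the
#' 3x3 local-entropy and local-standard-deviation maps are each min-max
#' normalized to `[0, 1]` over the box and subtracted (entropy minus
#' standard deviation), giving values in `[-1, 1]`. Flat-on-noisy organ
#' boundaries produce extreme values, which is what makes the map useful
#' for checking contours. A constant crop yields an all-zero map.
#'
#' @param slice Numeric matrix of intensities.
#' @param box Integer vector `c(row_min, row_max, col_min, col_max)`;
#'   default is the whole slice.
#' @param n_levels Gray levels used for the entropy filter input
#'   (256, mirroring 8-bit filter implementations).
#' @param std_type Convention passed to [local_std()].
#' @return Object of class `nestd_maps`: list with `entropy`, `std`,
#'   `nestd` (matrices over the box), and `box`.
#' @export
nestd_maps <- function(slice, box = NULL, n_levels = 256L,
                       std_type = "sample") {
  if (!is.matrix(slice)) stop("'slice' must be a matrix")
  if (is.null(box)) box <- c(1L, nrow(slice), 1L, ncol(slice))
  box <- as.integer(box)
  if (length(box) != 4L || box[1] < 1L || box[3] < 1L ||
      box[2] > nrow(slice) || box[4] > ncol(slice) ||
      box[2] - box[1] < 2L || box[4] - box[3] < 2L)
    stop("'box' must be c(row_min, row_max, col_min, col_max) inside the slice, at least 3 x 3")
  crop <- slice[box[1]:box[2], box[3]:box[4], drop = FALSE]
  rg <- range(crop)
  lev <- if (rg[2] > rg[1]) {
    pmin(floor((crop - rg[1]) / (rg[2] - rg[1]) * n_levels) + 1, n_levels)
  } else {
    array(1, dim(crop))
  }
  ent <- minmax01(local_entropy(matrix(lev, nrow(crop))))
  sdm <- minmax01(local_std(crop, type = std_type))
  structure(list(entropy = ent, std = sdm, nestd = ent - sdm, box = box),
            class = "nestd_maps")
}

## default per-slice box: mask bounding box plus margin, clamped to slice
auto_box <- function(mask_slice, margin = 2L) {
  idx <- which(mask_slice, arr.ind = TRUE)
  r <- range(idx[, 1]); c <- range(idx[, 2])
  box <- c(max(1L, r[1] - margin), min(nrow(mask_slice), r[2] + margin),
           max(1L, c[1] - margin), min(ncol(mask_slice), c[2] + margin))
  # widen degenerate boxes so the 3x3 filters are defined
  while (box[2] - box[1] < 2L) {
    box[1] <- max(1L, box[1] - 1L)
    box[2] <- min(nrow(mask_slice), box[2] + 1L)
    if (box[1] == 1L && box[2] == nrow(mask_slice)) break
  }
  while (box[4] - box[3] < 2L) {
    box[3] <- max(1L, box[3] - 1L)
    box[4] <- min(ncol(mask_slice), box[4] + 1L)
    if (box[3] == 1L && box[4] == ncol(mask_slice)) break
  }
  as.integer(box)
}

#' Scalar NESTD feature of a 3D ROI
#'
#' Mean of the per-slice NESTD map values over the masked voxels of every
#' mask-bearing axial slice. Because the entropy input is quantized over
#' each box's own range and both maps are min-max normalized, the feature
#' is invariant to adding a constant to all intensities.
#'
#' @param roi An [image_roi()].
#' @param boxes Optional list of per-slice boxes (indexed by slice number);
#'   by default the mask bounding box plus `margin` is used per slice.
#' @param margin Margin (pixels) around the mask for the automatic box.
#' @param ... Passed to [nestd_maps()].
#' @return A single number in `[-1, 1]`.
#' @export
nestd_feature <- function(roi, boxes = NULL, margin = 2L, ...) {
  stopifnot(inherits(roi, "image_roi"))
  dims <- dim(roi$mask)
  vals <- numeric(0)
  for (k in seq_len(dims[3])) {
    msk <- matrix(roi$mask[, , k], dims[1], dims[2])
    if (!any(msk)) next
    box <- if (!is.null(boxes) && length(boxes) >= k && !is.null(boxes[[k]]))
      as.integer(boxes[[k]]) else auto_box(msk, margin)
    sl <- matrix(roi$intensities[, , k], dims[1], dims[2])
    maps <- nestd_maps(sl, box, ...)
    sub <- msk[box[1]:box[2], box[3]:box[4], drop = FALSE]
    vals <- c(vals, maps$nestd[sub])
  }
  if (!length(vals)) stop("mask is empty")
  mean(vals)
}

#' Write NESTD contour-QA overlays
#'
#' For every mask-bearing slice, writes a PNG of the CT slice with the
#' NESTD map blended over the box region and the mask contour drawn: a
#' quick visual check that the contour follows the boundary the map
#' detects. Purely a QA artifact; nothing downstream consumes it.
#'
#' @param roi An [image_roi()].
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @param margin Box margin as in [nestd_feature()].
#' @return Invisibly, the vector of files written.
#' @export
contour_overlay <- function(roi, dir, prefix = "nestd", margin = 2L) {
  stopifnot(inherits(roi, "image_roi"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dims <- dim(roi$mask)
  files <- character(0)
  for (k in seq_len(dims[3])) {
    msk <- matrix(roi$mask[, , k], dims[1], dims[2])
    if (!any(msk)) next
    box <- auto_box(msk, margin)
    sl <- matrix(roi$intensities[, , k], dims[1], dims[2])
    maps <- nestd_maps(sl, box)
    fn <- file.path(dir, sprintf("%s_slice%03d.png", prefix, k))
    grDevices::png(fn, width = 480, height = 480)
    graphics::par(mar = c(1, 1, 2, 1))
    graphics::image(seq_len(nrow(sl)), seq_len(ncol(sl)), sl,
                    col = grDevices::gray(seq(0, 1, length.out = 128)),
                    axes = FALSE, xlab = "", ylab = "",
                    main = sprintf("NESTD overlay, slice %d", k))
    nc <- grDevices::adjustcolor(
      grDevices::hcl.colors(64, "RdBu", rev = TRUE), alpha.f = 0.45)
    graphics::image(box[1]:box[2], box[3]:box[4], maps$nestd,
                    col = nc, zlim = c(-1, 1), add = TRUE)
    graphics::contour(seq_len(nrow(sl)), seq_len(ncol(sl)),
                      msk + 0, levels = 0.5, drawlabels = FALSE,
                      add = TRUE, col = "yellow", lwd = 2)
    grDevices::dev.off()
    files <- c(files, fn)
  }
  invisible(files)
}
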