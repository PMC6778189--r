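#' Construct an image ROI
#'
#' Bundles a 3D intensity volume, a binary mask of the region of interest and
#' the voxel spacing. All texture extraction in the package operates on this
#' container; intensities outside the mask are carried along (they are needed
#' for boundary maps) but never enter masked statistics.
#'
#' @param intensities Numeric 3D array of intensities (arbitrary units;
#'   CT-like values are typical).
#' @param mask Logical (or 0/1) array of the same dimension marking ROI
#'   voxels.
#' @param spacing Numeric length-3 voxel spacing in mm.
#' @return An object of class `image_roi`: a list with elements
#'   `intensities`, `mask` (logical array) and `spacing`.
#' @examples
#' vol <- array(rnorm(4^3), c(4, 4, 4))
#' roi <- image_roi(vol, array(TRUE, dim(vol)))
#' @export
image_roi <- function(intensities, mask, spacing = c(1, 1, 1)) {
  if (!is.array(intensities) || length(dim(intensities)) != 3L)
    stop("'intensities' must be a 3D array")
  if (is.null(dim(mask)) || !identical(dim(mask), dim(intensities)))
    stop("'mask' must be an array with the same dimensions as 'intensities'")
  mask <- array(as.logical(mask), dim(intensities))
  if (anyNA(mask)) stop("'mask' must not contain NA")
  if (!any(mask)) stop("'mask' must contain at least one voxel")
  if (!all(is.finite(intensities[mask])))
    stop("masked intensities must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be three positive numbers (mm)")
  structure(list(intensities = intensities, mask = mask, spacing = spacing),
            class = "image_roi")
}

#' @export
print.image_roi <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<image_roi> %d x %d x %d voxels, %d in mask, spacing %s mm\n",
              d[1], d[2], d[3], sum(x$mask),
              paste(signif(x$spacing, 3), collapse = " x ")))
  invisible(x)
}

#' Quantize ROI intensities to discrete gray levels
#'
#' Equal-width binning of masked intensities over a fixed window, the
#' discretization used by all matrix-based texture features. A fixed window
#' (rather than a per-image range) keeps gray levels comparable across
#' fractions of a longitudinal series.
#'
#' @param roi An [image_roi()].
#' @param G Number of gray levels (>= 2).
#' @param window Length-2 numeric intensity window; values are clipped to
#'   it. Default is the range of the masked intensities.
#' @return Object of class `quantized_roi`: list with `levels` (array of
#'   integer levels in `1..G`, `NA` outside the mask), `G`, `bin_edges`,
#'   `mask`, `spacing`.
#' @export
quantize_roi <- function(roi, G = 32L, window = NULL) {
  stopifnot(inherits(roi, "image_roi"))
  if (!is_count(G, 2L)) stop("'G' must be an integer >= 2")
  x <- roi$intensities[roi$mask]
  if (is.null(window)) window <- range(x)
  window <- as.numeric(window)
  if (length(window) != 2L || !all(is.finite(window)) || diff(window) <= 0)
    stop("degenerate intensity window: supply a window with positive width")
  bw <- diff(window) / G
  lev <- floor((pmin(pmax(x, window[1]), window[2]) - window[1]) / bw) + 1
  lev <- as.integer(pmin(pmax(lev, 1L), G))
  levels <- array(NA_integer_, dim(roi$intensities))
  levels[roi$mask] <- lev
  structure(list(levels = levels, G = as.integer(G),
                 bin_edges = seq(window[1], window[2], length.out = G + 1),
                 mask = roi$mask, spacing = roi$spacing),
            class = "quantized_roi")
}

#' @export
print.quantized_roi <- function(x, ...) {
  cat(sprintf("<quantized_roi> G = %d, window [%g, %g], %d masked voxels\n",
              x$G, x$bin_edges[1], x$bin_edges[length(x$bin_edges)],
              sum(x$mask)))
  invisible(x)
}
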