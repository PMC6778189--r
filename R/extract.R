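#' Extract the configured radiomic feature vector from one ROI
#'
#' Runs the intensity-histogram, GLCM, GLRLM, NGTDM, shape and NESTD
#' extractors on a masked 3D volume with a shared discretization (fixed
#' window, `G` equal-width levels), returning one named numeric vector.
#' The fixed window keeps gray levels, and hence features, comparable
#' across the fractions of a longitudinal series.
#'
#' @param roi An [image_roi()].
#' @param G Number of gray levels for the matrix features.
#' @param window Fixed intensity window; defaults to the masked range.
#' @param d GLCM pixel distance.
#' @param families Feature families to compute; any subset of
#'   `c("firstorder","glcm","glrlm","ngtdm","shape","nestd")`.
#' @return Named numeric vector; all values finite.
#' @examples
#' roi <- image_roi(array(rnorm(6 * 6 * 3, 100, 20), c(6, 6, 3)),
#'                  array(TRUE, c(6, 6, 3)))
#' head(extract_features(roi, G = 8))
#' @export
extract_features <- function(roi, G = 32L, window = c(-200, 400), d = 1L,
                             families = c("firstorder", "glcm", "glrlm",
                                          "ngtdm", "shape", "nestd")) {
  stopifnot(inherits(roi, "image_roi"))
  families <- match.arg(families, several.ok = TRUE)
  out <- numeric(0)
  q <- NULL
  if (any(families %in% c("glcm", "glrlm", "ngtdm")))
    q <- quantize_roi(roi, G = G, window = window)
  if ("firstorder" %in% families)
    out <- c(out, histogram_features(roi, G = G, window = window))
  if ("glcm" %in% families)
    out <- c(out, glcm_features(glcm_3d(q, d = d)))
  if ("glrlm" %in% families)
    out <- c(out, glrlm_features(glrlm_3d(q), n_voxels = sum(roi$mask)))
  if ("ngtdm" %in% families)
    out <- c(out, ngtdm_features(q))
  if ("shape" %in% families)
    out <- c(out, shape_features(roi))
  if ("nestd" %in% families)
    out <- c(out, nestd = nestd_feature(roi))
  if (any(!is.finite(out)))
    stop("non-finite feature value(s): ",
         paste(names(out)[!is.finite(out)], collapse = ", "))
  out
}

#' Extract a longitudinal feature table from a synthetic cohort
#'
#' Applies [extract_features()] to every (patient, fraction) image of a
#' [generate_cohort()] result, producing the wide feature table consumed
#' by [compute_drf()].
#'
#' @param cohort A `synthetic_cohort`.
#' @param ... Passed to [extract_features()].
#' @return Data frame with columns `patient`, `fraction`, then one column
#'   per feature.
#' @export
extract_feature_table <- function(cohort, ...) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  rows <- lapply(names(cohort$images), function(key) {
    img <- cohort$images[[key]]
    fv <- extract_features(img$roi, ...)
    cbind(data.frame(patient = img$patient, fraction = img$fraction,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(fv)))
  })
  tab <- do.call(rbind, rows)
  tab[order(tab$patient, tab$fraction), , drop = FALSE]
}
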