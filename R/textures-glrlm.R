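#' Gray-level run-length matrix of a 3D ROI
#'
#' Run-length matrices are computed per axial slice along the 0 degree
#' (row) and 90 degree (column) directions, restricted to in-mask voxels
#' (a masked-out voxel breaks a run), summed over slices and directions,
#' and averaged over the number of directions.
#'
#' @param q A [quantize_roi()] result.
#' @param directions Character subset of `c("0","90")`.
#' @return `G x Lmax` matrix of (possibly fractional, after averaging) run
#'   counts; rows index gray level, columns run length.
#' @export
glrlm_3d <- function(q, directions = c("0", "90")) {
  stopifnot(inherits(q, "quantized_roi"))
  directions <- match.arg(directions, several.ok = TRUE)
  dims <- dim(q$levels)
  G <- q$G
  lmax <- max(dims[1], dims[2])
  R <- matrix(0, G, lmax)
  any_run <- FALSE
  for (k in seq_len(dims[3])) {
    L <- q$levels[, , k, drop = TRUE]
    if (is.null(dim(L))) L <- matrix(L, dims[1], dims[2])
    for (dir in directions) {
      lines <- if (dir == "0") seq_len(nrow(L)) else seq_len(ncol(L))
      for (li in lines) {
        v <- if (dir == "0") L[li, ] else L[, li]
        v[is.na(v)] <- 0L
        r <- rle(as.vector(v))
        keep <- r$values > 0L
        if (any(keep)) {
          any_run <- TRUE
          for (ri in which(keep))
            R[r$values[ri], r$lengths[ri]] <- R[r$values[ri], r$lengths[ri]] + 1
        }
      }
    }
  }
  if (!any_run) stop("mask is empty: no runs to count")
  R / length(directions)
}

#' GLRLM texture features
#'
#' Short-run emphasis, run percentage, gray-level nonuniformity and
#' high-gray-level run emphasis of a run-length matrix. `n_voxels` is the
#' number of masked voxels used by the run-percentage denominator.
#'
#' @param R Run-length matrix from [glrlm_3d()].
#' @param n_voxels Number of voxels in the mask.
#' @return Named numeric vector (prefix `glrlm_`).
#' @export
glrlm_features <- function(R, n_voxels) {
  if (!is.matrix(R) || any(R < 0)) stop("'R' must be a nonnegative matrix")
  nr <- sum(R)
  if (nr == 0) stop("run-length matrix is empty")
  if (!is_count(n_voxels, 1L)) stop("'n_voxels' must be a positive count")
  jl <- col(R)
  g  <- row(R)
  c(glrlm_sre            = sum(R / jl^2) / nr,
    glrlm_run_percentage = nr / n_voxels,
    glrlm_gln            = sum(rowSums(R)^2) / nr,
    glrlm_hglre          = sum(g^2 * R) / nr)
}
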