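## shift an array by (dx,dy,dz); out[x,y,z] = a[x+dx,y+dy,z+dz], zero-padded
shift_array3 <- function(a, dx, dy, dz) {
  d <- dim(a)
  out <- array(0, d)
  x0 <- max(1L, 1L - dx); x1 <- min(d[1], d[1] - dx)
  y0 <- max(1L, 1L - dy); y1 <- min(d[2], d[2] - dy)
  z0 <- max(1L, 1L - dz); z1 <- min(d[3], d[3] - dz)
  if (x0 > x1 || y0 > y1 || z0 > z1) return(out)
  out[x0:x1, y0:y1, z0:z1] <- a[(x0:x1) + dx, (y0:y1) + dy, (z0:z1) + dz]
  out
}

#' Neighborhood gray-tone difference matrix features
#'
#' Amadasun-King texture statistics with a 26-connected 3D neighborhood.
#' Only in-mask voxels with at least one in-mask neighbor contribute; the
#' neighborhood average is taken over the in-mask neighbors. On perfectly
#' homogeneous ROIs the coarseness denominator vanishes; it is then guarded
#' by `eps`, so a constant ROI returns coarseness `1/eps`, with contrast,
#' busyness, complexity and strength all 0.
#'
#' @param q A [quantize_roi()] result.
#' @param eps Guard constant for the coarseness denominator.
#' @return Named numeric vector (prefix `ngtdm_`).
#' @export
ngtdm_features <- function(q, eps = 1e-6) {
  stopifnot(inherits(q, "quantized_roi"))
  L <- q$levels
  G <- q$G
  Lz <- L; Lz[is.na(Lz)] <- 0L
  Mk <- array(0, dim(L)); Mk[!is.na(L)] <- 1
  S <- array(0, dim(L)); C <- array(0, dim(L))
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0L && dy == 0L && dz == 0L) next
    S <- S + shift_array3(Lz, dx, dy, dz)
    C <- C + shift_array3(Mk, dx, dy, dz)
  }
  ok <- !is.na(L) & C >= 1
  if (!any(ok)) stop("no masked voxel has an in-mask neighbor")
  lev  <- L[ok]
  abar <- S[ok] / C[ok]
  adiff <- abs(lev - abar)
  n_i <- vapply(seq_len(G), function(g) sum(lev == g), 0)
  s_i <- vapply(seq_len(G), function(g) sum(adiff[lev == g]), 0)
  N <- sum(n_i)
  p_i <- n_i / N
  pres <- which(p_i > 0)
  psum <- sum(p_i * s_i)

  coarseness <- 1 / max(psum, eps)
  contrast <- 0; busyness <- 0; complexity <- 0; strength <- 0
  if (length(pres) > 1) {
    ii <- rep(pres, each = length(pres)); jj <- rep(pres, length(pres))
    pi_ <- p_i[ii]; pj_ <- p_i[jj]
    contrast <- (sum(pi_ * pj_ * (ii - jj)^2) /
                   (length(pres) * (length(pres) - 1))) * sum(s_i) / N
    bden <- sum(abs(ii * pi_ - jj * pj_))
    if (bden > 0) busyness <- psum / bden
    complexity <- sum(abs(ii - jj) * (pi_ * s_i[ii] + pj_ * s_i[jj]) /
                        (pi_ + pj_)) / N
    sden <- sum(s_i)
    if (sden > 0) strength <- sum((pi_ + pj_) * (ii - jj)^2) / sden
  }
  c(ngtdm_coarseness = coarseness, ngtdm_contrast = contrast,
    ngtdm_busyness = busyness, ngtdm_complexity = complexity,
    ngtdm_strength = strength)
}
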