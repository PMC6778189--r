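#' Gray-level co-occurrence matrix of a 3D ROI
#'
#' Accumulates symmetric co-occurrence counts at distance `d` for the four
#' in-plane directions (0, 45, 90, 135 degrees) over all axial slices; only
#' voxel pairs with both members inside the mask contribute. The four
#' direction matrices are summed, averaged, and normalized to sum 1, giving
#' a single direction-averaged 3D GLCM.
#'
#' @param q A [quantize_roi()] result.
#' @param d Integer pixel offset (default 1).
#' @param directions Character subset of `c("0","45","90","135")`, mainly
#'   for testing single directions.
#' @return `G x G` numeric matrix summing to 1.
#' @export
glcm_3d <- function(q, d = 1L, directions = c("0", "45", "90", "135")) {
  stopifnot(inherits(q, "quantized_roi"))
  if (!is_count(d, 1L)) stop("'d' must be a positive integer")
  directions <- match.arg(directions, several.ok = TRUE)
  offs <- list("0" = c(0L, 1L), "45" = c(-1L, 1L),
               "90" = c(-1L, 0L), "135" = c(-1L, -1L))
  G <- q$G
  dims <- dim(q$levels)
  total <- matrix(0, G, G)
  for (dir in directions) {
    o <- offs[[dir]] * d
    M <- matrix(0, G, G)
    for (k in seq_len(dims[3])) {
      L <- q$levels[, , k, drop = TRUE]
      if (is.null(dim(L))) L <- matrix(L, dims[1], dims[2])
      cnt <- glcm_slice_counts(L, o[1], o[2], G)
      if (!is.null(cnt)) M <- M + cnt
    }
    total <- total + (M + t(M))  # symmetric: count both orders
  }
  total <- total / length(directions)
  s <- sum(total)
  if (s == 0) stop("mask contains no valid in-plane voxel pairs at this offset")
  total / s
}

## ordered co-occurrence counts for one slice and one (dr, dc) offset
glcm_slice_counts <- function(L, dr, dc, G) {
  nr <- nrow(L); nc <- ncol(L)
  r0 <- max(1L, 1L - dr); r1 <- min(nr, nr - dr)
  c0 <- max(1L, 1L - dc); c1 <- min(nc, nc - dc)
  if (r0 > r1 || c0 > c1) return(NULL)
  A <- L[r0:r1, c0:c1, drop = FALSE]
  B <- L[(r0 + dr):(r1 + dr), (c0 + dc):(c1 + dc), drop = FALSE]
  ok <- !is.na(A) & !is.na(B)
  if (!any(ok)) return(NULL)
  idx <- (B[ok] - 1L) * G + A[ok]          # column-major (A, B) cell
  matrix(tabulate(idx, nbins = G * G), G, G)
}

#' GLCM texture features
#'
#' Standard Haralick-style statistics of a normalized co-occurrence matrix.
#' Entropies use log base 2. The information measure of correlation is IMC1
#' (the variant `(HXY - HXY1) / max(HX, HY)`); degenerate matrices with zero
#' marginal entropy return 0 for it.
#'
#' @param P Normalized `G x G` co-occurrence matrix (sums to 1).
#' @return Named numeric vector of 15 features (prefix `glcm_`).
#' @export
glcm_features <- function(P) {
  if (!is.matrix(P) || nrow(P) != ncol(P))
    stop("'P' must be a square matrix")
  if (abs(sum(P) - 1) > 1e-6)
    stop("'P' must be normalized to sum 1")
  G <- nrow(P)
  i <- row(P); j <- col(P)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(seq_len(G) * px); muy <- sum(seq_len(G) * py)

  pdiff <- vapply(0:(G - 1), function(k) sum(P[abs(i - j) == k]), 0)
  psum  <- vapply(2:(2 * G), function(k) sum(P[(i + j) == k]), 0)

  hxy  <- -sum(plog2(P))
  hx   <- -sum(plog2(px)); hy <- -sum(plog2(py))
  ppos <- P > 0
  hxy1 <- -sum(P[ppos] * log2(pmax(px[i[ppos]] * py[j[ppos]], .Machine$double.xmin)))
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0

  offd <- i != j
  c(glcm_autocorrelation    = sum(i * j * P),
    glcm_cluster_shade      = sum((i + j - mux - muy)^3 * P),
    glcm_cluster_prominence = sum((i + j - mux - muy)^4 * P),
    glcm_cluster_tendency   = sum((i + j - mux - muy)^2 * P),
    glcm_contrast           = sum((i - j)^2 * P),
    glcm_difference_entropy = -sum(plog2(pdiff)),
    glcm_dissimilarity      = sum(abs(i - j) * P),
    glcm_energy             = sum(P^2),
    glcm_entropy            = hxy,
    glcm_homogeneity        = sum(P / (1 + abs(i - j))),
    glcm_imc1               = imc1,
    glcm_idn                = sum(P / (1 + abs(i - j) / G)),
    glcm_inverse_variance   = sum(P[offd] / (i[offd] - j[offd])^2),
    glcm_max_probability    = max(P),
    glcm_sum_average        = sum((2:(2 * G)) * psum))
}
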