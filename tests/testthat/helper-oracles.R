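# Brute-force reference implementations, written as plain loops so they
# stay independent of the package's vectorized code paths.

## ordered+symmetric co-occurrence counts by explicit pixel loops
oracle_glcm <- function(levels, mask, G, d = 1,
                        directions = c("0", "45", "90", "135")) {
  offs <- list("0" = c(0, 1), "45" = c(-1, 1),
               "90" = c(-1, 0), "135" = c(-1, -1))
  total <- matrix(0, G, G)
  for (dir in directions) {
    o <- offs[[dir]] * d
    M <- matrix(0, G, G)
    for (k in seq_len(dim(levels)[3])) {
      for (r in seq_len(dim(levels)[1])) {
        for (c in seq_len(dim(levels)[2])) {
          r2 <- r + o[1]; c2 <- c + o[2]
          if (r2 < 1 || r2 > dim(levels)[1] || c2 < 1 ||
              c2 > dim(levels)[2]) next
          if (!mask[r, c, k] || !mask[r2, c2, k]) next
          a <- levels[r, c, k]; b <- levels[r2, c2, k]
          M[a, b] <- M[a, b] + 1
          M[b, a] <- M[b, a] + 1
        }
      }
    }
    total <- total + M
  }
  total <- total / length(directions)
  total / sum(total)
}

## per-formula summation oracles for the GLCM statistics
oracle_glcm_features <- function(P) {
  G <- nrow(P)
  px <- rowSums(P); py <- colSums(P)
  mux <- 0; muy <- 0
  for (i in 1:G) { mux <- mux + i * px[i]; muy <- muy + i * py[i] }
  f <- c(glcm_autocorrelation = 0, glcm_cluster_shade = 0,
         glcm_cluster_prominence = 0, glcm_cluster_tendency = 0,
         glcm_contrast = 0, glcm_difference_entropy = 0,
         glcm_dissimilarity = 0, glcm_energy = 0, glcm_entropy = 0,
         glcm_homogeneity = 0, glcm_imc1 = 0, glcm_idn = 0,
         glcm_inverse_variance = 0, glcm_max_probability = 0,
         glcm_sum_average = 0)
  pd <- rep(0, G); ps <- rep(0, 2 * G)
  hxy1 <- 0
  for (i in 1:G) for (j in 1:G) {
    p <- P[i, j]
    f["glcm_autocorrelation"] <- f["glcm_autocorrelation"] + i * j * p
    f["glcm_cluster_shade"] <- f["glcm_cluster_shade"] +
      (i + j - mux - muy)^3 * p
    f["glcm_cluster_prominence"] <- f["glcm_cluster_prominence"] +
      (i + j - mux - muy)^4 * p
    f["glcm_cluster_tendency"] <- f["glcm_cluster_tendency"] +
      (i + j - mux - muy)^2 * p
    f["glcm_contrast"] <- f["glcm_contrast"] + (i - j)^2 * p
    f["glcm_dissimilarity"] <- f["glcm_dissimilarity"] + abs(i - j) * p
    f["glcm_energy"] <- f["glcm_energy"] + p^2
    if (p > 0) f["glcm_entropy"] <- f["glcm_entropy"] - p * log2(p)
    f["glcm_homogeneity"] <- f["glcm_homogeneity"] + p / (1 + abs(i - j))
    f["glcm_idn"] <- f["glcm_idn"] + p / (1 + abs(i - j) / G)
    if (i != j)
      f["glcm_inverse_variance"] <- f["glcm_inverse_variance"] +
        p / (i - j)^2
    pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + p
    ps[i + j] <- ps[i + j] + p
    if (p > 0) hxy1 <- hxy1 - p * log2(px[i] * py[j])
  }
  for (k in seq_along(pd)) if (pd[k] > 0)
    f["glcm_difference_entropy"] <- f["glcm_difference_entropy"] -
      pd[k] * log2(pd[k])
  for (k in 2:(2 * G)) f["glcm_sum_average"] <-
    f["glcm_sum_average"] + k * ps[k]
  hx <- 0; hy <- 0
  for (i in 1:G) {
    if (px[i] > 0) hx <- hx - px[i] * log2(px[i])
    if (py[i] > 0) hy <- hy - py[i] * log2(py[i])
  }
  f["glcm_imc1"] <- if (max(hx, hy) > 0)
    (f[["glcm_entropy"]] - hxy1) / max(hx, hy) else 0
  f["glcm_max_probability"] <- max(P)
  f
}

## run-length matrix by explicit line scans
oracle_glrlm <- function(levels, mask, G, directions = c("0", "90")) {
  lmax <- max(dim(levels)[1:2])
  R <- matrix(0, G, lmax)
  scan_line <- function(vals, msk) {
    run_val <- NA; run_len <- 0
    for (t in seq_along(vals)) {
      v <- if (msk[t]) vals[t] else NA
      if (!is.na(v) && !is.na(run_val) && v == run_val) {
        run_len <- run_len + 1
      } else {
        if (!is.na(run_val)) R[run_val, run_len] <<- R[run_val, run_len] + 1
        run_val <- v; run_len <- 1
      }
    }
    if (!is.na(run_val)) R[run_val, run_len] <<- R[run_val, run_len] + 1
  }
  for (k in seq_len(dim(levels)[3])) {
    if ("0" %in% directions)
      for (r in seq_len(dim(levels)[1]))
        scan_line(levels[r, , k], mask[r, , k])
    if ("90" %in% directions)
      for (c in seq_len(dim(levels)[2]))
        scan_line(levels[, c, k], mask[, c, k])
  }
  R / length(directions)
}

oracle_glrlm_features <- function(R, n_voxels) {
  nr <- sum(R)
  sre <- 0; gln <- 0; hgl <- 0
  for (g in seq_len(nrow(R))) {
    rowsum_g <- 0
    for (j in seq_len(ncol(R))) {
      sre <- sre + R[g, j] / j^2
      hgl <- hgl + g^2 * R[g, j]
      rowsum_g <- rowsum_g + R[g, j]
    }
    gln <- gln + rowsum_g^2
  }
  c(glrlm_sre = sre / nr, glrlm_run_percentage = nr / n_voxels,
    glrlm_gln = gln / nr, glrlm_hglre = hgl / nr)
}

## NGTDM by an explicit 26-neighborhood loop per voxel
oracle_ngtdm <- function(levels, mask, G, eps = 1e-6) {
  d <- dim(levels)
  n_i <- rep(0, G); s_i <- rep(0, G)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    if (!mask[x, y, z]) next
    nb <- c()
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      x2 <- x + dx; y2 <- y + dy; z2 <- z + dz
      if (x2 < 1 || x2 > d[1] || y2 < 1 || y2 > d[2] ||
          z2 < 1 || z2 > d[3]) next
      if (mask[x2, y2, z2]) nb <- c(nb, levels[x2, y2, z2])
    }
    if (!length(nb)) next
    g <- levels[x, y, z]
    n_i[g] <- n_i[g] + 1
    s_i[g] <- s_i[g] + abs(g - mean(nb))
  }
  N <- sum(n_i)
  p_i <- n_i / N
  pres <- which(p_i > 0)
  psum <- sum(p_i * s_i)
  contrast <- 0; busy_den <- 0; complexity <- 0; strength_num <- 0
  if (length(pres) > 1) {
    csum <- 0
    for (i in pres) for (j in pres) {
      csum <- csum + p_i[i] * p_i[j] * (i - j)^2
      busy_den <- busy_den + abs(i * p_i[i] - j * p_i[j])
      complexity <- complexity +
        abs(i - j) * (p_i[i] * s_i[i] + p_i[j] * s_i[j]) /
        (p_i[i] + p_i[j])
      strength_num <- strength_num + (p_i[i] + p_i[j]) * (i - j)^2
    }
    contrast <- csum / (length(pres) * (length(pres) - 1)) * sum(s_i) / N
    complexity <- complexity / N
  }
  c(ngtdm_coarseness = 1 / max(psum, eps),
    ngtdm_contrast = contrast,
    ngtdm_busyness = if (busy_den > 0) psum / busy_den else 0,
    ngtdm_complexity = complexity,
    ngtdm_strength = if (sum(s_i) > 0) strength_num / sum(s_i) else 0)
}

## per-pixel neighborhood maps with explicit symmetric padding
oracle_entropy_map <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  refl <- function(i, n) ifelse(i < 1, 1 - i, ifelse(i > n, 2 * n + 1 - i, i))
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    vals <- c()
    for (dr in -1:1) for (dc in -1:1)
      vals <- c(vals, m[refl(r + dr, nr), refl(c + dc, nc)])
    p <- table(vals) / 9
    out[r, c] <- -sum(p * log2(p))
  }
  out
}

oracle_std_map <- function(m, type = "sample") {
  nr <- nrow(m); nc <- ncol(m)
  refl <- function(i, n) ifelse(i < 1, 1 - i, ifelse(i > n, 2 * n + 1 - i, i))
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    vals <- c()
    for (dr in -1:1) for (dc in -1:1)
      vals <- c(vals, m[refl(r + dr, nr), refl(c + dc, nc)])
    out[r, c] <- if (type == "sample") sd(vals) else
      sqrt(mean((vals - mean(vals))^2))
  }
  out
}

## small random quantized ROI whose intensities equal the gray levels
random_test_roi <- function(G = 4, dims = c(6, 6, 3), p_mask = 0.85) {
  repeat {
    mask <- array(runif(prod(dims)) < p_mask, dims)
    if (sum(mask) >= 27) break
  }
  lev <- array(sample.int(G, prod(dims), replace = TRUE), dims)
  roi <- image_roi(array(as.numeric(lev), dims), mask)
  q <- quantize_roi(roi, G = G, window = c(1, G + 1))
  list(roi = roi, q = q, mask = mask, levels = lev, G = G)
}
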