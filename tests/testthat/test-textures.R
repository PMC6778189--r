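test_that("quantization bins equal-width windows and handles degeneracy", {
  dims <- c(8, 4, 1)
  vals <- array(0:31, dims)
  roi <- image_roi(vals, array(TRUE, dims))
  q <- quantize_roi(roi, G = 32, window = c(0, 32))
  expect_identical(as.integer(q$levels), as.integer(vals + 1L))

  const <- image_roi(array(5, c(3, 3, 3)), array(TRUE, c(3, 3, 3)))
  qc <- quantize_roi(const, G = 8, window = c(0, 10))
  expect_true(length(unique(qc$levels[qc$mask])) == 1L)
  expect_error(quantize_roi(const, G = 8), "degenerate")

  set.seed(7)
  u <- array(runif(4000, 0, 100), c(20, 20, 10))
  qu <- quantize_roi(image_roi(u, array(TRUE, dim(u))), G = 4,
                     window = c(0, 100))
  counts <- tabulate(qu$levels[qu$mask], 4)
  expect_true(all(abs(counts - 1000) < 3 * sqrt(1000)))
})

test_that("GLCM matches hand counts on the four-level toy slice", {
  toy <- matrix(c(0, 0, 1, 1,
                  0, 0, 1, 1,
                  0, 2, 2, 2,
                  2, 2, 3, 3), 4, 4, byrow = TRUE) + 1
  lev <- array(toy, c(4, 4, 1))
  roi <- image_roi(array(as.numeric(lev), dim(lev)),
                   array(TRUE, dim(lev)))
  q <- quantize_roi(roi, G = 4, window = c(1, 5))
  ## 0-degree direction only, unnormalized symmetric counts
  raw <- deltarad:::glcm_slice_counts(q$levels[, , 1], 0L, 1L, 4L)
  sym <- raw + t(raw)
  expect_equal(sym[1, 1], 4)  # two horizontal (0,0) adjacencies, both orders
  P <- glcm_3d(q, directions = "0")
  expect_equal(P, oracle_glcm(lev, roi$mask, 4, directions = "0"))
  fv <- glcm_features(P)
  expect_equal(fv, oracle_glcm_features(P), tolerance = 1e-12)
})

test_that("GLCM is symmetric, normalized, and transpose-invariant", {
  set.seed(11)
  for (rep in 1:10) {
    tr <- random_test_roi(G = 4)
    P <- glcm_3d(tr$q)
    expect_equal(sum(P), 1, tolerance = 1e-12)
    expect_equal(P, t(P), tolerance = 1e-12)
    ## transposing every slice swaps 0<->90 and 45<->135, so the
    ## direction-averaged matrix is unchanged
    lev_t <- aperm(tr$levels, c(2, 1, 3))
    mask_t <- aperm(tr$mask, c(2, 1, 3))
    roi_t <- image_roi(array(as.numeric(lev_t), dim(lev_t)), mask_t)
    q_t <- quantize_roi(roi_t, G = tr$G, window = c(1, tr$G + 1))
    expect_equal(glcm_3d(q_t), P, tolerance = 1e-12)
  }
})

test_that("constant ROI degenerates correctly across families", {
  dims <- c(5, 5, 3)
  roi <- image_roi(array(7, dims), array(TRUE, dims))
  q <- quantize_roi(roi, G = 8, window = c(0, 16))
  P <- glcm_3d(q)
  fv <- glcm_features(P)
  expect_equal(unname(fv["glcm_energy"]), 1)
  expect_equal(unname(fv["glcm_entropy"]), 0)
  expect_equal(unname(fv["glcm_max_probability"]), 1)
  expect_equal(unname(fv["glcm_contrast"]), 0)
  expect_equal(unname(fv["glcm_dissimilarity"]), 0)

  ng <- ngtdm_features(q)
  expect_equal(unname(ng["ngtdm_contrast"]), 0)
  expect_equal(unname(ng["ngtdm_busyness"]), 0)
  expect_equal(unname(ng["ngtdm_complexity"]), 0)
  expect_equal(unname(ng["ngtdm_coarseness"]), 1e6)  # 1/eps guard

  hf <- histogram_features(roi, G = 8, window = c(0, 16))
  expect_equal(unname(hf["fo_std"]), 0)
  expect_equal(unname(hf["fo_entropy"]), 0)
  expect_equal(unname(hf["fo_uniformity"]), 1)
})

test_that("GLRLM run accounting matches manual enumeration", {
  ## single row 1,1,2,2,2 scanned in the 0-degree direction only
  lev <- array(c(1, 1, 2, 2, 2), c(1, 5, 1))
  roi <- image_roi(array(as.numeric(lev), dim(lev)), array(TRUE, dim(lev)))
  q <- quantize_roi(roi, G = 2, window = c(1, 3))
  R <- glrlm_3d(q, directions = "0")
  expect_equal(R[1, 2], 1)  # one run of level 1, length 2
  expect_equal(R[2, 3], 1)  # one run of level 2, length 3
  expect_equal(sum(R), 2)
  fv <- glrlm_features(R, n_voxels = 5)
  expect_equal(unname(fv["glrlm_run_percentage"]), 2 / 5)

  ## constant row: one run of length N -> SRE = 1/N^2
  levc <- array(1, c(1, 6, 1))
  qc <- quantize_roi(image_roi(array(1, dim(levc)), array(TRUE, dim(levc))),
                     G = 2, window = c(1, 3))
  Rc <- glrlm_3d(qc, directions = "0")
  expect_equal(unname(glrlm_features(Rc, 6)["glrlm_sre"]), 1 / 36)

  ## checkerboard: all runs length 1 -> SRE = 1
  cb <- outer(1:4, 1:4, function(a, b) (a + b) %% 2 + 1)
  qcb <- quantize_roi(image_roi(array(cb, c(4, 4, 1)),
                                array(TRUE, c(4, 4, 1))),
                      G = 2, window = c(1, 3))
  expect_equal(unname(glrlm_features(glrlm_3d(qcb), 16)["glrlm_sre"]), 1)
})

test_that("NGTDM matches the explicit neighborhood-loop oracle", {
  set.seed(5)
  lev <- array(sample.int(2, 27, replace = TRUE), c(3, 3, 3))
  roi <- image_roi(array(as.numeric(lev), dim(lev)), array(TRUE, dim(lev)))
  q <- quantize_roi(roi, G = 2, window = c(1, 3))
  expect_equal(ngtdm_features(q), oracle_ngtdm(lev, roi$mask, 2),
               tolerance = 1e-12)
})

test_that("histogram features reproduce direct arithmetic and moments", {
  vals <- c(1, 2, 3, 4, 5)
  roi <- image_roi(array(vals, c(5, 1, 1)), array(TRUE, c(5, 1, 1)))
  hf <- histogram_features(roi, G = 8, window = c(0, 8))
  expect_equal(unname(hf["fo_mean"]), 3)
  expect_equal(unname(hf["fo_median"]), 3)
  expect_equal(unname(hf["fo_mad"]), 1.2)
  expect_equal(unname(hf["fo_max_mean"]), 5 / 3)

  set.seed(42)
  z <- rnorm(1e5)
  rz <- image_roi(array(z, c(100, 100, 10)), array(TRUE, c(100, 100, 10)))
  hz <- histogram_features(rz, G = 32, window = c(-5, 5))
  expect_lt(abs(hz[["fo_skewness"]]), 3 * sqrt(6 / 1e5))
  expect_lt(abs(hz[["fo_kurtosis"]] - 3), 3 * sqrt(24 / 1e5))

  roi0 <- image_roi(array(c(-1, 1), c(2, 1, 1)), array(TRUE, c(2, 1, 1)))
  expect_error(histogram_features(roi0), "zero")
})

test_that("shape features: cube volume and closed-form sphericity", {
  m <- array(FALSE, c(12, 12, 12)); m[2:11, 2:11, 2:11] <- TRUE
  roi <- image_roi(array(0, dim(m)), m)
  sf <- shape_features(roi)
  expect_equal(unname(sf["shape_volume"]), 1000)
  expect_equal(unname(sf["shape_sphericity"]), pi^(1 / 3) * 6^(2 / 3) / 6,
               tolerance = 1e-12)
  ## an elongated box is less spherical than the cube
  m2 <- array(FALSE, c(30, 6, 6)); m2[2:29, 2:5, 2:5] <- TRUE
  sf2 <- shape_features(image_roi(array(0, dim(m2)), m2))
  expect_lt(sf2[["shape_sphericity"]], sf[["shape_sphericity"]])
})

test_that("features ignore voxels outside the mask", {
  set.seed(9)
  tr <- random_test_roi(G = 4)
  roi2 <- tr$roi
  roi2$intensities[!roi2$mask] <- 999
  q2 <- quantize_roi(roi2, G = tr$G, window = c(1, tr$G + 1))
  expect_equal(glcm_3d(tr$q), glcm_3d(q2))
  expect_equal(ngtdm_features(tr$q), ngtdm_features(q2))
  expect_equal(histogram_features(tr$roi, G = 4, window = c(1, 5)),
               histogram_features(roi2, G = 4, window = c(1, 5)))
})

test_that("all matrix features match brute-force oracles on random ROIs", {
  set.seed(123)
  for (rep in 1:25) {
    G <- sample(2:5, 1)
    tr <- random_test_roi(G = G, dims = c(sample(4:6, 1), sample(4:6, 1),
                                          sample(2:3, 1)))
    P <- glcm_3d(tr$q)
    expect_equal(P, oracle_glcm(tr$levels, tr$mask, G), tolerance = 1e-10)
    expect_equal(glcm_features(P), oracle_glcm_features(P),
                 tolerance = 1e-10)
    R <- glrlm_3d(tr$q)
    expect_equal(R, oracle_glrlm(tr$levels, tr$mask, G), tolerance = 1e-10)
    expect_equal(glrlm_features(R, sum(tr$mask)),
                 oracle_glrlm_features(R, sum(tr$mask)), tolerance = 1e-10)
    expect_equal(ngtdm_features(tr$q), oracle_ngtdm(tr$levels, tr$mask, G),
                 tolerance = 1e-10)
  }
})
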