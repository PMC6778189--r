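test_that("local entropy: constant, distinct-levels and oracle agreement", {
  expect_equal(local_entropy(matrix(5, 4, 4)), matrix(0, 4, 4))
  m9 <- matrix(1:9, 3, 3)
  expect_equal(local_entropy(m9)[2, 2], log2(9))
  set.seed(21)
  for (rep in 1:20) {
    sl <- matrix(sample.int(8, 64, replace = TRUE), 8, 8)
    expect_equal(local_entropy(sl), oracle_entropy_map(sl),
                 tolerance = 1e-10)
  }
})

test_that("local std: convention, nonnegativity and oracle agreement", {
  ## neighborhood {0 x8, 9}: sample sd = 3 exactly
  m <- matrix(0, 5, 5); m[3, 3] <- 9
  expect_equal(local_std(m)[3, 3], 3)
  expect_equal(local_std(m, type = "population")[3, 3], sqrt(8))
  set.seed(22)
  for (rep in 1:20) {
    sl <- matrix(rnorm(64), 8, 8)
    expect_true(all(local_std(sl) >= 0))
    expect_equal(local_std(sl), oracle_std_map(sl), tolerance = 1e-8)
  }
})

test_that("entropy map is invariant to monotone level relabeling", {
  set.seed(23)
  sl <- matrix(sample.int(6, 64, replace = TRUE), 8, 8)
  relab <- c(2, 5, 11, 20, 33, 50)  # strictly increasing relabeling
  expect_equal(local_entropy(matrix(relab[sl], 8, 8)), local_entropy(sl))
})

test_that("NESTD maps are bounded, zero for constant input, extreme at edges", {
  cm <- nestd_maps(matrix(3, 8, 8))
  expect_equal(cm$nestd, matrix(0, 8, 8))

  set.seed(24)
  ## flat organ (left half) against an offset, mildly noisy background:
  ## the intensity step makes the std map spike at the boundary, so the
  ## minimum of entropy - std localizes the organ edge
  ph <- cbind(matrix(0, 16, 8), matrix(rnorm(16 * 8, 100, 5), 16, 8))
  mp <- nestd_maps(ph)
  expect_true(all(mp$nestd >= -1 & mp$nestd <= 1))
  expect_true(all(mp$entropy >= 0 & mp$entropy <= 1))
  expect_true(all(mp$std >= 0 & mp$std <= 1))
  ## the most negative NESTD values sit in the boundary band (cols 7-10)
  ext <- which(mp$nestd == min(mp$nestd), arr.ind = TRUE)
  expect_true(all(ext[, 2] >= 7 & ext[, 2] <= 10))
})

test_that("scalar NESTD feature: constant zero, shift invariance, oracle", {
  dims <- c(10, 10, 3)
  mask <- array(FALSE, dims); mask[3:8, 3:8, ] <- TRUE
  roi_const <- image_roi(array(4, dims), mask)
  expect_equal(nestd_feature(roi_const), 0)

  set.seed(25)
  vol <- array(rnorm(prod(dims), 100, 25), dims)
  roi <- image_roi(vol, mask)
  f1 <- nestd_feature(roi)
  f2 <- nestd_feature(image_roi(vol + 500, mask))
  expect_equal(f1, f2, tolerance = 1e-12)

  ## independent per-slice recomputation
  vals <- c()
  for (k in 1:dims[3]) {
    msk <- mask[, , k]
    box <- deltarad:::auto_box(msk, 2L)
    maps <- nestd_maps(vol[, , k], box)
    vals <- c(vals, maps$nestd[msk[box[1]:box[2], box[3]:box[4]]])
  }
  expect_equal(f1, mean(vals), tolerance = 1e-12)
})

test_that("contour overlays are written for mask-bearing slices only", {
  dims <- c(12, 12, 4)
  mask <- array(FALSE, dims); mask[4:9, 4:9, 2:3] <- TRUE
  set.seed(26)
  roi <- image_roi(array(rnorm(prod(dims), 0, 10), dims), mask)
  dir <- tempfile("overlay")
  files <- contour_overlay(roi, dir)
  expect_length(files, 2)
  expect_true(all(file.exists(files)))
})
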