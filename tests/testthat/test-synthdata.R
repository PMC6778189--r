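test_that("cohort bookkeeping: counts, labels, shared masks", {
  spec <- cohort_spec(n_good = 2, n_bad = 2, n_fractions = 3,
                      volume_shape = c(12, 12, 9), seed = 1)
  co <- generate_cohort(spec)
  expect_length(co$images, 12)
  expect_equal(sum(co$labels == "good"), 2)
  expect_equal(sum(co$labels == "bad"), 2)
  ## one shared mask per patient, nonempty
  m1 <- co$images[["P001_1"]]$roi$mask
  m3 <- co$images[["P001_3"]]$roi$mask
  expect_identical(m1, m3)
  expect_gte(sum(m1), 27)
  expect_error(cohort_spec(n_good = 1, n_bad = 1,
                           volume_shape = c(4, 4, 4)),
               "minimum shape")
})

test_that("same seed reproduces the cohort bit-identically", {
  spec <- cohort_spec(n_good = 1, n_bad = 1, n_fractions = 2,
                      volume_shape = c(12, 12, 9), seed = 7)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$images[["P002_2"]]$roi$intensities,
                   b$images[["P002_2"]]$roi$intensities)
  expect_identical(a$motion, b$motion)
})

test_that("no drift, no noise: every fraction of a patient is identical", {
  spec <- cohort_spec(n_good = 1, n_bad = 1, n_fractions = 4,
                      volume_shape = c(12, 12, 9), patient_sd = 0,
                      noise_sd = 0, motion_fraction = 0,
                      scanner_fraction = 0, seed = 3)
  co <- generate_cohort(spec)
  for (n in 2:4)
    expect_identical(co$images[[paste0("P001_", n)]]$roi$intensities,
                     co$images[["P001_1"]]$roi$intensities)
  ## hence every DRF downstream is exactly zero
  ft <- extract_feature_table(co, G = 8,
                              families = c("firstorder", "glcm"))
  drf <- compute_drf(ft)
  expect_true(all(abs(as.matrix(drf$drf[, drf$features])) < 1e-12))
})

test_that("planted mean drift is recovered in feature units", {
  spec <- cohort_spec(n_good = 8, n_bad = 1, n_fractions = 6,
                      volume_shape = c(16, 16, 9),
                      planted_features = data.frame(
                        feature = "mean", slope_good = -2, slope_bad = 0),
                      patient_sd = 0.01, noise_sd = 2,
                      motion_fraction = 0, scanner_fraction = 0, seed = 4)
  co <- generate_cohort(spec)
  slopes <- vapply(names(co$labels)[co$labels == "good"], function(id) {
    ms <- vapply(1:6, function(n) {
      roi <- co$images[[paste(id, n, sep = "_")]]$roi
      mean(roi$intensities[roi$mask])
    }, 0)
    unname(coef(lm(ms ~ I(1:6)))[2])
  }, 0)
  se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - (-2)), 3 * se + 0.05)
})

test_that("planted kurtosis drift is recovered on an uncorrelated field", {
  spec <- cohort_spec(n_good = 10, n_bad = 1, n_fractions = 8,
                      volume_shape = c(20, 20, 10),
                      planted_features = data.frame(
                        feature = "kurtosis", slope_good = -0.05,
                        slope_bad = 0),
                      patient_sd = 0.01, noise_sd = 0,
                      motion_fraction = 0, scanner_fraction = 0,
                      base_texture = list(lambda = 0), seed = 2)
  co <- generate_cohort(spec)
  slopes <- vapply(names(co$labels)[co$labels == "good"], function(id) {
    ks <- vapply(1:8, function(n) {
      histogram_features(co$images[[paste(id, n, sep = "_")]]$roi,
                         G = 16, window = c(-200, 400))[["fo_kurtosis"]]
    }, 0)
    unname(coef(lm(ks ~ I(1:8)))[2])
  }, 0)
  se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - (-0.05)), 3 * se)
})

test_that("NIfTI round trip preserves the cohort", {
  spec <- cohort_spec(n_good = 1, n_bad = 1, n_fractions = 2,
                      volume_shape = c(12, 12, 9), seed = 5)
  co <- generate_cohort(spec)
  dir <- tempfile("cohort")
  man <- write_cohort(co, dir)
  expect_equal(nrow(man), 4)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- read_cohort(dir)
  expect_equal(back$labels, co$labels)
  expect_equal(back$images[["P001_1"]]$roi$intensities,
               co$images[["P001_1"]]$roi$intensities, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(back$images[["P001_1"]]$roi$mask,
               co$images[["P001_1"]]$roi$mask, ignore_attr = TRUE)
})

test_that("DRF-level cohort: determinism and stratified nuisance balance", {
  a <- simulate_drf_cohort(n_good = 10, n_bad = 8, n_fractions = 6,
                           n_features = 5, seed = 9)
  b <- simulate_drf_cohort(n_good = 10, n_bad = 8, n_fractions = 6,
                           n_features = 5, seed = 9)
  expect_identical(a$drf$drf, b$drf$drf)
  expect_equal(nrow(a$drf$drf), 18 * 5)
  ## motion split is balanced within each response group
  good <- names(a$labels)[a$labels == "good"]
  expect_equal(sum(a$motion[good] == "high"), 5)
  ## weekly aggregates are present and finite
  expect_false(is.null(a$drf$weekly))
  expect_true(all(is.finite(as.matrix(a$drf$weekly[, a$drf$features]))))
})

test_that("Bayes-optimal AUC oracle behaves sensibly", {
  sim <- simulate_drf_cohort(n_good = 5, n_bad = 5, seed = 10)
  a1 <- bayes_optimal_auc(sim$truth, n_mc = 2e4, seed = 1)
  a2 <- bayes_optimal_auc(sim$truth, n_mc = 2e4, seed = 1)
  expect_identical(a1, a2)
  expect_gt(a1, 0.8); expect_lt(a1, 1)
  ## a single weaker feature has lower Bayes AUC than the full triple
  a_one <- bayes_optimal_auc(sim$truth, features = "nestd",
                             n_mc = 2e4, seed = 1)
  expect_lt(a_one, a1)
})
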