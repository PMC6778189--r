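small_cohort <- function(seed = 61, ...) {
  simulate_drf_cohort(n_good = 15, n_bad = 12, n_fractions = 12,
                      n_features = 8, seed = seed, ...)
}

test_that("Spearman filter removes monotone duplicates, keeps independents", {
  set.seed(62)
  drf <- data.frame(patient = rep(sprintf("p%02d", 1:10), each = 5),
                    fraction = rep(2:6, 10))
  drf$a <- rnorm(50)
  drf$b <- exp(drf$a)          # strictly monotone transform: rho = 1
  drf$c <- rnorm(50)           # independent
  drf$d <- 1                   # constant: excluded with warning
  t <- new_drf_table(drf)
  expect_warning(sp <- spearman_filter(t), "constant")
  expect_true(all(c("a", "c") %in% sp$kept) || all(c("b", "c") %in% sp$kept))
  expect_length(sp$kept, 2)
  expect_equal(sp$cluster[["a"]], sp$cluster[["b"]])
  expect_true(is.na(sp$cluster[["d"]]))

  ## many independent features over many rows: none removed
  set.seed(63)
  big <- data.frame(patient = rep(sprintf("p%02d", 1:20), each = 25),
                    fraction = rep(2:26, 20))
  for (k in 1:12) big[[paste0("f", k)]] <- runif(500)
  spb <- spearman_filter(new_drf_table(big))
  expect_length(spb$kept, 12)
})

test_that("motion robustness flags planted motion sensitivity", {
  sim <- simulate_drf_cohort(n_good = 24, n_bad = 20, n_fractions = 16,
                             n_features = 8, seed = 64,
                             motion_affected = "kurtosis",
                             motion_sd_mult = 4)
  cm <- cov_mslr(sim$drf, sim$motion, seed = 64)
  expect_false(cm$motion_robust[cm$feature == "kurtosis"])
  expect_true(cm$motion_robust[cm$feature == "coarseness"])
  expect_true(cm$motion_robust[cm$feature == "nestd"])
  ## noise features have near-zero means: COV unusable, never robust
  expect_false(any(cm$motion_robust[grepl("noise", cm$feature)]))
})

test_that("scanner screen: null passes, strong offset fails, balanced closed form", {
  sim0 <- small_cohort(seed = 65)
  se0 <- scanner_effect(sim0$drf, sim0$scanner, sim0$labels)
  expect_true(se0$scanner_robust[se0$feature == "kurtosis"])

  sim1 <- small_cohort(seed = 65, scanner_affected = "kurtosis",
                       scanner_offset = 0.5)
  se1 <- scanner_effect(sim1$drf, sim1$scanner, sim1$labels)
  expect_false(se1$scanner_robust[se1$feature == "kurtosis"])

  ## balanced response x scanner: the adjusted regression coefficient on
  ## per-patient means equals the raw difference of scanner means
  drf <- expand.grid(patient = sprintf("p%02d", 1:8), fraction = 2:4,
                     stringsAsFactors = FALSE)
  labels <- setNames(rep(c("good", "bad"), each = 4), sprintf("p%02d", 1:8))
  scanner <- setNames(rep(c("A", "B"), 4), sprintf("p%02d", 1:8))
  set.seed(66)
  drf$f <- rnorm(nrow(drf)) + 0.8 * (scanner[drf$patient] == "B")
  pm <- tapply(drf$f, drf$patient, mean)
  fit <- lm(pm ~ factor(scanner[names(pm)]) + factor(labels[names(pm)]))
  sb <- scanner[names(pm)] == "B"
  expect_equal(unname(coef(fit)[2]), mean(pm[sb]) - mean(pm[!sb]),
               tolerance = 1e-10)
})

test_that("overall Welch t test equals the hand formula", {
  ## six patients whose per-patient mean DRFs are 1,2,3 (good), 4,5,6 (bad)
  drf <- data.frame(patient = rep(sprintf("p%d", 1:6), each = 2),
                    fraction = rep(2:3, 6),
                    f = rep(1:6, each = 2))
  t <- new_drf_table(drf)
  labels <- setNames(rep(c("good", "bad"), each = 3), sprintf("p%d", 1:6))
  gt <- group_ttests(t, labels)
  m1 <- mean(1:3); m2 <- mean(4:6); v1 <- var(1:3); v2 <- var(4:6)
  tstat <- (m1 - m2) / sqrt(v1 / 3 + v2 / 3)
  df <- (v1 / 3 + v2 / 3)^2 / ((v1 / 3)^2 / 2 + (v2 / 3)^2 / 2)
  expect_equal(gt$overall$ttest_overall_p,
               2 * pt(-abs(tstat), df), tolerance = 1e-12)
})

test_that("trend regression recovers exact slopes and detects interactions", {
  drf <- expand.grid(patient = sprintf("p%02d", 1:6), fraction = 2:9,
                     stringsAsFactors = FALSE)
  labels <- setNames(rep(c("good", "bad"), each = 3), sprintf("p%02d", 1:6))
  drf$f <- ifelse(labels[drf$patient] == "good",
                  0.02 * drf$fraction, -0.01 * drf$fraction)
  tr <- suppressWarnings(trend_regression(new_drf_table(drf), labels))
  expect_equal(tr$slope_good, 0.02, tolerance = 1e-12)
  expect_equal(tr$slope_bad, -0.01, tolerance = 1e-12)

  set.seed(67)
  drf$g <- drf$f + rnorm(nrow(drf), 0, 0.01)
  tr2 <- trend_regression(new_drf_table(drf[, c("patient", "fraction", "g")]),
                          labels)
  expect_lt(tr2$trend_p, 0.01)
})

test_that("screening cascade finds planted features and controls noise", {
  sim <- simulate_drf_cohort(n_good = 20, n_bad = 16, n_fractions = 20,
                             n_features = 10, seed = 68)
  sc <- drf_screen(sim$drf, sim$labels, motion = sim$motion,
                   scanner = sim$scanner, seed = 68)
  expect_s3_class(sc, "drf_screen")
  got <- sc$candidates
  planted <- sim$truth$planted$feature
  expect_gte(length(intersect(got, planted)), 2)
  expect_lte(length(setdiff(got, planted)), 1)
  ## relaxing alpha is monotone: candidates only grow
  expect_true(all(candidates(sc, 0.01) %in% candidates(sc, 0.05)))
  expect_true(all(candidates(sc, 0.05) %in% candidates(sc, 0.20)))
  ## report invariants
  pcols <- c("mslr_p", "motion_ttest_p", "scanner_reg_p",
             "ttest_overall_p", "trend_p", "lrt_p")
  for (pc in pcols) {
    v <- sc$report[[pc]]
    expect_true(all(v[is.finite(v)] >= 0 & v[is.finite(v)] <= 1))
  }
})
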