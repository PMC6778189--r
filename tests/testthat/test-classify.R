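test_that("class models: means, sample covariance and priors", {
  X <- rbind(c(0, 0), c(2, 0), c(0, 2), c(2, 2),
             c(5, 5), c(6, 5), c(5, 6), c(6, 6), c(7, 7), c(4, 4))
  y <- rep(c("good", "bad"), each = 4)
  ## 30/20-style priors
  y2 <- c(rep("good", 6), rep("bad", 4))
  cm <- fit_class_models(X, y2, classes = c("good", "bad"))
  expect_equal(unname(cm$prior), c(0.6, 0.4))
  cmg <- fit_class_models(X[1:8, ], y, classes = c("good", "bad"))
  expect_equal(unname(cmg$mean$good), c(1, 1))
  expect_equal(cmg$cov$good, diag(4 / 3, 2), ignore_attr = TRUE)
})

test_that("Mahalanobis distance: Euclidean reduction and dual-route check", {
  expect_equal(maha_dist2(c(3, 4), c(0, 0), diag(2)), 25)
  expect_equal(maha_dist2(c(1, 2), c(1, 2), diag(2)), 0)
  set.seed(91)
  for (rep in 1:20) {
    A <- matrix(rnorm(9), 3)
    C <- crossprod(A) + diag(0.5, 3)
    t <- rnorm(3); m <- rnorm(3)
    direct <- drop(t(t - m) %*% solve(C) %*% (t - m))
    expect_equal(maha_dist2(t, m, C), direct, tolerance = 1e-10)
  }
  expect_error(maha_dist2(c(1, 1), c(0, 0), matrix(c(1, 2, 2, 1), 2)),
               "positive definite")
})

test_that("Gaussian discriminant matches the explicit density oracle", {
  m1 <- c(0, 0); m2 <- c(2, 1)
  C1 <- matrix(c(1, 0.3, 0.3, 0.8), 2)
  C2 <- matrix(c(1.5, -0.2, -0.2, 0.6), 2)
  cm <- structure(list(classes = c("good", "bad"),
                       mean = list(good = m1, bad = m2),
                       cov = list(good = C1, bad = C2),
                       prior = c(good = 0.6, bad = 0.4), d = 2),
                  class = "class_models")
  dens <- function(x, m, C)
    (2 * pi)^(-1) * det(C)^(-0.5) *
      exp(-0.5 * drop(t(x - m) %*% solve(C) %*% (x - m)))
  set.seed(92)
  for (rep in 1:10) {
    x <- rnorm(2)
    res <- classify_bayes(x, cm)
    pg <- 0.6 * dens(x, m1, C1)
    pb <- 0.4 * dens(x, m2, C2)
    expect_equal(unname(res$posterior[1, "good"]), pg / (pg + pb),
                 tolerance = 1e-10)
    expect_equal(res$label, if (pg >= pb) "good" else "bad")
  }
})

test_that("equal priors and covariances reduce to nearest centroid / bisector", {
  C <- matrix(c(1.2, 0.4, 0.4, 0.9), 2)
  cm <- structure(list(classes = c("good", "bad"),
                       mean = list(good = c(-1, 0), bad = c(1, 0)),
                       cov = list(good = C, bad = C),
                       prior = c(good = 0.5, bad = 0.5), d = 2),
                  class = "class_models")
  mid <- c(0, 0)
  expect_equal(unname(classify_bayes(mid, cm)$posterior[1, "good"]), 0.5,
               tolerance = 1e-12)
  set.seed(93)
  X <- matrix(rnorm(40), 20, 2)
  res <- classify_bayes(X, cm)
  nearest <- ifelse(res$d2[, "good"] <= res$d2[, "bad"], "good", "bad")
  expect_equal(res$label, nearest)

  ## identical class distributions with priors 0.9/0.1: prior always wins
  cm2 <- cm; cm2$mean$bad <- cm2$mean$good
  cm2$prior <- c(good = 0.9, bad = 0.1)
  expect_true(all(classify_bayes(X, cm2)$label == "good"))
})

test_that("Mann-Whitney AUC equals trapezoidal ROC area, and matches pROC", {
  set.seed(94)
  for (rep in 1:20) {
    n <- 40
    truth <- sample(c("good", "bad"), n, replace = TRUE,
                    prob = c(0.6, 0.4))
    scores <- round(rnorm(n, ifelse(truth == "good", 0.5, 0)), 1)  # ties
    if (length(unique(truth)) < 2) next
    a1 <- auc_mw(scores, truth)
    a2 <- roc_curve(scores, truth)$auc
    expect_equal(a1, a2, tolerance = 1e-12)
  }
  skip_if_not_installed("pROC")
  set.seed(95)
  truth <- rep(c("good", "bad"), each = 25)
  scores <- rnorm(50, ifelse(truth == "good", 1, 0))
  pr <- suppressMessages(pROC::auc(pROC::roc(
    truth, scores, levels = c("bad", "good"), direction = "<")))
  expect_equal(auc_mw(scores, truth), as.numeric(pr), tolerance = 1e-12)
})

test_that("LOO-CV separates a planted cohort and scores perfectly when separable", {
  sim <- simulate_drf_cohort(n_good = 10, n_bad = 8, n_fractions = 28,
                             n_features = 4, seed = 96,
                             planted = data.frame(
                               feature = c("f1", "f2"),
                               offset = c(0.5, 0.5),
                               slope_good = c(0.05, -0.04),
                               slope_bad = c(-0.01, 0.01)),
                             patient_sd = 0.01, noise_sd = 0.02)
  ws <- weekly_samples(sim, weeks = 2:4)
  cv <- loo_cv(ws, sim$labels, c("f1", "f2"), seed = 1)
  expect_gte(cv$auc, 0.99)
  expect_gte(cv$accuracy, 0.95)
  expect_equal(cv$accuracy_patient, 1)
  expect_equal(sum(cv$confusion) , 18)
  expect_equal(sum(diag(cv$confusion)), 18)
})

test_that("bootstrap ensemble: disjointness, CI from order statistics", {
  sim <- simulate_drf_cohort(n_good = 12, n_bad = 10, n_fractions = 28,
                             n_features = 4, seed = 97)
  ws <- weekly_samples(sim, weeks = 2:4)
  ids <- unique(ws$patient)
  lab <- sim$labels
  good <- ids[lab[ids] == "good"]; bad <- ids[lab[ids] == "bad"]
  train <- ws[ws$patient %in% c(good[1:7], bad[1:6]), ]
  test <- ws[ws$patient %in% c(good[8:12], bad[7:10]), ]
  be <- bootstrap_ensemble(train, test, lab, c("kurtosis", "coarseness"),
                           nboot = 20, seed = 2)
  sa <- sort(be$boot_aucs)
  expect_equal(unname(be$auc_ci),
               c(sa[ceiling(0.025 * 20)], sa[ceiling(0.975 * 20)]))
  expect_error(bootstrap_ensemble(train, train, lab,
                                  c("kurtosis", "coarseness")),
               "disjoint")
})

test_that("combo search enumerates C(k,2)+C(k,3) combos deterministically", {
  sim <- simulate_drf_cohort(n_good = 8, n_bad = 7, n_fractions = 28,
                             n_features = 3, seed = 98)
  ws <- weekly_samples(sim, weeks = 2:4)
  cs1 <- combo_search(ws, sim$labels, sim$drf$features, seed = 3)
  expect_equal(nrow(cs1), choose(3, 2) + choose(3, 3))
  cs2 <- combo_search(ws, sim$labels, sim$drf$features, seed = 3)
  expect_identical(cs1$combo, cs2$combo)
  expect_identical(cs1$auc, cs2$auc)
})
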