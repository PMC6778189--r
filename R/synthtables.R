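#' Default planted-feature configuration for DRF-level cohorts
#'
#' Three discriminative features whose DRF trajectories drift at
#' group-dependent per-fraction rates on top of a common baseline offset.
#' The offsets keep the group coefficient of variation moderate (DRF
#' magnitudes well away from zero), which is what makes the COV-based
#' motion-robustness grading meaningful; the slope contrasts are sized so
#' that the three features jointly separate the response groups at an
#' AUC in the low-to-mid 0.9s on weekly values, the regime of interest
#' for early-response prediction.
#'
#' @return Data frame with columns `feature`, `offset`, `slope_good`,
#'   `slope_bad`.
#' @export
default_planted <- function() {
  data.frame(feature = c("kurtosis", "coarseness", "nestd"),
             offset = c(0.50, 0.45, 0.40),
             slope_good = c(0.016, -0.013, 0.010),
             slope_bad = c(0.006, -0.005, 0.004),
             stringsAsFactors = FALSE)
}

#' Simulate a cohort of delta-radiomic feature trajectories
#'
#' Generates DRF values directly at the feature-table level (no images):
#' for a planted feature, `DRF[i, n] = offset + slope_g * n + u[i] + e`,
#' with per-(patient, feature) random intercepts `u ~ N(0, patient_sd)`
#' and i.i.d. noise `e ~ N(0, noise_sd)`; non-planted features are pure
#' noise around zero. This is the statistical structure the screening
#' cascade and classifier assume, at the exact cohort dimensions of a
#' daily-imaging study, and is the workhorse for validating those stages
#' at full scale. Motion and scanner assignments are stratified by
#' response group; optional nuisance effects (noise inflation for
#' high-motion patients, additive offsets for scanner B) can be planted
#' on chosen features to exercise the robustness screens.
#'
#' @param n_good,n_bad Patients per response group (defaults 50/40).
#' @param n_fractions Fractions per patient (default 28; DRFs exist for
#'   fractions 2 onward).
#' @param n_features Total number of features (planted ones included).
#' @param planted Data frame as in [default_planted()] (features, common
#'   offset, per-group slopes).
#' @param patient_sd Sd of the per-(patient, feature) random intercept.
#' @param noise_sd Sd of the per-observation noise.
#' @param null_sd Sd of the non-planted (pure noise) features.
#' @param motion_fraction,scanner_fraction Nuisance proportions
#'   (stratified within response groups).
#' @param motion_affected Features whose noise is inflated for
#'   high-motion patients.
#' @param motion_sd_mult Noise multiplier for those features.
#' @param scanner_affected Features receiving an additive scanner-B
#'   offset.
#' @param scanner_offset The offset.
#' @param seed Integer seed.
#' @return Object of class `synthetic_drf_cohort`: `drf` (a `drf_table`
#'   with weekly aggregates), `labels`, `motion`, `scanner` (named by
#'   patient) and `truth` (all generator parameters).
#' @examples
#' sim <- simulate_drf_cohort(n_good = 5, n_bad = 5, n_fractions = 6,
#'                            n_features = 4, seed = 1)
#' sim$drf
#' @export
simulate_drf_cohort <- function(n_good = 50L, n_bad = 40L,
                                n_fractions = 28L, n_features = 20L,
                                planted = default_planted(),
                                patient_sd = 0.03, noise_sd = 0.08,
                                null_sd = 0.05,
                                motion_fraction = 0.5,
                                scanner_fraction = 0.44,
                                motion_affected = character(0),
                                motion_sd_mult = 2,
                                scanner_affected = character(0),
                                scanner_offset = 0,
                                seed = 1L) {
  if (!is_count(n_good) || !is_count(n_bad)) stop("need n_good, n_bad >= 1")
  if (!is_count(n_fractions, 2L)) stop("n_fractions must be >= 2")
  planted <- as.data.frame(planted)
  if (nrow(planted) > n_features)
    stop("n_features must cover the planted features")
  fnames <- c(planted$feature,
              sprintf("noise%02d", seq_len(n_features - nrow(planted))))
  ids <- sprintf("P%03d", seq_len(n_good + n_bad))
  labels <- setNames(rep(c("good", "bad"), c(n_good, n_bad)), ids)
  fracs <- 2:n_fractions

  with_seed(seed, {
    motion <- scanner <- character(0)
    for (g in c("good", "bad")) {
      gi <- ids[labels == g]
      motion <- c(motion, assign_nuisance(gi, motion_fraction,
                                          c("low", "high")))
      scanner <- c(scanner, assign_nuisance(gi, scanner_fraction,
                                            c("A", "B")))
    }
    motion <- motion[ids]; scanner <- scanner[ids]

    drf <- data.frame(patient = rep(ids, each = length(fracs)),
                      fraction = rep(fracs, length(ids)),
                      stringsAsFactors = FALSE)
    for (f in fnames) {
      pi_ <- match(f, planted$feature)
      u <- setNames(rnorm(length(ids), 0, patient_sd), ids)
      v <- numeric(nrow(drf))
      for (id in ids) {
        i <- drf$patient == id
        n <- drf$fraction[i]
        sdn <- if (f %in% motion_affected && motion[[id]] == "high")
          noise_sd * motion_sd_mult else noise_sd
        if (!is.na(pi_)) {
          sl <- if (labels[[id]] == "good") planted$slope_good[pi_] else
            planted$slope_bad[pi_]
          v[i] <- planted$offset[pi_] + sl * n + u[[id]] +
            rnorm(length(n), 0, sdn)
        } else {
          v[i] <- u[[id]] + rnorm(length(n), 0, max(null_sd, sdn - noise_sd + null_sd))
        }
        if (f %in% scanner_affected && scanner[[id]] == "B")
          v[i] <- v[i] + scanner_offset
      }
      drf[[f]] <- v
    }
    t <- weekly_drf(new_drf_table(drf))
    structure(list(drf = t, labels = labels, motion = motion,
                   scanner = scanner,
                   truth = list(n_good = n_good, n_bad = n_bad,
                                n_fractions = n_fractions,
                                planted = planted,
                                patient_sd = patient_sd,
                                noise_sd = noise_sd, null_sd = null_sd,
                                seed = seed)),
              class = "synthetic_drf_cohort")
  })
}

#' @export
print.synthetic_drf_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_drf_cohort> %d good / %d bad patients, %d fractions, %d features (%d planted)\n",
              x$truth$n_good, x$truth$n_bad, x$truth$n_fractions,
              length(x$drf$features), nrow(x$truth$planted)))
  invisible(x)
}

#' Weekly samples table for classification
#'
#' Extracts the weekly DRF aggregates of selected weeks as a samples
#' table (one row per patient and week, column `patient` plus features) —
#' the representation consumed by [loo_cv()], [bootstrap_ensemble()] and
#' [combo_search()].
#'
#' @param t A `drf_table` (weekly slot required) or a
#'   `synthetic_drf_cohort`.
#' @param weeks Weeks to keep (default 2:4).
#' @param features Feature subset (default all).
#' @return Data frame `patient`, features.
#' @export
weekly_samples <- function(t, weeks = 2:4, features = NULL) {
  if (inherits(t, "synthetic_drf_cohort")) t <- t$drf
  stopifnot(inherits(t, "drf_table"))
  if (is.null(t$weekly)) t <- weekly_drf(t)
  features <- features %||% t$features
  w <- t$weekly[t$weekly$week %in% weeks, c("patient", features),
                drop = FALSE]
  rownames(w) <- NULL
  w
}

#' Bayes-optimal AUC of the planted weekly score distributions
#'
#' From the generator truth, the class-conditional distribution of a
#' weekly DRF vector is an equal-weight mixture over the selected weeks
#' of independent Gaussians (week-k mean `offset + slope_g * nbar_k`
#' with `nbar_k` the mean usable fraction index of the week; variance
#' `patient_sd^2 + noise_sd^2 / m_k` with `m_k` fractions in the week).
#' The optimal score is the class likelihood ratio of these mixtures;
#' its AUC is evaluated by a large seeded Monte-Carlo draw from the truth
#' distributions — no fitted model is involved, so it serves as the
#' ceiling against which cross-validated classifier AUCs are judged.
#'
#' @param truth The `truth` element of a [simulate_drf_cohort()] result.
#' @param features Planted features to use (default all planted).
#' @param weeks Weeks included (default 2:4).
#' @param n_mc Monte-Carlo draws per class.
#' @param seed Seed for the draw.
#' @return AUC in `[0, 1]`.
#' @export
bayes_optimal_auc <- function(truth, features = NULL, weeks = 2:4,
                              n_mc = 2e5, seed = 1L) {
  pl <- truth$planted
  features <- features %||% pl$feature
  pl <- pl[match(features, pl$feature), , drop = FALSE]
  if (anyNA(pl$feature)) stop("all 'features' must be planted")
  nf <- max(truth$n_fractions, 2L)
  wk_fr <- lapply(weeks, function(w) {
    fr <- (5 * (w - 1) + 1):(5 * w)
    fr[fr >= 2 & fr <= nf]
  })
  wk_fr <- wk_fr[lengths(wk_fr) > 0]
  nbar <- vapply(wk_fr, mean, 0)
  mfr <- lengths(wk_fr)
  sds <- sqrt(truth$patient_sd^2 + outer(truth$noise_sd^2 / mfr,
                                         rep(1, nrow(pl))))
  mu_g <- outer(nbar, pl$slope_good) + rep(pl$offset, each = length(nbar))
  mu_b <- outer(nbar, pl$slope_bad) + rep(pl$offset, each = length(nbar))

  mix_logdens <- function(X, MU) {
    ## log of equal-weight mixture over weeks of independent Gaussians
    lw <- sapply(seq_along(nbar), function(k) {
      rowSums(dnorm(X, rep(MU[k, ], each = nrow(X)),
                    rep(sds[k, ], each = nrow(X)), log = TRUE))
    })
    mx <- apply(lw, 1, max)
    mx + log(rowMeans(exp(lw - mx)))
  }
  draw <- function(MU, n) {
    k <- sample.int(length(nbar), n, replace = TRUE)
    matrix(rnorm(n * nrow(pl), as.vector(MU[k, ]),
                 as.vector(sds[k, ])), n)
  }
  with_seed(seed, {
    Xg <- draw(mu_g, n_mc); Xb <- draw(mu_b, n_mc)
    sg <- mix_logdens(Xg, mu_g) - mix_logdens(Xg, mu_b)
    sb <- mix_logdens(Xb, mu_g) - mix_logdens(Xb, mu_b)
    auc_mw(c(sg, sb), rep(c("good", "bad"), each = n_mc))
  })
}
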