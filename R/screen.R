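## long (patient x fraction) x feature matrix from a drf_table
drf_matrix <- function(t, features = t$features) {
  as.matrix(t$drf[, features, drop = FALSE])
}

#' Spearman redundancy filter
#'
#' Computes pairwise Spearman rank correlations of the DRFs over all
#' (patient, fraction) rows and greedily clusters features whose absolute
#' correlation exceeds `threshold`, keeping one representative per
#' cluster: the member with the largest variance across rows, with ties
#' broken alphabetically. Constant features (undefined correlation) are
#' excluded with a warning.
#'
#' @param t A `drf_table`.
#' @param threshold Absolute Spearman correlation above which two features
#'   are considered redundant (default 0.9).
#' @return List with `kept` (character), `cluster` (named integer: cluster
#'   id per feature, `NA` for constant features) and `rho` (correlation
#'   matrix).
#' @export
spearman_filter <- function(t, threshold = 0.9) {
  stopifnot(inherits(t, "drf_table"))
  M <- drf_matrix(t)
  if (ncol(M) < 2L) stop("need at least 2 features")
  if (nrow(M) < 3L) stop("need at least 3 observations")
  vs <- apply(M, 2, function(v) var(v[is.finite(v)]))
  const <- !is.finite(vs) | vs == 0
  if (any(const)) {
    warning("constant feature(s) excluded from Spearman filter: ",
            paste(colnames(M)[const], collapse = ", "))
  }
  feats <- colnames(M)[!const]
  rho <- suppressWarnings(
    cor(M[, feats, drop = FALSE], method = "spearman",
        use = "pairwise.complete.obs"))
  ## greedy clustering in decreasing-variance order (name breaks ties)
  ord <- feats[order(-vs[feats], feats)]
  cluster <- setNames(rep(NA_integer_, ncol(M)), colnames(M))
  cid <- 0L
  for (f in ord) {
    if (!is.na(cluster[f])) next
    cid <- cid + 1L
    cluster[f] <- cid
    mates <- feats[is.na(cluster[feats]) &
                     abs(rho[f, feats]) > threshold]
    cluster[mates] <- cid
  }
  reps <- vapply(seq_len(cid), function(k) {
    members <- names(cluster)[!is.na(cluster) & cluster == k]
    members[order(-vs[members], members)][1]
  }, "")
  list(kept = sort(reps), cluster = cluster, rho = rho)
}

## COV (sd / |mean|) of a vector, NA when the mean is numerically zero
cov_of <- function(v) {
  v <- v[is.finite(v)]
  m <- mean(v)
  if (abs(m) < 1e-12 * max(sd(v), 1e-300)) return(NA_real_)
  sd(v) / abs(m)
}

#' Motion robustness: COV comparison, MSLR and t test
#'
#' Grades each DRF's sensitivity to respiratory motion by comparing its
#' values between the low- and high-motion patient groups: the difference
#' in coefficient of variation, the modified signed likelihood-ratio test
#' for equality of CVs, and a Welch t test. The t test compares
#' per-patient mean DRFs (the patient is the independent unit; testing
#' pooled fraction-level values would treat correlated repeats as
#' independent and over-reject). A feature
#' is motion-robust when the COV difference is below `cov_limit` (default
#' 5 percentage points) and neither test is significant at `alpha`.
#' Features whose group mean is numerically zero have no usable COV and
#' are marked not robust.
#'
#' @param t A `drf_table`.
#' @param motion Named vector mapping patient to `"low"`/`"high"`.
#' @param alpha Significance level.
#' @param cov_limit Allowed |COV difference|.
#' @param nr,seed Passed to [mslr_cov_test()] (per-feature sub-seeds are
#'   derived from `seed`).
#' @return Data frame, one row per feature: `cov_low`, `cov_high`,
#'   `cov_delta`, `mslr_p`, `motion_ttest_p`, `motion_robust`.
#' @export
cov_mslr <- function(t, motion, alpha = 0.05, cov_limit = 0.05,
                     nr = 200L, seed = 1L) {
  stopifnot(inherits(t, "drf_table"))
  g <- motion[as.character(t$drf$patient)]
  if (!all(c("low", "high") %in% g))
    stop("both motion groups must be present")
  out <- lapply(seq_along(t$features), function(k) {
    f <- t$features[k]
    v <- t$drf[[f]]
    lo <- v[g == "low"]; hi <- v[g == "high"]
    cl <- cov_of(lo); ch <- cov_of(hi)
    ms <- tryCatch(
      mslr_cov_test(lo, hi, nr = nr, seed = derive_seed(seed, k)),
      error = function(e) NULL)
    pm <- tapply(v, t$drf$patient, function(z) mean(z[is.finite(z)]))
    gm <- motion[names(pm)]
    tt <- tryCatch(t.test(pm[gm == "low"], pm[gm == "high"])$p.value,
                   error = function(e) NA_real_)
    delta <- abs(ch - cl)
    robust <- is.finite(delta) && delta < cov_limit &&
      !is.null(ms) && ms$p.value >= alpha &&
      is.finite(tt) && tt >= alpha
    data.frame(feature = f, cov_low = cl, cov_high = ch, cov_delta = delta,
               mslr_p = if (is.null(ms)) NA_real_ else ms$p.value,
               motion_ttest_p = tt, motion_robust = robust,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Scanner (acquisition-protocol) effect screen
#'
#' Per feature, a Welch t test between the two scanners within each
#' response stratum, plus a linear regression of the DRF on the scanner
#' indicator adjusted for response; both operate on per-patient mean DRFs
#' (the scanner is a patient-level factor, so patients are the
#' independent replicates). The stratified t-test p-value is the
#' Bonferroni-corrected minimum over the strata, so the combined gate
#' holds its nominal level. A feature is scanner-robust when neither that
#' combined p nor the regression coefficient is significant at `alpha`.
#' With balanced response groups the scanner regression coefficient
#' equals the difference of adjusted scanner means.
#'
#' @param t A `drf_table`.
#' @param scanner Named vector mapping patient to `"A"`/`"B"`.
#' @param labels Named vector mapping patient to `"good"`/`"bad"`.
#' @param alpha Significance level.
#' @return Data frame: `scanner_ttest_p` (minimum over strata),
#'   `scanner_reg_p`, `scanner_robust`.
#' @export
scanner_effect <- function(t, scanner, labels, alpha = 0.05) {
  stopifnot(inherits(t, "drf_table"))
  if (length(unique(scanner[as.character(t$drf$patient)])) != 2L)
    stop("need exactly two scanners")
  out <- lapply(t$features, function(f) {
    v <- t$drf[[f]]
    pm <- tapply(v, t$drf$patient, function(z) mean(z[is.finite(z)]))
    sc <- factor(scanner[names(pm)])
    lb <- factor(labels[names(pm)])
    tps <- vapply(levels(lb), function(s) {
      i <- lb == s
      if (length(unique(sc[i])) < 2L) return(NA_real_)
      tryCatch(t.test(pm[i] ~ sc[i])$p.value, error = function(e) NA_real_)
    }, 0)
    rp <- tryCatch({
      fit <- lm(pm ~ sc + lb)
      summary(fit)$coefficients[2, 4]
    }, error = function(e) NA_real_)
    ## Bonferroni over strata keeps the combined test at level alpha
    nok <- sum(is.finite(tps))
    tmin <- if (nok > 0) min(1, nok * min(tps, na.rm = TRUE)) else NA_real_
    robust <- is.finite(tmin) && tmin >= alpha &&
      is.finite(rp) && rp >= alpha
    data.frame(feature = f, scanner_ttest_p = tmin, scanner_reg_p = rp,
               scanner_robust = robust, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Group-difference t tests over the treatment course
#'
#' Per feature: (a) the overall Welch t test of per-patient mean DRFs
#' between the response groups; (b) descriptive per-fraction and per-week
#' t tests of the values at each time point, with the longest run of
#' consecutive significant fractions reported (sustained separation over
#' several consecutive fractions is the pattern of interest for early
#' response assessment).
#'
#' @param t A `drf_table` (weekly slot used if present).
#' @param labels Named vector patient -> `"good"`/`"bad"`.
#' @param alpha Significance level for the run count.
#' @return List with `overall` (data frame `feature`, `ttest_overall_p`,
#'   `max_sig_run`), `per_fraction` and `per_week` (matrices of p-values,
#'   features x time points).
#' @export
group_ttests <- function(t, labels, alpha = 0.05) {
  stopifnot(inherits(t, "drf_table"))
  lb <- factor(labels[as.character(t$drf$patient)])
  if (nlevels(lb) != 2L) stop("need exactly two response groups")
  fracs <- sort(unique(t$drf$fraction))
  pf <- matrix(NA_real_, length(t$features), length(fracs),
               dimnames = list(t$features, fracs))
  overall <- lapply(t$features, function(f) {
    v <- t$drf[[f]]
    pm <- tapply(v, t$drf$patient, function(z) mean(z[is.finite(z)]))
    gl <- factor(labels[names(pm)])
    po <- tryCatch(t.test(pm ~ gl)$p.value, error = function(e) NA_real_)
    for (j in seq_along(fracs)) {
      i <- t$drf$fraction == fracs[j]
      pf[f, j] <<- tryCatch(t.test(v[i] ~ lb[i])$p.value,
                            error = function(e) NA_real_)
    }
    sig <- is.finite(pf[f, ]) & pf[f, ] < alpha
    runs <- rle(sig)
    mr <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
    data.frame(feature = f, ttest_overall_p = po, max_sig_run = mr,
               stringsAsFactors = FALSE)
  })
  pw <- NULL
  if (!is.null(t$weekly)) {
    weeks <- sort(unique(t$weekly$week))
    lw <- factor(labels[as.character(t$weekly$patient)])
    pw <- matrix(NA_real_, length(t$features), length(weeks),
                 dimnames = list(t$features, weeks))
    for (f in t$features) for (j in seq_along(weeks)) {
      i <- t$weekly$week == weeks[j]
      pw[f, j] <- tryCatch(t.test(t$weekly[[f]][i] ~ lw[i])$p.value,
                           error = function(e) NA_real_)
    }
  }
  list(overall = do.call(rbind, overall), per_fraction = pf, per_week = pw)
}

#' Trend regression: does the DRF drift differently per response group?
#'
#' Per feature, ordinary least squares of the DRF on the fraction index
#' within each response group, and a pooled model with a group-by-fraction
#' interaction; `trend_p` is the interaction p-value, i.e. the evidence
#' that the temporal drift differs between good and bad responders.
#'
#' @param t A `drf_table`.
#' @param labels Named vector patient -> response group.
#' @return Data frame: `slope_good`, `slope_bad`, `trend_p`.
#' @export
trend_regression <- function(t, labels) {
  stopifnot(inherits(t, "drf_table"))
  lb <- factor(labels[as.character(t$drf$patient)])
  fr <- t$drf$fraction
  if (length(unique(fr)) < 3L) stop("need at least 3 fractions")
  out <- lapply(t$features, function(f) {
    v <- t$drf[[f]]
    ok <- is.finite(v)
    slopes <- vapply(levels(lb), function(s) {
      i <- ok & lb == s
      if (sum(i) < 3L) return(NA_real_)
      coef(lm(v[i] ~ fr[i]))[2]
    }, 0)
    p <- tryCatch({
      fit <- lm(v[ok] ~ lb[ok] * fr[ok])
      cf <- summary(fit)$coefficients
      cf[nrow(cf), 4]
    }, error = function(e) NA_real_)
    gi <- which(levels(lb) == "good")
    bi <- which(levels(lb) == "bad")
    data.frame(feature = f,
               slope_good = if (length(gi)) slopes[gi] else slopes[1],
               slope_bad = if (length(bi)) slopes[bi] else slopes[2],
               trend_p = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Mixed-model likelihood-ratio screen over all features
#'
#' Runs [lmm_response_lrt()] per feature.
#'
#' @param t A `drf_table`.
#' @param labels Named vector patient -> response group.
#' @return Data frame: `lrt_stat`, `lrt_p`, `lmm_converged`.
#' @export
mixed_model_lrt <- function(t, labels) {
  stopifnot(inherits(t, "drf_table"))
  lb <- labels[as.character(t$drf$patient)]
  out <- lapply(t$features, function(f) {
    res <- tryCatch(
      lmm_response_lrt(t$drf[[f]], lb, t$drf$patient, t$drf$fraction),
      error = function(e) NULL)
    data.frame(feature = f,
               lrt_stat = if (is.null(res)) NA_real_ else res$lrt_stat,
               lrt_p = if (is.null(res)) NA_real_ else res$p.value,
               lmm_converged = !is.null(res) && res$fit_full$converged,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Run the full DRF screening cascade
#'
#' Chains the redundancy filter, motion and scanner robustness screens,
#' overall and per-time-point group t tests, trend regression and the
#' mixed-model likelihood-ratio test into one per-feature report, and
#' flags candidate features: kept by the Spearman filter, robust to motion
#' and scanner (when that information is supplied), with a significant
#' group-by-fraction trend, overall t test and mixed-model LRT at `alpha`.
#' No multiple-testing correction is applied by default; set
#' `adjust = "BH"` for Benjamini-Hochberg adjustment of the three
#' candidate-gating p-values.
#'
#' @param t A `drf_table` (weekly aggregates are computed if absent).
#' @param labels Named vector patient -> `"good"`/`"bad"`.
#' @param motion Optional named vector patient -> `"low"`/`"high"`.
#' @param scanner Optional named vector patient -> `"A"`/`"B"`.
#' @param alpha Significance level for every gate (default 0.05).
#' @param spearman_threshold Redundancy threshold.
#' @param mslr_nr Null simulations for the MSLR test.
#' @param seed Seed for the MSLR simulations.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Object of class `drf_screen`: list with `report` (per-feature
#'   data frame), `per_fraction_p`, `per_week_p`, `alpha`, `candidates`.
#' @export
drf_screen <- function(t, labels, motion = NULL, scanner = NULL,
                       alpha = 0.05, spearman_threshold = 0.9,
                       mslr_nr = 200L, seed = 1L,
                       adjust = c("none", "BH")) {
  stopifnot(inherits(t, "drf_table"))
  adjust <- match.arg(adjust)
  if (is.null(t$weekly)) t <- weekly_drf(t)
  sp <- spearman_filter(t, threshold = spearman_threshold)
  rep_df <- data.frame(feature = t$features, stringsAsFactors = FALSE)
  rep_df$spearman_cluster <- sp$cluster[rep_df$feature]
  rep_df$kept_after_spearman <- rep_df$feature %in% sp$kept

  if (!is.null(motion)) {
    rep_df <- merge(rep_df, cov_mslr(t, motion, alpha = alpha,
                                     nr = mslr_nr, seed = seed),
                    by = "feature", sort = FALSE)
  } else {
    rep_df$motion_robust <- TRUE
  }
  if (!is.null(scanner)) {
    rep_df <- merge(rep_df, scanner_effect(t, scanner, labels,
                                           alpha = alpha),
                    by = "feature", sort = FALSE)
  } else {
    rep_df$scanner_robust <- TRUE
  }
  gt <- group_ttests(t, labels, alpha = alpha)
  rep_df <- merge(rep_df, gt$overall, by = "feature", sort = FALSE)
  rep_df <- merge(rep_df, trend_regression(t, labels),
                  by = "feature", sort = FALSE)
  rep_df <- merge(rep_df, mixed_model_lrt(t, labels),
                  by = "feature", sort = FALSE)

  pt <- rep_df$ttest_overall_p
  pr <- rep_df$trend_p
  pl <- rep_df$lrt_p
  if (adjust == "BH") {
    pt <- p.adjust(pt, "BH"); pr <- p.adjust(pr, "BH")
    pl <- p.adjust(pl, "BH")
  }
  rep_df$candidate <- rep_df$kept_after_spearman &
    rep_df$motion_robust & rep_df$scanner_robust &
    is.finite(pr) & pr < alpha &
    is.finite(pt) & pt < alpha &
    is.finite(pl) & pl < alpha &
    rep_df$lmm_converged
  rownames(rep_df) <- NULL
  structure(list(report = rep_df, per_fraction_p = gt$per_fraction,
                 per_week_p = gt$per_week, alpha = alpha,
                 candidates = rep_df$feature[rep_df$candidate]),
            class = "drf_screen")
}

#' Candidate features of a screening report
#'
#' Re-applies the candidate gate of [drf_screen()] at a chosen `alpha`;
#' relaxing `alpha` never removes a candidate.
#'
#' @param screen A `drf_screen`.
#' @param alpha Significance level.
#' @return Character vector of candidate feature names.
#' @export
candidates <- function(screen, alpha = screen$alpha) {
  stopifnot(inherits(screen, "drf_screen"))
  r <- screen$report
  ok <- r$kept_after_spearman & r$motion_robust & r$scanner_robust &
    is.finite(r$trend_p) & r$trend_p < alpha &
    is.finite(r$ttest_overall_p) & r$ttest_overall_p < alpha &
    is.finite(r$lrt_p) & r$lrt_p < alpha & r$lmm_converged
  r$feature[ok]
}

#' @export
print.drf_screen <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    "<drf_screen> %d features; %d kept after Spearman; %d candidates (alpha = %g)\n",
    nrow(r), sum(r$kept_after_spearman), sum(r$candidate), x$alpha))
  if (length(x$candidates))
    cat("candidates:", paste(x$candidates, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.drf_screen <- function(object, ...) {
  cols <- intersect(c("feature", "kept_after_spearman", "cov_delta",
                      "mslr_p", "motion_robust", "scanner_robust",
                      "ttest_overall_p", "trend_p", "lrt_p", "candidate"),
                    names(object$report))
  object$report[, cols]
}
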