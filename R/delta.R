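#' Compute delta-radiomic features (DRFs)
#'
#' The DRF of a feature at fraction `n >= 2` is its relative change from
#' the first fraction, `(value_1 - value_n) / value_1`: a decrease from
#' baseline gives a positive DRF, and multiplying a feature's whole
#' trajectory by a nonzero constant leaves its DRFs unchanged. The DRF is
#' undefined at fraction 1 and for zero baselines; by default a zero
#' baseline drops that (patient, feature) with a warning.
#'
#' @param features Data frame with columns `patient`, `fraction`, then one
#'   numeric column per feature; every patient must have a fraction-1 row.
#' @param on_zero_baseline `"drop"` (default) or `"error"`.
#' @return Object of class `drf_table`: list with `drf` (data frame of
#'   DRFs, fractions >= 2), `baseline` (per patient), `features` (names)
#'   and `weekly` (filled by [weekly_drf()], otherwise `NULL`).
#' @examples
#' ft <- data.frame(patient = "p1", fraction = 1:3, f = c(10, 8, 9))
#' compute_drf(ft)$drf
#' @export
compute_drf <- function(features, on_zero_baseline = c("drop", "error")) {
  on_zero_baseline <- match.arg(on_zero_baseline)
  need <- c("patient", "fraction")
  if (!all(need %in% names(features)))
    stop("'features' must have columns 'patient' and 'fraction'")
  fnames <- setdiff(names(features), need)
  if (!length(fnames)) stop("no feature columns found")
  features <- features[order(features$patient, features$fraction), ,
                       drop = FALSE]
  pats <- unique(features$patient)
  base <- features[features$fraction == 1, , drop = FALSE]
  if (!all(pats %in% base$patient))
    stop("every patient needs a fraction-1 (baseline) row")
  rownames(base) <- as.character(base$patient)
  post <- features[features$fraction >= 2, , drop = FALSE]
  drf <- post
  for (f in fnames) {
    b <- base[as.character(post$patient), f]
    bad <- b == 0
    if (any(bad)) {
      msg <- sprintf("zero baseline for feature '%s' in patient(s) %s", f,
                     paste(unique(post$patient[bad]), collapse = ", "))
      if (on_zero_baseline == "error") stop(msg)
      warning(msg, "; DRF set to NA for those patients")
      b[bad] <- NA_real_
    }
    drf[[f]] <- (b - post[[f]]) / b
  }
  rownames(drf) <- NULL
  structure(list(drf = drf, baseline = base[, c("patient", fnames)],
                 features = fnames, weekly = NULL),
            class = "drf_table")
}

## construct a drf_table directly from an already-delta data frame
new_drf_table <- function(drf, baseline = NULL) {
  fnames <- setdiff(names(drf), c("patient", "fraction"))
  structure(list(drf = drf, baseline = baseline, features = fnames,
                 weekly = NULL),
            class = "drf_table")
}

#' @export
print.drf_table <- function(x, ...) {
  cat(sprintf("<drf_table> %d patients, fractions %d..%d, %d features%s\n",
              length(unique(x$drf$patient)), min(x$drf$fraction),
              max(x$drf$fraction), length(x$features),
              if (is.null(x$weekly)) "" else ", weekly aggregates present"))
  invisible(x)
}

#' Which treatment week does a fraction belong to?
#'
#' Week `k` covers fractions `5(k-1)+1 .. 5k` (five fractions per week);
#' for 28 fractions, weeks 2-4 aggregate fractions 6-10, 11-15 and 16-20.
#'
#' @param fraction Integer fraction numbers.
#' @return Integer week numbers.
#' @export
fraction_week <- function(fraction) as.integer(ceiling(fraction / 5))

#' Weekly DRF aggregation
#'
#' Fills the `weekly` slot of a [compute_drf()] table with the mean DRF
#' over each week's available fractions. Week 1 uses fractions 2-5 only
#' (the fraction-1 DRF does not exist); weeks with no available fraction
#' are absent.
#'
#' @param t A `drf_table`.
#' @return The same `drf_table` with `weekly`: data frame `patient`,
#'   `week`, then one column per feature.
#' @export
weekly_drf <- function(t) {
  stopifnot(inherits(t, "drf_table"))
  d <- t$drf
  wk <- fraction_week(d$fraction)
  agg <- aggregate(d[, t$features, drop = FALSE],
                   by = list(patient = d$patient, week = wk),
                   FUN = function(v) mean(v[is.finite(v)]))
  agg <- agg[order(agg$patient, agg$week), , drop = FALSE]
  rownames(agg) <- NULL
  t$weekly <- agg
  t
}
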