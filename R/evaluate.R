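## check a samples table: column 'patient' plus numeric feature columns
check_samples <- function(samples, combo) {
  if (!"patient" %in% names(samples))
    stop("'samples' needs a 'patient' column")
  miss <- setdiff(combo, names(samples))
  if (length(miss))
    stop("missing feature column(s): ", paste(miss, collapse = ", "))
  invisible(TRUE)
}

## majority vote over a patient's per-sample labels; ties go to `positive`
patient_vote <- function(labels, patients, positive) {
  vapply(split(labels, patients), function(ls) {
    if (sum(ls == positive) * 2 >= length(ls)) positive else
      setdiff(unique(c(ls, positive)), positive)[1]
  }, "")
}

# ROC/AUC rank by the (ensemble) network score; accuracy and the confusion
# table use the Gaussian-discriminant class decision
new_eval_result <- function(scores, truth, patients, positive, scheme) {
  roc <- roc_curve(scores$score, truth, positive)
  acc <- mean(scores$label == truth)
  pv <- patient_vote(scores$label, patients, positive)
  pt <- vapply(split(truth, patients), `[`, "", 1)
  confusion <- table(factor(pv[names(pt)], levels = unique(c(positive, pt))),
                     factor(pt, levels = unique(c(positive, pt))),
                     dnn = c("predicted", "true"))
  structure(list(auc = auc_mw(scores$score, truth, positive),
                 roc = roc$points,
                 accuracy = acc,
                 accuracy_patient = mean(pv[names(pt)] == pt),
                 confusion = confusion,
                 scores = cbind(data.frame(patient = patients,
                                           truth = truth,
                                           stringsAsFactors = FALSE),
                                scores),
                 cv_scheme = scheme, positive = positive),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> %s\n  AUC = %.3f, sample accuracy = %.3f, patient accuracy = %.3f\n",
              x$cv_scheme, x$auc, x$accuracy, x$accuracy_patient))
  if (!is.null(x$auc_ci))
    cat(sprintf("  bootstrap AUC CI: [%.3f, %.3f]\n",
                x$auc_ci[1], x$auc_ci[2]))
  invisible(x)
}

#' Leave-one-patient-out cross-validation
#'
#' For each patient, trains the classifier on every other patient's
#' samples and scores all of the held-out patient's samples (so a
#' patient's repeated measurements never appear on both sides). Scores are
#' pooled over folds into one ROC/AUC; sample-level accuracy uses the
#' Gaussian-discriminant decision and patient-level accuracy a majority
#' vote over the patient's samples (ties to the positive class).
#'
#' @param samples Data frame: column `patient` plus feature columns, one
#'   row per (patient, time point).
#' @param labels Named vector patient -> class.
#' @param combo 2-3 feature names.
#' @param seed Base seed (a per-fold seed is derived from it).
#' @param positive Positive class.
#' @param ... Passed to [train_response_classifier()].
#' @return An `eval_result` (AUC, ROC points, accuracies, confusion,
#'   pooled scores).
#' @export
loo_cv <- function(samples, labels, combo, seed = 1L, positive = "good",
                   ...) {
  check_samples(samples, combo)
  pats <- unique(samples$patient)
  if (length(unique(labels[as.character(pats)])) != 2L)
    stop("need two classes among the patients")
  all_scores <- NULL
  for (i in seq_along(pats)) {
    p <- pats[i]
    tr <- samples$patient != p
    te <- !tr
    fit <- tryCatch(
      train_response_classifier(samples[tr, , drop = FALSE],
                                labels[as.character(samples$patient[tr])],
                                combo = combo, seed = derive_seed(seed, i),
                                positive = positive, ...),
      error = function(e) NULL)
    if (is.null(fit)) next
    sc <- predict(fit, samples[te, , drop = FALSE])
    sc$patient <- samples$patient[te]
    all_scores <- rbind(all_scores, sc)
  }
  if (is.null(all_scores)) stop("no fold produced scores")
  truth <- labels[as.character(all_scores$patient)]
  new_eval_result(all_scores[, c("score", "posterior", "label")],
                  unname(truth), all_scores$patient, positive,
                  "leave-one-patient-out CV")
}

#' Bootstrap-ensemble training and external evaluation
#'
#' Draws `nboot` patient-level bootstrap resamples of the training
#' cohort, trains one classifier per resample, and scores the disjoint
#' test cohort with the ensemble mean of the per-model posteriors. The
#' reported AUC is that of the ensemble score; the confidence interval is
#' the 2.5/97.5 percentile (order statistics) of the `nboot` per-model
#' test AUCs. Resamples missing a class are redrawn (bounded retries).
#'
#' @param train,test Samples tables (disjoint patients).
#' @param labels Named vector patient -> class covering both cohorts.
#' @param combo 2-3 feature names.
#' @param nboot Number of bootstrap models (default 100).
#' @param seed Base seed.
#' @param positive Positive class.
#' @param ... Passed to [train_response_classifier()].
#' @return An `eval_result` with extra elements `auc_ci` and
#'   `boot_aucs`.
#' @export
bootstrap_ensemble <- function(train, test, labels, combo, nboot = 100L,
                               seed = 1L, positive = "good", ...) {
  check_samples(train, combo); check_samples(test, combo)
  tr_pats <- unique(train$patient)
  if (length(intersect(tr_pats, unique(test$patient))))
    stop("train and test patients must be disjoint")
  post <- matrix(NA_real_, nrow(test), nboot)
  smat <- matrix(NA_real_, nrow(test), nboot)
  aucs <- numeric(nboot)
  test_truth <- unname(labels[as.character(test$patient)])
  b <- 1L
  draws <- 0L
  while (b <= nboot) {
    draws <- draws + 1L
    if (draws > 20L * nboot) stop("could not draw class-complete resamples")
    idx <- with_seed(derive_seed(seed, draws),
                     sample(length(tr_pats), replace = TRUE))
    bp <- tr_pats[idx]
    if (length(unique(labels[as.character(bp)])) < 2L) next
    rows <- unlist(lapply(bp, function(p) which(train$patient == p)))
    fit <- tryCatch(
      train_response_classifier(train[rows, , drop = FALSE],
                                labels[as.character(train$patient[rows])],
                                combo = combo, seed = derive_seed(seed, b),
                                positive = positive, ...),
      error = function(e) NULL)
    if (is.null(fit)) next
    sc <- predict(fit, test)
    post[, b] <- sc$posterior
    smat[, b] <- sc$score
    aucs[b] <- auc_mw(sc$score, test_truth, positive)
    b <- b + 1L
  }
  ens <- rowMeans(smat)        # ensemble-mean network output
  ensp <- rowMeans(post)
  neg <- setdiff(unique(test_truth), positive)
  lab <- ifelse(ensp >= 0.5, positive, neg)
  res <- new_eval_result(
    data.frame(score = ens, posterior = ensp, label = lab,
               stringsAsFactors = FALSE),
    test_truth, test$patient, positive,
    sprintf("bootstrap ensemble (nboot = %d) on external test set", nboot))
  sa <- sort(aucs)
  res$auc_ci <- c(sa[max(1L, ceiling(0.025 * nboot))],
                  sa[ceiling(0.975 * nboot)])
  res$boot_aucs <- aucs
  res
}

#' Exhaustive 2- and 3-feature combination search
#'
#' Evaluates every 2- and 3-feature combination of the candidate features
#' by leave-one-patient-out CV and ranks them by CV-AUC (ties broken by
#' name for determinism).
#'
#' @param samples Samples table.
#' @param labels Named vector patient -> class.
#' @param features Candidate feature names (>= 2).
#' @param sizes Combination sizes (default `c(2, 3)`).
#' @param seed Base seed.
#' @param positive Positive class.
#' @param ... Passed to [loo_cv()].
#' @return Data frame `combo`, `n_features`, `auc`, `accuracy`, sorted by
#'   decreasing AUC, with the per-combo `eval_result`s in
#'   `attr(, "results")`.
#' @export
combo_search <- function(samples, labels, features, sizes = c(2L, 3L),
                         seed = 1L, positive = "good", ...) {
  if (length(features) < 2L) stop("need at least 2 candidate features")
  sizes <- sizes[sizes <= length(features)]
  combos <- unlist(lapply(sizes, function(s)
    utils::combn(sort(features), s, simplify = FALSE)), recursive = FALSE)
  results <- vector("list", length(combos))
  rows <- lapply(seq_along(combos), function(ci) {
    cb <- combos[[ci]]
    ev <- loo_cv(samples, labels, cb, seed = derive_seed(seed, ci),
                 positive = positive, ...)
    results[[ci]] <<- ev
    data.frame(combo = paste(cb, collapse = "+"),
               n_features = length(cb), auc = ev$auc,
               accuracy = ev$accuracy, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  ord <- order(-tab$auc, tab$combo)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "results") <- results[ord]
  tab
}
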