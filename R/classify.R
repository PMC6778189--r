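#' Fit per-class Gaussian models
#'
#' For each class: the sample mean vector, sample covariance matrix and
#' prior (class frequency). Near-singular covariances (condition number
#' above `cond_limit`) receive a ridge `eps * trace(c)/d` on the diagonal,
#' logged via a message.
#'
#' @param X Numeric matrix of observations.
#' @param y Class labels (2 classes); the first level/class listed in
#'   `classes` wins deterministic tie-breaks downstream.
#' @param classes Optional class ordering (default: unique labels).
#' @param eps Ridge scale.
#' @param cond_limit Condition-number threshold triggering the ridge.
#' @return Object of class `class_models`: list with `classes`, `mean`,
#'   `cov`, `prior`.
#' @export
fit_class_models <- function(X, y, classes = NULL, eps = 1e-6,
                             cond_limit = 1e10) {
  X <- as.matrix(X)
  y <- as.character(y)
  classes <- classes %||% unique(y)
  if (length(classes) != 2L) stop("exactly two classes expected")
  d <- ncol(X)
  mods <- lapply(classes, function(cl) {
    Xi <- X[y == cl, , drop = FALSE]
    if (nrow(Xi) <= d)
      stop(sprintf("class '%s' needs more than %d samples", cl, d))
    m <- colMeans(Xi)
    C <- cov(Xi)
    if (!is.finite(rcond(C)) || rcond(C) < 1 / cond_limit) {
      ridge <- eps * sum(diag(C)) / d
      message(sprintf("ridging near-singular covariance of class '%s' (+%g I)",
                      cl, ridge))
      C <- C + diag(ridge, d)
    }
    if (rcond(C) < 1e-15) stop("covariance singular even after ridging")
    list(mean = m, cov = C)
  })
  names(mods) <- classes
  prior <- vapply(classes, function(cl) mean(y == cl), 0)
  structure(list(classes = classes,
                 mean = lapply(mods, `[[`, "mean"),
                 cov = lapply(mods, `[[`, "cov"),
                 prior = prior, d = d),
            class = "class_models")
}

#' Squared Mahalanobis distance to a class centroid
#'
#' `D^2 = (t - m)' c^-1 (t - m)`: the covariance acts as a metric that
#' stretches the space, so distance is measured in units of class spread.
#' With an identity covariance it reduces to squared Euclidean distance.
#'
#' @param t Numeric vector or matrix of points (rows).
#' @param m Class mean vector.
#' @param c Class covariance matrix (positive definite).
#' @return Numeric vector of squared distances.
#' @export
maha_dist2 <- function(t, m, c) {
  T <- if (is.matrix(t)) t else matrix(t, nrow = 1)
  if (ncol(T) != length(m)) stop("dimension mismatch")
  U <- tryCatch(chol(c), error = function(e)
    stop("covariance matrix is not positive definite"))
  dev <- sweep(T, 2, m)
  z <- backsolve(U, t(dev), transpose = TRUE)
  colSums(z^2)
}

#' Gaussian-discriminant classification
#'
#' Evaluates `g_j(t) = log p(w_j) - 1/2 log |c_j| - 1/2 D_j^2` for each
#' class (the log of the multivariate-normal class density times the
#' prior), assigns the class with the largest discriminant (equivalently,
#' with equal priors and covariances, the minimum Mahalanobis distance to
#' the class centroid) and returns posteriors from the normalized
#' exponentials. Exact ties go deterministically to the first class.
#'
#' @param t Numeric vector or matrix of points (rows).
#' @param models A [fit_class_models()] result.
#' @return List with `label` (character), `posterior` (matrix, one column
#'   per class), `discriminant` (same shape), `d2` (squared Mahalanobis
#'   distances).
#' @export
classify_bayes <- function(t, models) {
  stopifnot(inherits(models, "class_models"))
  T <- if (is.matrix(t)) t else matrix(t, nrow = 1, byrow = TRUE)
  g <- sapply(models$classes, function(cl) {
    C <- models$cov[[cl]]
    ld <- 2 * sum(log(diag(chol(C))))
    log(models$prior[[cl]]) - 0.5 * ld -
      0.5 * maha_dist2(T, models$mean[[cl]], C)
  })
  g <- matrix(g, nrow = nrow(T), dimnames = list(NULL, models$classes))
  d2 <- sapply(models$classes, function(cl)
    maha_dist2(T, models$mean[[cl]], models$cov[[cl]]))
  d2 <- matrix(d2, nrow = nrow(T), dimnames = list(NULL, models$classes))
  mx <- apply(g, 1, max)
  post <- exp(g - mx)
  post <- post / rowSums(post)
  ## argmax with deterministic tie-break to the first listed class
  lab <- models$classes[max.col(g, ties.method = "first")]
  list(label = lab, posterior = post, discriminant = g, d2 = d2)
}

#' Train the response classifier (BNN + Mahalanobis discriminant)
#'
#' Trains a Bayesian-regularized network on the selected DRF combination,
#' then fits per-class Gaussian models in the augmented space of the
#' inputs joined with the network output, so that test points are
#' classified by the Gaussian discriminant (minimum Mahalanobis distance
#' corrected for priors and covariance volume) with the learned network
#' score in play. `space = "input"` fits the class models on the raw
#' inputs instead.
#'
#' @param x Data frame or matrix of DRF values.
#' @param labels Class labels aligned with the rows of `x`.
#' @param combo Feature columns to use (2 or 3).
#' @param seed Seed for the network initialization.
#' @param space `"augmented"` (default) or `"input"`.
#' @param positive Positive class (mapped to +1; also the ROC direction).
#' @param ... Passed to [bnn_train()].
#' @return Object of class `drf_classifier`.
#' @export
train_response_classifier <- function(x, labels, combo = NULL, seed = 1L,
                                      space = c("augmented", "input"),
                                      positive = "good", ...) {
  space <- match.arg(space)
  X <- as.matrix(as.data.frame(x)[, combo %||% colnames(x), drop = FALSE])
  if (ncol(X) < 2L || ncol(X) > 3L)
    stop("the classifier uses 2 or 3 input features")
  labels <- as.character(labels)
  classes <- c(positive, setdiff(unique(labels), positive))
  net <- bnn_train(X, labels, seed = seed, positive = positive, ...)
  s <- predict(net, X)
  S <- if (space == "augmented") cbind(X, bnn_score = s) else X
  cm <- fit_class_models(S, labels, classes = classes)
  structure(list(net = net, class_models = cm, combo = colnames(X),
                 space = space, positive = positive),
            class = "drf_classifier")
}

#' @export
print.drf_classifier <- function(x, ...) {
  cat(sprintf("<drf_classifier> features: %s; %s-space Gaussian discriminant\n",
              paste(x$combo, collapse = ", "), x$space))
  print(x$net)
  invisible(x)
}

#' Predict response class and posterior
#'
#' @param object A `drf_classifier`.
#' @param newdata Data frame or matrix containing the training columns.
#' @param ... Unused.
#' @return Data frame with `score` (network output), `posterior`
#'   (probability of the positive class) and `label`.
#' @export
predict.drf_classifier <- function(object, newdata, ...) {
  X <- as.matrix(as.data.frame(newdata)[, object$combo, drop = FALSE])
  s <- predict(object$net, X)
  S <- if (object$space == "augmented") cbind(X, bnn_score = s) else X
  cb <- classify_bayes(S, object$class_models)
  data.frame(score = s,
             posterior = cb$posterior[, object$positive],
             label = cb$label, stringsAsFactors = FALSE)
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' `P(score_pos > score_neg)` with the average-rank treatment of ties —
#' the Mann-Whitney U statistic scaled to `[0, 1]`, identical to the
#' trapezoidal area under the empirical ROC curve.
#'
#' @param scores Numeric scores, larger meaning "more positive".
#' @param truth Labels.
#' @param positive Positive label.
#' @return AUC in `[0, 1]`.
#' @export
auc_mw <- function(scores, truth, positive = "good") {
  pos <- as.character(truth) == positive
  np <- sum(pos); nn <- sum(!pos)
  if (np == 0L || nn == 0L) stop("both classes needed for AUC")
  r <- rank(scores)
  (sum(r[pos]) - as.numeric(np) * (np + 1) / 2) /
    (as.numeric(np) * as.numeric(nn))
}

#' Empirical ROC curve and trapezoidal AUC
#'
#' @inheritParams auc_mw
#' @return List with `points` (data frame `threshold`, `fpr`, `tpr`) and
#'   `auc` (trapezoidal area).
#' @export
roc_curve <- function(scores, truth, positive = "good") {
  pos <- as.character(truth) == positive
  np <- sum(pos); nn <- sum(!pos)
  if (np == 0L || nn == 0L) stop("both classes needed for ROC")
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(th, function(t) sum(scores[pos] >= t) / np, 0)
  fpr <- vapply(th, function(t) sum(scores[!pos] >= t) / nn, 0)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(points = data.frame(threshold = th, fpr = fpr, tpr = tpr), auc = auc)
}
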