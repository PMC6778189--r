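#' Train a Bayesian-regularization neural network
#'
#' A small feedforward network (2-3 standardized inputs, `hidden` tanh
#' units, one linear output) trained on +/-1 targets by minimizing
#' `F = beta * E_D + alpha * E_W`, with `E_D = 1/2 sum (out - y)^2` and
#' `E_W = 1/2 sum w^2`, using damped Gauss-Newton (Levenberg-Marquardt)
#' steps. After each inner convergence the regularization is re-estimated
#' by the evidence framework: with `k` weights and Hessian
#' `H = beta J'J + alpha I`, the effective number of parameters is
#' `gamma = k - alpha * tr(H^-1)`, and `alpha <- gamma / (2 E_W)`,
#' `beta <- (n - gamma) / (2 E_D)`. This shrinks weights automatically,
#' trading data fit against network complexity without a validation set.
#' Deterministic given `seed` (weight initialization).
#'
#' @param x Numeric input matrix (n x d, d of 2 or 3 typical).
#' @param y Targets: numeric +/-1, or a factor/character whose `positive`
#'   level maps to +1.
#' @param hidden Hidden units (default 3).
#' @param seed Seed for the weight initialization.
#' @param positive Label mapped to +1 when `y` is not numeric.
#' @param alpha,beta Fix the penalty/noise precisions instead of evidence
#'   re-estimation (mainly for studying limiting behavior).
#' @param max_outer Evidence re-estimation rounds.
#' @param max_inner Levenberg-Marquardt iterations per round.
#' @return Object of class `bnn`: weights, standardization, `alpha`,
#'   `beta`, `gamma`, training record.
#' @examples
#' X <- cbind(rnorm(40), rnorm(40)); y <- ifelse(X[, 1] > 0, 1, -1)
#' fit <- bnn_train(X, y, seed = 1)
#' cor(predict(fit, X), y) > 0
#' @export
bnn_train <- function(x, y, hidden = 3L, seed = 1L, positive = "good",
                      alpha = NULL, beta = NULL,
                      max_outer = 4L, max_inner = 60L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (!is.numeric(y)) {
    y <- ifelse(as.character(y) == positive, 1, -1)
  }
  if (!all(y %in% c(-1, 1))) stop("targets must be +/-1 (or labels)")
  if (length(unique(y)) < 2L) stop("both classes must be present")
  n <- nrow(x); d <- ncol(x); h <- as.integer(hidden)
  k <- h * d + h + h + 1L
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd); scl[scl == 0 | !is.finite(scl)] <- 1
  Xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")

  unpack <- function(w) {
    list(W1 = matrix(w[seq_len(h * d)], h, d),
         b1 = w[h * d + seq_len(h)],
         w2 = w[h * d + h + seq_len(h)],
         b2 = w[k])
  }
  forward <- function(w) {
    p <- unpack(w)
    Z <- tanh(sweep(Xs %*% t(p$W1), 2, p$b1, "+"))
    list(out = drop(Z %*% p$w2) + p$b2, Z = Z, p = p)
  }
  jac <- function(fw) {
    p <- fw$p
    dz <- 1 - fw$Z^2
    J <- matrix(0, n, k)
    for (hh in seq_len(h)) {
      base <- dz[, hh] * p$w2[hh]
      J[, (seq_len(d) - 1L) * h + hh] <- base * Xs       # W1[hh, ]
      J[, h * d + hh] <- base                            # b1
      J[, h * d + h + hh] <- fw$Z[, hh]                  # w2
    }
    J[, k] <- 1
    J
  }
  obj <- function(w, fw, a, b) {
    e <- fw$out - y
    ed <- 0.5 * sum(e^2); ew <- 0.5 * sum(w^2)
    list(F = b * ed + a * ew, ed = ed, ew = ew, e = e)
  }

  w <- with_seed(seed, runif(k, -0.5, 0.5) / sqrt(d + 1))
  a <- alpha %||% 0.01
  b <- beta %||% 1
  fixed <- !is.null(alpha) || !is.null(beta)
  iters <- 0L
  gamma <- NA_real_
  for (outer in seq_len(max_outer)) {
    lambda <- 0.005
    fw <- forward(w)
    ob <- obj(w, fw, a, b)
    for (inner in seq_len(max_inner)) {
      iters <- iters + 1L
      J <- jac(fw)
      g <- b * drop(crossprod(J, ob$e)) + a * w
      H <- b * crossprod(J) + diag(a, k)
      improved <- FALSE
      for (try in 1:25) {
        step <- tryCatch(solve(H + diag(lambda, k), -g),
                         error = function(e) NULL)
        if (!is.null(step)) {
          wn <- w + drop(step)
          fwn <- forward(wn)
          obn <- obj(wn, fwn, a, b)
          if (is.finite(obn$F) && obn$F < ob$F) { improved <- TRUE; break }
        }
        lambda <- lambda * 10
        if (lambda > 1e12) break
      }
      if (!improved) break
      conv <- (ob$F - obn$F) < 1e-10 * (1 + abs(ob$F))
      w <- wn; fw <- fwn; ob <- obn
      lambda <- max(lambda / 10, 1e-12)
      if (conv) break
    }
    J <- jac(fw)
    H <- b * crossprod(J) + diag(a, k)
    trHinv <- tryCatch(sum(diag(solve(H))), error = function(e) NA_real_)
    gamma <- if (is.finite(trHinv)) k - a * trHinv else NA_real_
    if (fixed || !is.finite(gamma)) break
    a <- min(max(gamma, 1e-3) / max(2 * ob$ew, 1e-8), 1e6)
    b <- min(max(n - gamma, 1e-3) / max(2 * ob$ed, 1e-8), 1e8)
  }
  structure(list(weights = w, hidden = h, d = d, center = ctr, scale = scl,
                 alpha = a, beta = b, gamma = gamma, e_w = ob$ew,
                 e_d = ob$ed, iterations = iters, positive = positive,
                 seed = seed),
            class = "bnn")
}

#' @export
print.bnn <- function(x, ...) {
  cat(sprintf(
    "<bnn> %d-%d-1 tanh/linear network; alpha = %.4g, beta = %.4g, gamma = %.3g eff. params (%d iterations)\n",
    x$d, x$hidden, x$alpha, x$beta, x$gamma, x$iterations))
  invisible(x)
}

#' Network output for new inputs
#'
#' @param object A `bnn`.
#' @param newdata Numeric matrix with the training columns.
#' @param ... Unused.
#' @return Numeric vector of raw network outputs (around -1..1).
#' @export
predict.bnn <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != object$d) stop("wrong number of input columns")
  Xs <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  h <- object$hidden; d <- object$d; w <- object$weights
  W1 <- matrix(w[seq_len(h * d)], h, d)
  b1 <- w[h * d + seq_len(h)]
  w2 <- w[h * d + h + seq_len(h)]
  b2 <- w[length(w)]
  Z <- tanh(sweep(Xs %*% t(W1), 2, b1, "+"))
  drop(Z %*% w2) + b2
}
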