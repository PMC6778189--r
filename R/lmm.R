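#' Gaussian linear mixed model with two crossed random intercepts
#'
#' Fits `y = X beta + u[patient] + v[fraction] + e` by maximum likelihood,
#' with independent random intercepts `u ~ N(0, sigma_u^2)` (one per
#' patient) and `v ~ N(0, sigma_v^2)` (one per fraction, shared across
#' patients, i.e. crossed with patient) and residual `e ~ N(0, sigma^2)`.
#' The likelihood is profiled over `beta` and `sigma^2`, leaving a 2-D
#' optimization over the log variance ratios, solved with multiple `nlminb`
#' starts; the linear algebra works on the (patients + fractions)-sized
#' random-effect system, so cohorts of thousands of observations fit in
#' milliseconds. ML (not REML) is used throughout so that likelihood-ratio
#' tests between models with different fixed effects are valid.
#'
#' @param y Numeric response.
#' @param X Fixed-effects design matrix (including the intercept column).
#' @param patient,fraction Grouping vectors (coerced to factor).
#' @param starts Optional list of starting values for
#'   `c(log(sigma_u^2/sigma^2), log(sigma_v^2/sigma^2))`.
#' @return List with `logLik`, `beta`, `sigma2`, `sigma2_u`, `sigma2_v`,
#'   `converged`.
#' @export
lmm_crossed_ml <- function(y, X, patient, fraction, starts = NULL) {
  X <- as.matrix(X)
  n <- length(y)
  if (nrow(X) != n) stop("nrow(X) must match length(y)")
  patient <- factor(patient); fraction <- factor(fraction)
  p <- nlevels(patient); f <- nlevels(fraction)
  if (p < 2L || f < 2L) stop("need at least 2 patients and 2 fractions")

  XtX <- crossprod(X); Xty <- drop(crossprod(X, y)); yty <- sum(y * y)
  ZuX <- rowsum(X, patient, reorder = TRUE)
  ZvX <- rowsum(X, fraction, reorder = TRUE)
  Zuy <- drop(rowsum(y, patient, reorder = TRUE))
  Zvy <- drop(rowsum(y, fraction, reorder = TRUE))
  Nuv <- unclass(table(patient, fraction))
  nu <- tabulate(as.integer(patient), p)
  nv <- tabulate(as.integer(fraction), f)
  ZtZ <- rbind(cbind(diag(nu, p), Nuv), cbind(t(Nuv), diag(nv, f)))
  ZtX <- rbind(ZuX, ZvX)
  Zty <- c(Zuy, Zvy)

  profile_fit <- function(par) {
    gu <- exp(par[1]); gv <- exp(par[2])
    A <- ZtZ
    diag(A) <- diag(A) + c(rep(1 / gu, p), rep(1 / gv, f))
    U <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(U)) return(NULL)
    M <- backsolve(U, ZtX, transpose = TRUE)
    my <- backsolve(U, Zty, transpose = TRUE)
    XtVX <- XtX - crossprod(M)
    XtVy <- Xty - drop(crossprod(M, my))
    ytVy <- yty - sum(my^2)
    beta <- tryCatch(solve(XtVX, XtVy), error = function(e) NULL)
    if (is.null(beta)) return(NULL)
    rss <- ytVy - sum(XtVy * beta)
    if (!is.finite(rss) || rss <= 0) return(NULL)
    sigma2 <- rss / n
    logdetV <- 2 * sum(log(diag(U))) + p * par[1] + f * par[2]
    list(loglik = -0.5 * (n * log(2 * pi * sigma2) + n + logdetV),
         beta = drop(beta), sigma2 = sigma2)
  }
  negll <- function(par) {
    fit <- profile_fit(par)
    if (is.null(fit)) return(1e10)
    -fit$loglik
  }

  if (is.null(starts))
    starts <- list(c(-1, -1), c(-4, -4), c(0, -5), c(-5, 0), c(-8, -8))
  best <- NULL
  conv <- FALSE
  for (st in starts) {
    op <- tryCatch(
      nlminb(st, negll, lower = c(-20, -20), upper = c(20, 20),
             control = list(iter.max = 300, eval.max = 400)),
      error = function(e) NULL)
    if (is.null(op)) next
    if (is.null(best) || op$objective < best$objective - 1e-9) {
      best <- op
      conv <- op$convergence == 0
    }
  }
  if (is.null(best)) stop("mixed-model fit failed to converge")
  fit <- profile_fit(best$par)
  gu <- exp(best$par[1]); gv <- exp(best$par[2])
  list(logLik = fit$loglik, beta = fit$beta, sigma2 = fit$sigma2,
       sigma2_u = gu * fit$sigma2, sigma2_v = gv * fit$sigma2,
       converged = conv)
}

#' Mixed-model likelihood-ratio test of a response effect on one DRF
#'
#' Fits the model `DRF ~ response + (1 | patient) + (1 | fraction)` and its
#' null without the response term, both by ML, and refers twice the
#' log-likelihood difference to chi-square(1). The patient intercept
#' absorbs patient-dependent offsets; the crossed fraction intercept
#' absorbs fraction-dependent (longitudinal) shifts shared by all
#' patients.
#'
#' @param value Numeric DRF values.
#' @param response Two-level grouping (factor or character).
#' @param patient,fraction Grouping vectors.
#' @return List with `lrt_stat`, `p.value`, `beta` (full-model fixed
#'   effects), `fit_full`, `fit_null`.
#' @export
lmm_response_lrt <- function(value, response, patient, fraction) {
  keep <- is.finite(value)
  value <- value[keep]
  response <- factor(response[keep]); patient <- patient[keep]
  fraction <- fraction[keep]
  if (nlevels(response) != 2L) stop("'response' must have exactly 2 levels")
  Xf <- cbind(1, as.integer(response) - 1L)
  Xn <- matrix(1, length(value), 1)
  full <- lmm_crossed_ml(value, Xf, patient, fraction)
  null <- lmm_crossed_ml(value, Xn, patient, fraction)
  stat <- max(0, 2 * (full$logLik - null$logLik))
  list(lrt_stat = stat,
       p.value = pchisq(stat, df = 1, lower.tail = FALSE),
       beta = full$beta, fit_full = full, fit_null = null)
}
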