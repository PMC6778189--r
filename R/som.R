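#' Per-patient DRF slopes
#'
#' Ordinary least-squares slope of each feature's DRF against the fraction
#' index, per patient: the temporal summary presented to the
#' self-organizing map. Patients with fewer than 3 usable fractions are
#' dropped with a message.
#'
#' @param t A `drf_table`.
#' @param features Feature subset (default all).
#' @return Numeric matrix, patients x features.
#' @export
drf_slopes <- function(t, features = t$features) {
  stopifnot(inherits(t, "drf_table"))
  pats <- unique(t$drf$patient)
  rows <- lapply(pats, function(p) {
    i <- t$drf$patient == p
    fr <- t$drf$fraction[i]
    if (length(fr) < 3L) return(NULL)
    vapply(features, function(f) {
      v <- t$drf[[f]][i]
      ok <- is.finite(v)
      if (sum(ok) < 3L) return(NA_real_)
      unname(coef(lm(v[ok] ~ fr[ok]))[2])
    }, 0)
  })
  drop_idx <- vapply(rows, is.null, TRUE)
  if (any(drop_idx))
    message(sum(drop_idx), " patient(s) dropped (fewer than 3 fractions)")
  out <- do.call(rbind, rows[!drop_idx])
  rownames(out) <- as.character(pats[!drop_idx])
  colnames(out) <- features
  out
}

#' Train a batch self-organizing map
#'
#' Classic batch SOM on a rectangular lattice: per epoch each input is
#' assigned its nearest (Euclidean) neuron, then every neuron's weight
#' vector moves to the neighborhood-kernel-weighted mean of the inputs won
#' by it or its lattice neighbors. A Gaussian neighborhood kernel is used,
#' with radius decaying linearly to 0 over the epochs; at radius 0 the
#' update is exactly one Lloyd k-means step. Deterministic given `seed`
#' (weights initialized from seeded draws of the input rows).
#'
#' @param X Numeric matrix of input vectors (rows).
#' @param grid `c(rows, cols)` lattice size.
#' @param epochs Batch epochs.
#' @param radius0 Initial neighborhood radius (default `max(grid)/2`).
#' @param seed Seed for the initialization.
#' @return Object of class `som_model`: `weights` (neurons x features),
#'   `grid`, `coords`, `epochs`.
#' @export
som_train <- function(X, grid = c(4L, 4L), epochs = 20L, radius0 = NULL,
                      seed = 1L) {
  X <- as.matrix(X)
  if (nrow(X) < 1L) stop("need at least one input vector")
  if (length(grid) != 2L || any(grid < 1L)) stop("'grid' must be c(rows, cols)")
  m <- prod(grid)
  coords <- as.matrix(expand.grid(row = seq_len(grid[1]),
                                  col = seq_len(grid[2])))
  D2 <- as.matrix(dist(coords))^2
  radius0 <- radius0 %||% (max(grid) / 2)
  W <- with_seed(seed, {
    idx <- sample.int(nrow(X), m, replace = TRUE)
    X[idx, , drop = FALSE] + matrix(rnorm(m * ncol(X), 0, 1e-4), m)
  })
  for (ep in seq_len(epochs)) {
    r <- if (epochs == 1L) 0 else radius0 * (epochs - ep) / (epochs - 1)
    ## squared distances inputs x neurons
    dmat <- outer(rowSums(X^2), rep(1, m)) - 2 * X %*% t(W) +
      outer(rep(1, nrow(X)), rowSums(W^2))
    win <- max.col(-dmat, ties.method = "first")
    H <- if (r > 0) exp(-D2 / (2 * r^2)) else diag(1, m)
    Hw <- H[, win, drop = FALSE]               # m x n
    denom <- rowSums(Hw)
    Wnew <- (Hw %*% X)
    upd <- denom > 0
    Wnew[upd, ] <- Wnew[upd, , drop = FALSE] / denom[upd]
    W[upd, ] <- Wnew[upd, , drop = FALSE]
  }
  structure(list(weights = W, grid = as.integer(grid), coords = coords,
                 epochs = epochs, features = colnames(X)),
            class = "som_model")
}

#' @export
print.som_model <- function(x, ...) {
  cat(sprintf("<som_model> %d x %d lattice, %d features, %d epochs\n",
              x$grid[1], x$grid[2], ncol(x$weights), x$epochs))
  invisible(x)
}

#' SOM weight planes and their correlations
#'
#' Reshapes each feature's weight component onto the lattice and reports
#' the Pearson correlation between every pair of flattened planes. Two
#' inputs with near-identical planes (|r| above `flag_threshold`) are
#' flagged as highly correlated — the SOM's advisory check that candidate
#' features carry non-redundant information. On a single-neuron lattice
#' the planes are scalars and correlations are reported as `NA`.
#'
#' @param m A `som_model`.
#' @param flag_threshold Absolute correlation that triggers a flag.
#' @return List with `planes` (list of matrices), `correlations`
#'   (feature x feature), `flagged` (data frame of flagged pairs).
#' @export
som_weight_planes <- function(m, flag_threshold = 0.9) {
  stopifnot(inherits(m, "som_model"))
  nf <- ncol(m$weights)
  fn <- m$features %||% paste0("f", seq_len(nf))
  planes <- lapply(seq_len(nf), function(k)
    matrix(m$weights[, k], m$grid[1], m$grid[2]))
  names(planes) <- fn
  if (nrow(m$weights) < 2L) {
    co <- matrix(NA_real_, nf, nf, dimnames = list(fn, fn))
  } else {
    co <- suppressWarnings(cor(m$weights))
    dimnames(co) <- list(fn, fn)
  }
  pairs <- which(upper.tri(co) & is.finite(co) &
                   abs(co) > flag_threshold, arr.ind = TRUE)
  flagged <- data.frame(feature1 = fn[pairs[, 1]], feature2 = fn[pairs[, 2]],
                        r = co[pairs], stringsAsFactors = FALSE)
  list(planes = planes, correlations = co, flagged = flagged)
}
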