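#' Fit a Box-Cox power transform by profile likelihood
#'
#' Estimates the power parameter lambda maximizing the Box-Cox profile
#' log-likelihood \deqn{\ell(\lambda) = -\frac{n}{2}\log \hat\sigma^2_z +
#' (\lambda - 1)\sum_i \log y_i} over a bounded interval, where `z` is the
#' transformed sample. Values that are not strictly positive are shifted by
#' `1 - min(y)` before fitting, and the shift is stored so the transform
#' stays invertible.
#'
#' @param y Numeric sample with at least 3 distinct values.
#' @param lambda_range Search interval for lambda (default `c(-5, 5)`).
#' @return An object of class `boxcox_state` with elements `lambda` and
#'   `shift`.
#' @export
boxcox_fit <- function(y, lambda_range = c(-5, 5)) {
  y <- as.numeric(y)
  if (anyNA(y) || any(!is.finite(y))) stopf("y must be finite")
  if (length(unique(y)) < 3) {
    stopf("Box-Cox fit needs at least 3 distinct values")
  }
  shift <- if (min(y) <= 0) 1 - min(y) else 0
  ys <- y + shift
  logy <- sum(log(ys))
  n <- length(ys)
  negll <- function(lambda) {
    z <- if (abs(lambda) < 1e-12) log(ys) else (ys^lambda - 1) / lambda
    s2 <- mean((z - mean(z))^2)
    0.5 * n * log(s2) - (lambda - 1) * logy
  }
  opt <- stats::optimize(negll, lambda_range, tol = 1e-6)
  structure(list(lambda = opt$minimum, shift = shift), class = "boxcox_state")
}

#' Apply / invert a fitted Box-Cox transform
#'
#' `boxcox_apply` computes `((y + shift)^lambda - 1) / lambda` (the natural
#' log of `y + shift` when lambda is zero); `boxcox_invert` is its exact
#' inverse, erroring on values outside the transform's range.
#'
#' @param state A `boxcox_state` from [boxcox_fit()] (or constructed with
#'   known `lambda`/`shift`).
#' @param y,z Values on the original / transformed scale.
#' @return Transformed (or back-transformed) numeric vector.
#' @export
boxcox_apply <- function(state, y) {
  stopifnot(inherits(state, "boxcox_state"))
  ys <- y + state$shift
  if (any(ys <= 0)) stopf("values must exceed -shift to be transformable")
  if (abs(state$lambda) < 1e-12) log(ys)
  else (ys^state$lambda - 1) / state$lambda
}

#' @rdname boxcox_apply
#' @export
boxcox_invert <- function(state, z) {
  stopifnot(inherits(state, "boxcox_state"))
  lam <- state$lambda
  if (abs(lam) < 1e-12) return(exp(z) - state$shift)
  base <- lam * z + 1
  if (any(base <= 0)) {
    stopf("values outside the range of the Box-Cox transform")
  }
  base^(1 / lam) - state$shift
}

#' Standardization state for model inputs
#'
#' Distances in the kernel regression are scale-sensitive, so inputs are
#' centered and scaled using statistics of the training subset only.
#'
#' @param X Training input matrix or data frame.
#' @return An object of class `scaling_state` (per-column mean and sd).
#' @export
scaling_fit <- function(X) {
  X <- as.matrix(X)
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  if (any(!is.finite(sd)) || any(sd <= 0)) {
    stopf("every retained input must have positive standard deviation")
  }
  structure(list(mean = mu, sd = sd), class = "scaling_state")
}

#' @rdname scaling_fit
#' @param state A `scaling_state`.
#' @export
scaling_apply <- function(state, X) {
  stopifnot(inherits(state, "scaling_state"))
  X <- as.matrix(X)
  sweep(sweep(X, 2, state$mean), 2, state$sd, `/`)
}

#' Screen for multivariate outliers by principal component analysis
#'
#' Columns are standardized, scores are taken on the leading components
#' covering at least `var_explained` of the variance, and each row's score
#' distance (Euclidean norm of its component-wise standardized scores) is
#' computed. Rows whose distance exceeds the mean by more than `threshold`
#' standard deviations are flagged. In a clean sample of size n the largest
#' distance is expected to sit near `qnorm(1 - 1/n)` SDs above the mean, so
#' the default threshold is Bonferroni-adjusted to the sample size,
#' `qnorm(1 - 0.01 / (2n))` (about 4.2 at n = 360): a clean dataset is
#' expected to produce zero flags while a grossly corrupted row (distances
#' tens of SDs out) is still caught. The screen is advisory: it reports rows,
#' it does not drop them.
#'
#' @param x Data frame or matrix of inputs and responses (>= 10 rows).
#' @param var_explained Minimum cumulative variance of retained components.
#' @param threshold Flagging threshold in standard deviations of the score
#'   distance; `NULL` (default) uses the sample-size-adjusted value above.
#' @return Integer vector of flagged row indices (possibly empty), with the
#'   score distances attached as attribute `"distance"` and the threshold
#'   used as attribute `"threshold"`.
#' @export
pca_outliers <- function(x, var_explained = 0.95, threshold = NULL) {
  X <- as.matrix(as.data.frame(x)[, sapply(as.data.frame(x), is.numeric)])
  if (nrow(X) < 10) stopf("outlier screening needs at least 10 rows")
  keep <- apply(X, 2, stats::sd) > 0
  p <- stats::prcomp(X[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
  cum <- cumsum(p$sdev^2) / sum(p$sdev^2)
  k <- which(cum >= var_explained)[1]
  Z <- sweep(p$x[, 1:k, drop = FALSE], 2, p$sdev[1:k], `/`)
  d <- sqrt(rowSums(Z^2))
  if (is.null(threshold)) {
    threshold <- stats::qnorm(1 - 0.01 / (2 * nrow(X)))
  }
  flagged <- which(d > mean(d) + threshold * stats::sd(d))
  attr(flagged, "distance") <- d
  attr(flagged, "threshold") <- threshold
  flagged
}

#' Build a repeated k-fold cross-validation plan
#'
#' Every row appears in exactly one test fold per repeat, fold sizes differ by
#' at most one, and the assignment is reproducible bit-for-bit under the seed.
#'
#' @param n Number of rows.
#' @param k Folds per repeat (default 5).
#' @param repeats Number of repeats (default 10).
#' @param seed Integer seed.
#' @return An object of class `cv_plan`: `n`, `k`, `repeats`, `seed` and an
#'   `n x repeats` integer matrix `assignments` of fold indices.
#' @export
make_cv_plan <- function(n, k = 5, repeats = 10, seed = 1) {
  if (!is_count(n) || !is_count(k) || !is_count(repeats)) {
    stopf("n, k and repeats must be positive integers")
  }
  if (n < k) stopf("need at least as many rows (%d) as folds (%d)", n, k)
  assignments <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(repeats),
           function(r) sample(rep_len(seq_len(k), n)),
           integer(n))
  })
  structure(list(n = as.integer(n), k = as.integer(k),
                 repeats = as.integer(repeats), seed = as.integer(seed),
                 assignments = assignments),
            class = "cv_plan")
}

# Iterate (repeat, fold) pairs of a cv_plan as a list of test-row index vectors.
cv_folds <- function(plan) {
  stopifnot(inherits(plan, "cv_plan"))
  out <- list()
  for (r in seq_len(plan$repeats)) {
    for (f in seq_len(plan$k)) {
      out[[length(out) + 1L]] <- list(
        repeat_ = r, fold = f,
        test = which(plan$assignments[, r] == f))
    }
  }
  out
}
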