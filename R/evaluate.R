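# Factory for the repeated-CV RMSE objective used when tuning sigma.
#
# Distances are computed once on inputs standardized with full-sample
# statistics and reused across all (repeat, fold) pairs; per-fold
# nearest-neighbor fallback targets (the sigma -> 0 limit) are also
# precomputed, so evaluating one sigma costs one kernel matrix plus 50 small
# matrix-vector products.
cv_rmse_objective <- function(x, y, plan) {
  X <- as.matrix(x)
  y <- as.numeric(y)
  stopifnot(inherits(plan, "cv_plan"))
  if (nrow(X) != length(y) || nrow(X) != plan$n) {
    stopf("x, y and the CV plan disagree on the number of rows")
  }
  Xs <- scaling_apply(scaling_fit(X), X)
  D2 <- pairwise_sqdist(Xs, Xs)
  pre <- lapply(cv_folds(plan), function(f) {
    train <- setdiff(seq_len(plan$n), f$test)
    if (length(f$test) == 0 || length(train) == 0) {
      stopf("degenerate CV fold (empty training or testing subset)")
    }
    nn <- train[max.col(-D2[f$test, train, drop = FALSE],
                        ties.method = "first")]
    list(test = f$test, train = train, nn_y = y[nn])
  })
  function(sigma) {
    P <- exp(-D2 / (2 * sigma^2))
    mean(vapply(pre, function(f) {
      Psub <- P[f$test, f$train, drop = FALSE]
      pred <- as.vector(Psub %*% y[f$train]) / rowSums(Psub)
      bad <- !is.finite(pred)
      if (any(bad)) pred[bad] <- f$nn_y[bad]
      sqrt(mean((pred - y[f$test])^2))
    }, numeric(1)))
  }
}

#' Tune the GRNN smoothing parameter with FOA
#'
#' Searches sigma over `sigma_range` (on the standardized-input scale) with
#' the fruit-fly optimizer, using the negative mean repeated-CV RMSE as the
#' smell-concentration (fitness) function. Deterministic under the FOA seed.
#'
#' @param x Input matrix (n x d).
#' @param y Targets on the modeling (possibly Box-Cox) scale.
#' @param plan A [make_cv_plan()] for `nrow(x)` rows.
#' @param foa An [foa_config()].
#' @param sigma_range Search interval for sigma (default `c(1e-3, 10)`).
#' @return An object of class `sigma_tuning`: `sigma`, `cv_rmse`, the
#'   `objective` function (mean CV RMSE as a function of sigma, reusable for
#'   grid checks), and the raw `foa` result.
#' @export
tune_sigma_foa <- function(x, y, plan, foa = foa_config(),
                           sigma_range = c(1e-3, 10)) {
  if (nrow(as.matrix(x)) < 2 * plan$k) {
    stopf("sigma tuning needs at least 2k training rows")
  }
  obj <- cv_rmse_objective(x, y, plan)
  res <- foa_maximize(function(s) -obj(s[1]),
                      bounds = matrix(sigma_range, 1), config = foa)
  structure(list(sigma = unname(res$par[1]), cv_rmse = -res$value,
                 objective = obj, foa = res),
            class = "sigma_tuning")
}

#' Pipeline configuration
#'
#' @param responses Response columns to model (default all six).
#' @param boxcox Box-Cox-transform each response before modeling (default
#'   `TRUE`); metrics are always reported on the original scale after inverse
#'   transformation.
#' @param cv_k,cv_repeats Folds and repeats of the cross-validation plan.
#' @param seed Integer seed governing the CV plan and optimizer seeds.
#' @param sigma_range Smoothing-parameter search interval.
#' @param foa FOA settings for sigma tuning.
#' @param retune_per_fold Retune sigma inside every training fold instead of
#'   once per response (slower; default `FALSE`).
#' @param drop_outliers Drop rows flagged by [pca_outliers()] before modeling
#'   (default `FALSE`: the screen is advisory and only reported). The screen
#'   runs after response normalization, on the modeling scale.
#' @param outlier_threshold Flagging threshold passed to [pca_outliers()]
#'   (`NULL` = sample-size-adjusted default).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(responses = response_names(), boxcox = TRUE,
                            cv_k = 5, cv_repeats = 10, seed = 1,
                            sigma_range = c(1e-3, 10),
                            foa = foa_config(seed = seed),
                            retune_per_fold = FALSE, drop_outliers = FALSE,
                            outlier_threshold = NULL) {
  bad <- setdiff(responses, response_names())
  if (length(bad) > 0) stopf("unknown response(s): %s", paste(bad, collapse = ", "))
  structure(
    list(responses = responses, boxcox = isTRUE(boxcox),
         cv_k = as.integer(cv_k), cv_repeats = as.integer(cv_repeats),
         seed = as.integer(seed), sigma_range = sigma_range, foa = foa,
         retune_per_fold = isTRUE(retune_per_fold),
         drop_outliers = isTRUE(drop_outliers),
         outlier_threshold = outlier_threshold),
    class = "pipeline_config")
}

#' Fit and cross-validate GRNN-FOA models for every response
#'
#' For each configured response the pipeline (i) Box-Cox-transforms the
#' response, (ii) tunes the smoothing parameter by FOA against the repeated
#' k-fold CV RMSE, holding one sigma per response across all folds, (iii) for
#' every (repeat, fold) pair fits the GRNN on the k-1 training folds
#' (standardizing inputs with training-fold statistics only), predicts both
#' the in-fold (training) and held-out (testing) rows, back-transforms, and
#' computes R^2, RMSE and MBE on the original response scale, and (iv) refits
#' a deployment model on all rows. Reported metrics are the mean over the
#' `k * repeats` fold evaluations, with standard deviations alongside.
#'
#' @param dataset An elicitation dataset (see [simulate_dataset()] /
#'   [read_dataset()]).
#' @param config A [pipeline_config()].
#' @return An object of class `grnnfoa_pipeline`: per-response `models`
#'   (deployment GRNN, Box-Cox state, tuned sigma, CV RMSE), a long-format
#'   `metrics` data frame, the CV `plan`, flagged `outliers`, the stored
#'   `dataset`, and `provenance` (seed and config hash).
#' @export
evaluate_pipeline <- function(dataset, config = pipeline_config()) {
  validate_dataset(dataset)
  stopifnot(inherits(config, "pipeline_config"))
  df <- as.data.frame(dataset)
  screen_tab <- df[, dataset_columns()]
  if (config$boxcox) {
    for (resp in response_names()) {
      screen_tab[[resp]] <- boxcox_apply(boxcox_fit(screen_tab[[resp]]),
                                         screen_tab[[resp]])
    }
  }
  outliers <- pca_outliers(screen_tab, threshold = config$outlier_threshold)
  if (config$drop_outliers && length(outliers) > 0) {
    df <- df[-outliers, , drop = FALSE]
  }
  X <- as.matrix(df[, input_names()])
  n <- nrow(X)
  plan <- make_cv_plan(n, k = config$cv_k, repeats = config$cv_repeats,
                       seed = config$seed)
  folds <- cv_folds(plan)
  models <- list()
  rows <- list()
  for (resp in config$responses) {
    y <- df[[resp]]
    bc <- if (config$boxcox) boxcox_fit(y) else NULL
    z <- if (is.null(bc)) y else boxcox_apply(bc, y)
    tuning <- tune_sigma_foa(X, z, plan, foa = config$foa,
                             sigma_range = config$sigma_range)
    sigma <- tuning$sigma
    fold_metrics <- lapply(folds, function(f) {
      train <- setdiff(seq_len(n), f$test)
      sig_f <- if (config$retune_per_fold) {
        sub_plan <- make_cv_plan(length(train), k = config$cv_k,
                                 repeats = 1, seed = config$seed + f$fold)
        tune_sigma_foa(X[train, , drop = FALSE], z[train], sub_plan,
                       foa = config$foa,
                       sigma_range = config$sigma_range)$sigma
      } else sigma
      m <- grnn_fit(X[train, , drop = FALSE], z[train], sig_f)
      back <- function(p) if (is.null(bc)) p else boxcox_invert(bc, p)
      est_tr <- back(predict(m, X[train, , drop = FALSE]))
      est_te <- back(predict(m, X[f$test, , drop = FALSE]))
      list(train = compute_metrics(y[train], est_tr),
           test = compute_metrics(y[f$test], est_te))
    })
    agg <- function(subset) {
      vals <- sapply(fold_metrics, function(fm) unlist(fm[[subset]]))
      data.frame(response = resp,
                 subset = if (subset == "train") "training" else "testing",
                 r2 = mean(vals["r2", ]), rmse = mean(vals["rmse", ]),
                 mbe = mean(vals["mbe", ]), r2_sd = stats::sd(vals["r2", ]),
                 rmse_sd = stats::sd(vals["rmse", ]),
                 mbe_sd = stats::sd(vals["mbe", ]),
                 stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- rbind(agg("train"), agg("test"))
    models[[resp]] <- list(
      grnn = grnn_fit(X, z, sigma), boxcox = bc, sigma = sigma,
      cv_rmse = tuning$cv_rmse)
  }
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL
  cfg_hash <- object_hash(lapply(unclass(config),
                                 function(el) if (is.object(el)) unclass(el) else el))
  structure(
    list(models = models, metrics = metrics, plan = plan,
         outliers = as.integer(outliers), dataset = df, config = config,
         provenance = list(seed = config$seed, config_hash = cfg_hash)),
    class = "grnnfoa_pipeline")
}

#' Predict a response from a fitted pipeline on the original scale
#'
#' @param pipeline A `grnnfoa_pipeline`.
#' @param response Response name.
#' @param newdata Input point(s): vector, matrix or data frame with the four
#'   culture inputs.
#' @return Numeric predictions in the response's original units.
#' @export
predict_response <- function(pipeline, response, newdata) {
  stopifnot(inherits(pipeline, "grnnfoa_pipeline"))
  m <- pipeline$models[[response]]
  if (is.null(m)) stopf("response %s was not fitted in this pipeline", response)
  p <- predict(m$grnn, newdata)
  if (is.null(m$boxcox)) p else boxcox_invert(m$boxcox, p)
}

#' @export
print.grnnfoa_pipeline <- function(x, ...) {
  cat(sprintf("GRNN-FOA pipeline: %d responses, %d rows, %d-fold x %d CV\n",
              length(x$models), nrow(x$dataset), x$plan$k, x$plan$repeats))
  sig <- vapply(x$models, `[[`, numeric(1), "sigma")
  cat("tuned sigma:\n")
  print(round(sig, 4))
  invisible(x)
}
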