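#' Fit a general regression neural network
#'
#' A GRNN is a one-pass Gaussian kernel regressor (Nadaraya-Watson estimator)
#' organized as four layers. The pattern layer stores every training vector
#' `x_i` and, for a query `x`, emits
#' \deqn{p_i = \exp\{-\|x - x_i\|^2 / (2\sigma^2)\},}
#' the summation layer forms the simple sum `S_s = sum(p_i)` and the weighted
#' sum `S_w = sum(w_i p_i)` with the interconnection weights `w_i` taken as
#' the training targets, and the output layer returns the ratio of the
#' weighted to the simple summation, `Y = S_w / S_s` — a convex combination
#' of the training targets. Fitting is storage only (lazy learner); the single
#' free parameter is the smoothing bandwidth `sigma`, shared across the
#' (standardized) input dimensions.
#'
#' @param x Training inputs, n x d matrix or data frame.
#' @param y Training targets, length n.
#' @param sigma Smoothing parameter, > 0.
#' @param standardize Center and scale inputs before computing distances
#'   (default `TRUE`); queries are transformed with the stored training
#'   statistics.
#' @return An object of class `grnn`.
#' @export
grnn_fit <- function(x, y, sigma, standardize = TRUE) {
  X <- as.matrix(x)
  y <- as.numeric(y)
  if (nrow(X) == 0) stopf("cannot fit a GRNN with no training patterns")
  if (length(y) != nrow(X)) stopf("x and y sizes disagree")
  if (anyNA(X) || any(!is.finite(X)) || anyNA(y) || any(!is.finite(y))) {
    stopf("training data must be finite")
  }
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0) {
    stopf("sigma must be a positive scalar")
  }
  scaling <- if (standardize) scaling_fit(X) else NULL
  Xs <- if (standardize) scaling_apply(scaling, X) else X
  structure(
    list(X = Xs, w = y, sigma = sigma, scaling = scaling,
         dim = ncol(X), colnames = colnames(X)),
    class = "grnn")
}

# Prediction core on the model's internal (standardized) scale. Rows whose
# kernel mass underflows to zero fall back to the nearest pattern's target,
# which is the sigma -> 0 limit of the estimator. Large query batches are
# processed in blocks to bound the kernel matrix size.
grnn_predict_core <- function(model, Q, warn = TRUE, block = 20000L) {
  if (nrow(Q) > block) {
    starts <- seq(1L, nrow(Q), by = block)
    return(unlist(lapply(starts, function(s) {
      grnn_predict_block(model, Q[s:min(s + block - 1L, nrow(Q)), ,
                                  drop = FALSE], warn)
    }), use.names = FALSE))
  }
  grnn_predict_block(model, Q, warn)
}

grnn_predict_block <- function(model, Q, warn = TRUE) {
  D2 <- pairwise_sqdist(Q, model$X)
  P <- exp(-D2 / (2 * model$sigma^2))
  Ss <- rowSums(P)
  pred <- as.vector(P %*% model$w) / Ss
  bad <- !is.finite(pred)
  if (any(bad)) {
    if (warn) {
      warning("kernel mass underflowed for ", sum(bad),
              " query point(s); falling back to nearest-pattern target",
              call. = FALSE)
    }
    nn <- max.col(-D2[bad, , drop = FALSE], ties.method = "first")
    pred[bad] <- model$w[nn]
  }
  pred
}

#' Predict from a fitted GRNN
#'
#' @param object A `grnn` model.
#' @param newdata Query point(s): a length-d vector, or an m x d matrix or
#'   data frame.
#' @param ... Unused.
#' @return Numeric vector of predictions, always within the range of the
#'   training targets.
#' @export
predict.grnn <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  Q <- as.matrix(as.data.frame(newdata))
  if (!is.null(object$colnames) && all(object$colnames %in% colnames(Q))) {
    Q <- Q[, object$colnames, drop = FALSE]
  }
  if (ncol(Q) != object$dim) {
    stopf("query has %d columns; model expects %d", ncol(Q), object$dim)
  }
  if (anyNA(Q) || any(!is.finite(Q))) stopf("query values must be finite")
  if (!is.null(object$scaling)) Q <- scaling_apply(object$scaling, Q)
  grnn_predict_core(object, Q)
}

#' Serialize / restore a GRNN model as JSON
#'
#' Embeds the stored patterns, target weights, smoothing parameter and
#' scaling state so that predictions replay exactly.
#'
#' @param model A `grnn`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @param json JSON string or file path produced by `grnn_to_json`.
#' @return `grnn_to_json`: JSON string (or `path`, invisibly);
#'   `grnn_from_json`: a `grnn`.
#' @export
grnn_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "grnn"))
  obj <- list(
    type = "grnn", X = model$X, w = model$w, sigma = model$sigma,
    dim = model$dim, colnames = model$colnames,
    scaling = if (!is.null(model$scaling)) {
      list(mean = model$scaling$mean, sd = model$scaling$sd)
    })
  json <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE, null = "null")
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(path)
}

#' @rdname grnn_to_json
#' @export
grnn_from_json <- function(json) {
  if (length(json) == 1 && file.exists(json)) json <- readLines(json)
  obj <- jsonlite::fromJSON(paste(json, collapse = "\n"))
  if (!identical(obj$type, "grnn")) stopf("not a serialized GRNN model")
  scaling <- if (!is.null(obj$scaling)) {
    structure(list(mean = unlist(obj$scaling$mean), sd = unlist(obj$scaling$sd)),
              class = "scaling_state")
  }
  structure(
    list(X = matrix(obj$X, ncol = obj$dim), w = as.numeric(obj$w),
         sigma = obj$sigma, scaling = scaling, dim = obj$dim,
         colnames = obj$colnames),
    class = "grnn")
}

#' @export
print.grnn <- function(x, ...) {
  cat(sprintf("GRNN: %d stored patterns, %d inputs, sigma = %.6g%s\n",
              nrow(x$X), x$dim, x$sigma,
              if (is.null(x$scaling)) "" else " (standardized inputs)"))
  invisible(x)
}
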