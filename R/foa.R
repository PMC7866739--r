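#' Fruit-fly optimization configuration
#'
#' Defaults follow the settings used to tune GRNN smoothing in elicitation
#' modeling: swarm of 10 flies, 100 generations, initial location coordinates
#' drawn from `[0, 1]`, and flight distance range `[-10, 10]`.
#'
#' @param sizepop Flies per generation (>= 2).
#' @param maxgen Number of generations (>= 1).
#' @param lc_range Interval from which the group's initial location
#'   coordinates are drawn.
#' @param fdr Flight distance range: each fly perturbs the group coordinates
#'   by a fresh uniform draw from this interval (must contain 0).
#' @param seed Integer seed making the run reproducible.
#' @param mapping How a fly's smell-concentration judgment values `S = 1/Dist`
#'   are mapped into the search box: `"contract"` (default) rescales each
#'   generation's raw `S` values, dimension-wise by their min-max range, onto
#'   a trust region centered on the incumbent — after an initial exploration
#'   phase covering the whole box, the region contracts geometrically to
#'   `contract_final` of the box range, so the rescaling layer absorbs the
#'   scale mismatch between the location coordinates and the problem box
#'   while letting the swarm first explore globally and then converge;
#'   `"minmax"` rescales onto the full box every generation (the literal
#'   generation-wise min-max squash); `"direct"` clips the raw `S` values to
#'   the box.
#' @param contract_final Final trust-region half-width as a fraction of the
#'   box range (default 0.005).
#' @param explore_frac Fraction of the generations spent sampling the full
#'   box before contraction starts (default 0.5); guards against locking onto
#'   a local optimum of a multimodal fitness.
#' @return An object of class `foa_config`.
#' @export
foa_config <- function(sizepop = 10, maxgen = 100, lc_range = c(0, 1),
                       fdr = c(-10, 10), seed = 1,
                       mapping = c("contract", "minmax", "direct"),
                       contract_final = 0.005, explore_frac = 0.5) {
  if (!is_count(sizepop) || sizepop < 2) stopf("sizepop must be >= 2")
  if (!is_count(maxgen)) stopf("maxgen must be >= 1")
  if (length(fdr) != 2 || fdr[1] > 0 || fdr[2] < 0) {
    stopf("fdr must be an interval containing 0")
  }
  if (length(lc_range) != 2 || lc_range[1] > lc_range[2]) {
    stopf("lc_range must be an interval")
  }
  if (explore_frac < 0 || explore_frac >= 1) {
    stopf("explore_frac must be in [0, 1)")
  }
  structure(
    list(sizepop = as.integer(sizepop), maxgen = as.integer(maxgen),
         lc_range = lc_range, fdr = fdr, seed = as.integer(seed),
         mapping = match.arg(mapping), contract_final = contract_final,
         explore_frac = explore_frac),
    class = "foa_config")
}

#' Map smell-concentration judgment values into a box
#'
#' Affine min-max squash: within one generation, each dimension's raw `S`
#' values are rescaled so their minimum lands on the lower and their maximum
#' on the upper edge of the target interval (ordering is preserved), then
#' clipped. With `enabled = FALSE` the raw values are only clipped.
#'
#' @param S Matrix of raw judgment values, flies x dimensions (or a vector
#'   for one dimension).
#' @param bounds d x 2 matrix of target `[lo, hi]` intervals.
#' @param enabled Apply the min-max squash (default) or clip only.
#' @return Matrix of in-box candidates, same shape as `S`.
#' @export
foa_map_candidates <- function(S, bounds, enabled = TRUE) {
  if (is.null(dim(S))) S <- matrix(S, ncol = 1)
  bounds <- as_bounds_matrix(bounds, ncol(S))
  out <- S
  for (j in seq_len(ncol(S))) {
    lo <- bounds[j, 1]; hi <- bounds[j, 2]
    if (enabled) {
      rng <- range(S[, j])
      out[, j] <- if (rng[2] > rng[1]) {
        lo + (S[, j] - rng[1]) / (rng[2] - rng[1]) * (hi - lo)
      } else {
        rep((lo + hi) / 2, nrow(S))
      }
    }
    out[, j] <- pmin(pmax(out[, j], lo), hi)
  }
  out
}

#' Maximize a function over a box with the fruit-fly optimization algorithm
#'
#' Each search dimension carries an independent pair of location coordinates
#' `(X, Y)`. Per generation, every fly perturbs the group coordinates by a
#' uniform draw from the flight distance range, computes its distance to the
#' origin `Dist = sqrt(X^2 + Y^2)` and its smell-concentration judgment value
#' `S = 1/Dist`; the judgment values are mapped into the box (see
#' [foa_map_candidates()] and the `mapping` option of [foa_config()]), the
#' fitness ("smell concentration") is evaluated at each candidate, and the
#' best fly is identified (ties to the lowest index). The group relocates to
#' the best fly's coordinates only when its smell improves on the incumbent,
#' so the best-smell trace is non-decreasing. Exactly `sizepop * maxgen`
#' fitness evaluations are spent; candidates with `NA`/`NaN` fitness are
#' discarded for the generation with a warning (`-Inf` marks infeasible
#' candidates and is kept, it simply never wins).
#'
#' @param fitness Function mapping a length-d numeric vector to a scalar.
#' @param bounds d x 2 matrix (or list of `c(lo, hi)`) of finite box bounds.
#' @param config An [foa_config()].
#' @return An object of class `foa_result`: `par` (best candidate), `value`
#'   (best fitness), `trace` (per-generation incumbent fitness),
#'   `evaluations`, and `config`.
#' @export
foa_maximize <- function(fitness, bounds, config = foa_config()) {
  stopifnot(inherits(config, "foa_config"))
  bounds <- as_bounds_matrix(bounds)
  d <- nrow(bounds)
  lo <- bounds[, 1]; hi <- bounds[, 2]
  range_ <- hi - lo
  explore_gens <- if (config$mapping == "contract") {
    floor(config$explore_frac * config$maxgen)
  } else 0L
  shrink <- if (config$mapping == "contract") {
    (config$contract_final / 0.5)^(1 / max(config$maxgen - explore_gens, 1))
  } else 1
  withr::with_seed(config$seed, {
    X <- stats::runif(d, config$lc_range[1], config$lc_range[2])
    Y <- stats::runif(d, config$lc_range[1], config$lc_range[2])
    center <- (lo + hi) / 2
    radius <- range_ / 2
    best_par <- NULL
    best_val <- -Inf
    trace <- numeric(config$maxgen)
    evals <- 0L
    dropped <- 0L
    for (g in seq_len(config$maxgen)) {
      Xi <- sweep(matrix(stats::runif(config$sizepop * d, config$fdr[1],
                                      config$fdr[2]),
                         config$sizepop, d), 2, X, `+`)
      Yi <- sweep(matrix(stats::runif(config$sizepop * d, config$fdr[1],
                                      config$fdr[2]),
                         config$sizepop, d), 2, Y, `+`)
      Dist <- pmax(sqrt(Xi^2 + Yi^2), 1e-300)
      S <- 1 / Dist
      region <- if (g <= explore_gens) bounds else {
        cbind(pmax(lo, center - radius), pmin(hi, center + radius))
      }
      cand <- switch(config$mapping,
        contract = foa_map_candidates(S, region),
        minmax = foa_map_candidates(S, bounds),
        direct = foa_map_candidates(S, bounds, enabled = FALSE))
      smell <- vapply(seq_len(config$sizepop),
                      function(i) as.numeric(fitness(cand[i, ]))[1],
                      numeric(1))
      evals <- evals + config$sizepop
      invalid <- is.na(smell) | is.nan(smell)
      if (any(invalid)) {
        dropped <- dropped + sum(invalid)
        smell[invalid] <- -Inf
      }
      best_i <- which.max(smell)
      if (length(best_i) == 1 && smell[best_i] > best_val) {
        best_val <- smell[best_i]
        best_par <- cand[best_i, ]
        X <- Xi[best_i, ]
        Y <- Yi[best_i, ]
        center <- best_par
      }
      trace[g] <- best_val
      if (g > explore_gens) radius <- radius * shrink
    }
    if (dropped > 0) {
      warning(sprintf("FOA discarded %d candidate(s) with undefined fitness",
                      dropped), call. = FALSE)
    }
    structure(
      list(par = best_par, value = best_val, trace = trace,
           evaluations = evals, config = config),
      class = "foa_result")
  })
}

#' Export an optimizer trace as CSV
#'
#' @param result An `foa_result` or `ga_result`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(result, path) {
  df <- data.frame(generation = seq_along(result$trace),
                   best_fitness = result$trace)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
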