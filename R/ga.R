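#' Real-coded genetic algorithm configuration
#'
#' Conventional real-coded defaults: population 50, 100 generations, blend
#' crossover (alpha 0.5) at rate 0.9, per-gene Gaussian mutation at rate 0.1
#' with standard deviation 5% of each dimension's range, tournament selection
#' of size 3, and one elite individual carried over unchanged.
#'
#' @param popsize Population size (>= 4).
#' @param generations Number of generations.
#' @param pcross Crossover probability in `[0, 1]`.
#' @param alpha Blend-crossover expansion parameter.
#' @param pmut Per-gene mutation probability in `[0, 1]`.
#' @param mut_sd_frac Mutation standard deviation as a fraction of range.
#' @param tournament Tournament size.
#' @param elitism Number of elites (< popsize).
#' @param seed Integer seed.
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(popsize = 50, generations = 100, pcross = 0.9,
                      alpha = 0.5, pmut = 0.1, mut_sd_frac = 0.05,
                      tournament = 3, elitism = 1, seed = 1) {
  if (!is_count(popsize) || popsize < 4) stopf("popsize must be >= 4")
  if (!is_count(generations)) stopf("generations must be >= 1")
  if (pcross < 0 || pcross > 1 || pmut < 0 || pmut > 1) {
    stopf("rates must be in [0, 1]")
  }
  if (!is_count(tournament) || tournament > popsize) {
    stopf("tournament size must be in [1, popsize]")
  }
  if (elitism < 0 || elitism >= popsize) stopf("elitism must be < popsize")
  structure(
    list(popsize = as.integer(popsize), generations = as.integer(generations),
         pcross = pcross, alpha = alpha, pmut = pmut,
         mut_sd_frac = mut_sd_frac, tournament = as.integer(tournament),
         elitism = as.integer(elitism), seed = as.integer(seed)),
    class = "ga_config")
}

#' Maximize a function over a box with a real-coded genetic algorithm
#'
#' Tournament selection, blend (BLX-alpha) crossover, Gaussian mutation
#' clipped to the bounds, and elitist survival, so the best-fitness trace is
#' non-decreasing. Candidates with `NA`/`NaN` fitness are treated as `-Inf`
#' with a warning.
#'
#' @param fitness Function mapping a length-d numeric vector to a scalar.
#' @param bounds d x 2 matrix (or list of `c(lo, hi)`) of finite box bounds.
#' @param config A [ga_config()].
#' @return An object of class `ga_result`: `par`, `value`, `trace`,
#'   `evaluations`, `config`.
#' @export
ga_maximize <- function(fitness, bounds, config = ga_config()) {
  stopifnot(inherits(config, "ga_config"))
  bounds <- as_bounds_matrix(bounds)
  d <- nrow(bounds)
  lo <- bounds[, 1]; hi <- bounds[, 2]
  clip <- function(P) {
    for (j in seq_len(d)) P[, j] <- pmin(pmax(P[, j], lo[j]), hi[j])
    P
  }
  eval_pop <- function(P) {
    vapply(seq_len(nrow(P)),
           function(i) as.numeric(fitness(P[i, ]))[1], numeric(1))
  }
  withr::with_seed(config$seed, {
    np <- config$popsize
    pop <- clip(matrix(stats::runif(np * d, rep(lo, each = np),
                                    rep(hi, each = np)), np, d))
    fit <- eval_pop(pop)
    evals <- np
    dropped <- sum(is.na(fit) | is.nan(fit))
    fit[is.na(fit) | is.nan(fit)] <- -Inf
    trace <- numeric(config$generations)
    for (g in seq_len(config$generations)) {
      ord <- order(fit, decreasing = TRUE)
      newpop <- matrix(0, np, d)
      n_elite <- config$elitism
      if (n_elite > 0) newpop[seq_len(n_elite), ] <- pop[ord[seq_len(n_elite)], ]
      i <- n_elite
      while (i < np) {
        pick <- function() {
          cand <- sample.int(np, config$tournament, replace = TRUE)
          cand[which.max(fit[cand])]
        }
        p1 <- pop[pick(), ]; p2 <- pop[pick(), ]
        if (stats::runif(1) < config$pcross) {
          u <- stats::runif(d, -config$alpha, 1 + config$alpha)
          c1 <- u * p1 + (1 - u) * p2
          c2 <- u * p2 + (1 - u) * p1
        } else {
          c1 <- p1; c2 <- p2
        }
        for (child in list(c1, c2)) {
          if (i < np) {
            i <- i + 1
            mut <- stats::runif(d) < config$pmut
            if (any(mut)) {
              child[mut] <- child[mut] +
                stats::rnorm(sum(mut), sd = config$mut_sd_frac *
                               (hi[mut] - lo[mut]))
            }
            newpop[i, ] <- child
          }
        }
      }
      pop <- clip(newpop)
      fit <- eval_pop(pop)
      evals <- evals + np
      dropped <- dropped + sum(is.na(fit) | is.nan(fit))
      fit[is.na(fit) | is.nan(fit)] <- -Inf
      trace[g] <- max(fit)
    }
    if (dropped > 0) {
      warning(sprintf("GA treated %d candidate(s) with undefined fitness as -Inf",
                      dropped), call. = FALSE)
    }
    best <- which.max(fit)
    structure(
      list(par = pop[best, ], value = fit[best], trace = trace,
           evaluations = evals, config = config),
      class = "ga_result")
  })
}
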