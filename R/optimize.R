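#' Maximize a fitted response over the culture-input box
#'
#' Runs the fruit-fly and/or genetic-algorithm optimizer with the pipeline's
#' prediction (on original response units) as the fitness function.
#' Candidates violating the feasibility constraint `harvest_day > adding_day`
#' receive `-Inf` fitness. Because GRNN predictions are convex combinations
#' of training targets, the reported optimum can never exceed the largest
#' observed training response.
#'
#' By default the search is additionally confined to the training data's
#' support (`extrapolate = FALSE`): each input within its observed range, the
#' total elicitor dose `ce + cf` within the observed dose range, and the
#' elicitation-to-harvest gap within its observed range. Outside that region
#' a kernel regressor has no data and flattens onto its nearest stored
#' patterns, so "optima" there are artifacts; set `extrapolate = TRUE` to
#' search the full box anyway.
#'
#' @param pipeline A fitted `grnnfoa_pipeline`.
#' @param response Response to maximize.
#' @param bounds 4 x 2 input box (default [default_input_bounds()]).
#' @param optimizer `"foa"`, `"ga"` or `"both"`.
#' @param foa,ga Optimizer configurations (seeds for additional starts are
#'   derived from the configured seed).
#' @param extrapolate Allow candidates outside the training data's support
#'   (default `FALSE`).
#' @param foa_starts,ga_starts Independent optimizer starts; the best result
#'   is kept. A fitted kernel surface can be multimodal, and the small FOA
#'   swarm benefits from several starts (default 5); the larger GA population
#'   is robust with one.
#' @return A data frame of class `optimization_result`, one row per
#'   optimizer: the optimal inputs, predicted response at the optimum, and
#'   the derived quantities of [derived_quantities()].
#' @export
optimize_response <- function(pipeline, response,
                              bounds = default_input_bounds(),
                              optimizer = c("both", "foa", "ga"),
                              foa = foa_config(), ga = ga_config(),
                              extrapolate = FALSE, foa_starts = 5,
                              ga_starts = 1) {
  stopifnot(inherits(pipeline, "grnnfoa_pipeline"))
  optimizer <- match.arg(optimizer)
  bounds <- as_bounds_matrix(bounds, 4)
  if (bounds[4, 2] <= bounds[3, 1]) {
    stopf("empty feasible box: no harvest day can exceed the adding day")
  }
  support <- NULL
  if (!extrapolate && !is.null(pipeline$dataset)) {
    Xd <- pipeline$dataset[, input_names()]
    bounds <- cbind(pmax(bounds[, 1], apply(Xd, 2, min)),
                    pmin(bounds[, 2], apply(Xd, 2, max)))
    support <- list(dose = range(Xd$ce_pct + Xd$cf_pct),
                    gap = range(Xd$harvest_day - Xd$adding_day))
  }
  fitness <- function(v) {
    if (v[4] <= v[3]) return(-Inf)
    if (!is.null(support)) {
      dose <- v[1] + v[2]
      gap <- v[4] - v[3]
      if (dose < support$dose[1] - 1e-9 || dose > support$dose[2] + 1e-9 ||
          gap < support$gap[1] - 1e-9 || gap > support$gap[2] + 1e-9) {
        return(-Inf)
      }
    }
    predict_response(pipeline, response, matrix(v, nrow = 1))
  }
  multistart <- function(maximizer, config, starts) {
    best <- NULL
    for (k in seq_len(starts)) {
      config$seed <- as.integer(config$seed + (k - 1) * 1000L)
      res <- maximizer(fitness, bounds, config)
      if (is.null(best) || res$value > best$value) best <- res
      config$seed <- config$seed - (k - 1) * 1000L
    }
    best
  }
  run <- list()
  if (optimizer %in% c("both", "foa")) {
    run$foa <- multistart(foa_maximize, foa, foa_starts)
  }
  if (optimizer %in% c("both", "ga")) {
    run$ga <- multistart(ga_maximize, ga, ga_starts)
  }
  rows <- lapply(names(run), function(opt) {
    p <- run[[opt]]$par
    dq <- derived_quantities(p[1], p[2], p[3], p[4])
    data.frame(response = response, optimizer = opt,
               ce_pct = p[1], cf_pct = p[2], adding_day = p[3],
               harvest_day = p[4], dose_pct = dq$dose, ratio = dq$ratio,
               hours_post_elicitation = dq$hours,
               predicted = run[[opt]]$value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, runs = run,
            class = c("optimization_result", "data.frame"))
}

#' Optimize every fitted response
#'
#' Convenience wrapper running [optimize_response()] for each response of a
#' pipeline, producing an optimum report (one block per response and
#' optimizer).
#'
#' @inheritParams optimize_response
#' @param responses Responses to optimize (default: all fitted).
#' @return A combined `optimization_result` data frame.
#' @export
optimization_report <- function(pipeline, responses = names(pipeline$models),
                                bounds = default_input_bounds(),
                                optimizer = "both", foa = foa_config(),
                                ga = ga_config(), extrapolate = FALSE) {
  out <- do.call(rbind, lapply(responses, function(r) {
    as.data.frame(optimize_response(pipeline, r, bounds, optimizer, foa, ga,
                                    extrapolate = extrapolate))
  }))
  rownames(out) <- NULL
  structure(out, class = c("optimization_result", "data.frame"))
}

#' Derived quantities of an optimal input vector
#'
#' Total elicitor dose (`ce + cf`, percent v/v), the CE:CF blend ratio as
#' rounded percentages (e.g. `"44:56"`), and hours between elicitation and
#' harvest, `(harvest_day - adding_day) * 24`.
#'
#' @param ce_pct,cf_pct Elicitor fractions, percent v/v.
#' @param adding_day,harvest_day Culture days.
#' @return A list with `dose`, `ratio`, `hours`.
#' @export
derived_quantities <- function(ce_pct, cf_pct, adding_day, harvest_day) {
  dose <- ce_pct + cf_pct
  ratio <- if (dose > 0) {
    ce_share <- round(100 * ce_pct / dose)
    sprintf("%d:%d", ce_share, 100 - ce_share)
  } else {
    NA_character_
  }
  list(dose = dose, ratio = ratio,
       hours = hours_post_elicitation(adding_day, harvest_day))
}
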