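# Lazily built, cached fixtures shared across test files (built once per run).
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

input_ranges <- function() {
  b <- default_input_bounds()
  b[, 2] - b[, 1]
}

# Stratified (Latin hypercube style) sample of the culture-input box,
# honouring harvest > adding; used for surrogate-recovery studies where
# uniform coverage matters more than the factorial layout.
lhs_inputs <- function(n, seed) {
  withr::with_seed(seed, {
    L <- vapply(1:4, function(j) (sample(n) - stats::runif(n)) / n,
                numeric(n))
    X <- data.frame(ce_pct = 10 * L[, 1], cf_pct = 10 * L[, 2],
                    adding_day = 13 + 4 * L[, 3])
    X$harvest_day <- X$adding_day + 0.5 + L[, 4] * (23 - X$adding_day - 0.5)
    X
  })
}

surface_dataset <- function(surface, X) {
  structure(cbind(X, as.data.frame(surface_eval(surface, X))),
            class = c("elicitation_dataset", "data.frame"))
}

# Aligned-bump surface with a known interior peak (all three base responses
# share the same center, so the total-yield argmax is exactly `peak`).
recovery_surface <- function(peak = c(4.3, 5.4, 15.5, 19.5),
                             width = c(3.5, 3.5, 1.8, 3.5)) {
  true_surface(
    dw = list(baseline = 3, height = 9.57, center = peak, width = width),
    intra_g = list(baseline = 1.5, height = 18.26, center = peak,
                   width = width),
    extra = list(baseline = 2, height = 150.15, center = peak, width = width),
    noise_cv = 0)
}

# The reference study: full factorial design, 10% noise, all six responses.
default_noisy_pipeline <- function() fixture("noisy_pipeline", function() {
  evaluate_pipeline(simulate_dataset(seed = 1), pipeline_config(seed = 1))
})

# Noise-free surrogate-recovery study: 800 stratified runs of the aligned
# surface, total paclitaxel only.
recovery_pipeline <- function() fixture("recovery_pipeline", function() {
  d <- surface_dataset(recovery_surface(), lhs_inputs(800, seed = 42))
  evaluate_pipeline(d, pipeline_config(responses = "total_ug_l", seed = 1))
})

recovery_truth <- function() fixture("recovery_truth", function() {
  true_argmax(recovery_surface(), "total_ug_l", resolution = 41)
})

recovery_optima <- function() fixture("recovery_optima", function() {
  suppressWarnings(optimize_response(
    recovery_pipeline(), "total_ug_l",
    foa = foa_config(seed = 2), ga = ga_config(seed = 2)))
})

# Brute-force kernel-regression oracle: direct double-loop evaluation.
naive_grnn <- function(X, y, sigma, Q) {
  vapply(seq_len(nrow(Q)), function(i) {
    p <- vapply(seq_len(nrow(X)), function(j) {
      exp(-sum((Q[i, ] - X[j, ])^2) / (2 * sigma^2))
    }, numeric(1))
    sum(y * p) / sum(p)
  }, numeric(1))
}
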