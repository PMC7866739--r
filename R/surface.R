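.grnnfoa_cache <- new.env(parent = emptyenv())

#' Parametric ground-truth response surface
#'
#' A smooth, unimodal surface family used by the synthetic-data generator.
#' Three base responses — dry weight (`dw_g_l`), intracellular paclitaxel per
#' gram dry weight (`intra_ug_g`) and extracellular paclitaxel (`extra_ug_l`)
#' — are each modeled as a baseline plus a separable Gaussian bump over the
#' four culture inputs (CE %, CF %, adding day, harvest day):
#' \deqn{f(x) = b + h \prod_j \exp\{-(x_j - m_j)^2 / (2 s_j^2)\}.}
#' The remaining responses are derived identities: intracellular per liter is
#' `intra_ug_g * dw_g_l`, total is intracellular per liter plus extracellular,
#' and the extracellular portion is `100 * extra / total`.
#'
#' @param dw,intra_g,extra Lists with elements `baseline`, `height`, `center`
#'   (length-4, on the input scale) and `width` (length-4, positive).
#' @param noise_cv Relative standard deviation of the multiplicative Gaussian
#'   noise applied by [simulate_dataset()]; non-negative.
#' @return An object of class `true_surface`.
#' @export
true_surface <- function(dw, intra_g, extra, noise_cv = 0.1) {
  check_bump <- function(b, nm) {
    need <- c("baseline", "height", "center", "width")
    if (!is.list(b) || !all(need %in% names(b))) {
      stopf("%s must be a list with baseline, height, center, width", nm)
    }
    if (length(b$center) != 4L || length(b$width) != 4L) {
      stopf("%s center and width must have length 4", nm)
    }
    if (b$height <= 0 || b$baseline < 0 || any(b$width <= 0)) {
      stopf("%s requires positive height/widths and non-negative baseline", nm)
    }
    b
  }
  if (noise_cv < 0) stopf("noise_cv must be >= 0")
  structure(
    list(dw = check_bump(dw, "dw"), intra_g = check_bump(intra_g, "intra_g"),
         extra = check_bump(extra, "extra"), noise_cv = noise_cv),
    class = "true_surface")
}

bump_eval <- function(b, X) {
  v <- rep(1, nrow(X))
  for (j in 1:4) v <- v * exp(-0.5 * ((X[, j] - b$center[j]) / b$width[j])^2)
  b$baseline + b$height * v
}

#' Evaluate a true surface on a set of input points
#'
#' @param surface A `true_surface`.
#' @param newdata Data frame or matrix with columns `ce_pct`, `cf_pct`,
#'   `adding_day`, `harvest_day` (or four unnamed columns in that order).
#' @return Numeric matrix with one column per response (noise-free values).
#' @export
surface_eval <- function(surface, newdata) {
  stopifnot(inherits(surface, "true_surface"))
  df <- as.data.frame(newdata)
  if (all(input_names() %in% colnames(df))) {
    X <- as.matrix(df[, input_names()])
  } else if (ncol(df) >= 4L) {
    X <- as.matrix(df[, 1:4])
  } else {
    stopf("newdata must provide the four culture inputs")
  }
  dw <- bump_eval(surface$dw, X)
  intra_g <- bump_eval(surface$intra_g, X)
  extra <- bump_eval(surface$extra, X)
  intra_l <- intra_g * dw
  total <- intra_l + extra
  portion <- ifelse(total > 0, 100 * extra / total, 0)
  out <- cbind(dw, intra_g, intra_l, extra, total, portion)
  colnames(out) <- c("dw_g_l", "intra_ug_g", "intra_ug_l", "extra_ug_l",
                     "total_ug_l", "portion_pct")
  out
}

#' Default culture-input search box
#'
#' CE and CF from 0 to 10 percent v/v, adding day 13 to 17, harvest day 13 to
#' 23 (the feasibility constraint harvest > adding is enforced separately).
#'
#' @return A 4 x 2 matrix of `[lo, hi]` rows named by input.
#' @export
default_input_bounds <- function() {
  b <- rbind(ce_pct = c(0, 10), cf_pct = c(0, 10),
             adding_day = c(13, 17), harvest_day = c(13, 23))
  colnames(b) <- c("lo", "hi")
  b
}

# Dense feasible grid over the input box (harvest > adding enforced).
input_grid <- function(bounds = default_input_bounds(), resolution = 41) {
  g <- expand.grid(
    ce_pct = seq(bounds[1, 1], bounds[1, 2], length.out = resolution),
    cf_pct = seq(bounds[2, 1], bounds[2, 2], length.out = resolution),
    adding_day = seq(bounds[3, 1], bounds[3, 2], length.out = resolution),
    harvest_day = seq(bounds[4, 1], bounds[4, 2], length.out = resolution),
    KEEP.OUT.ATTRS = FALSE)
  g[g$harvest_day > g$adding_day, , drop = FALSE]
}

#' Grid-search argmax of a true surface (oracle)
#'
#' Dense grid search over the feasible input box; used as ground truth when
#' testing optimizer recovery.
#'
#' @param surface A `true_surface`.
#' @param response One of the six response names.
#' @param bounds Input box, 4 x 2 matrix (default [default_input_bounds()]).
#' @param resolution Grid points per dimension.
#' @return List with `par` (named input vector) and `value`.
#' @export
true_argmax <- function(surface, response = "total_ug_l",
                        bounds = default_input_bounds(), resolution = 41) {
  response <- match.arg(response, response_names())
  g <- input_grid(bounds, resolution)
  v <- surface_eval(surface, g)[, response]
  i <- which.max(v)
  list(par = unlist(g[i, , drop = TRUE]), value = unname(v[i]))
}

# Calibrate the intracellular bump height so that the grid maximum of total
# paclitaxel equals `target` (the configured peak height of the total-yield
# surface). Deterministic: fixed grid, fixed root-finder tolerance.
calibrate_total_peak <- function(surface, target, resolution = 41) {
  g <- input_grid(resolution = resolution)
  X <- as.matrix(g)
  dw <- bump_eval(surface$dw, X)
  ig <- bump_eval(surface$intra_g, X)
  ex <- bump_eval(surface$extra, X)
  f <- function(alpha) max(alpha * ig * dw + ex) - target
  alpha <- stats::uniroot(f, c(1e-3, 100), tol = 1e-10)$root
  surface$intra_g$baseline <- alpha * surface$intra_g$baseline
  surface$intra_g$height <- alpha * surface$intra_g$height
  surface
}

#' Default calibrated response surface
#'
#' Bump centers follow the optimum region reported for elicited hazel cell
#' cultures (CE near 4.3 % v/v, CF near 5.4 % v/v, elicitor added around day
#' 16, harvest around day 20-22); the dry-weight and extracellular peaks are
#' 12.57 g/l and 152.15 ug/l, and the intracellular bump is calibrated, by a
#' deterministic grid root-finder, so the maximum total paclitaxel over the
#' input box equals 372.89 ug/l.
#'
#' @param noise_cv Relative noise standard deviation (default 0.10).
#' @return A calibrated `true_surface`.
#' @export
default_surface <- function(noise_cv = 0.1) {
  key <- "default_surface"
  if (is.null(.grnnfoa_cache[[key]])) {
    s <- true_surface(
      dw = list(baseline = 3.0, height = 9.57,
                center = c(4.26, 0.54, 16.33, 20.58),
                width = c(3.0, 4.5, 2.5, 2.8)),
      intra_g = list(baseline = 1.5, height = 18.26,
                     center = c(4.12, 5.84, 15.72, 20.34),
                     width = c(2.4, 2.8, 2.5, 2.8)),
      extra = list(baseline = 2.0, height = 150.15,
                   center = c(4.58, 4.71, 15.91, 22.06),
                   width = c(2.5, 2.5, 2.8, 2.2)),
      noise_cv = 0)
    .grnnfoa_cache[[key]] <- calibrate_total_peak(s, target = 372.89)
  }
  s <- .grnnfoa_cache[[key]]
  s$noise_cv <- noise_cv
  s
}
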