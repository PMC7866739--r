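#' Simulate an elicitation dataset
#'
#' Evaluates a ground-truth surface on every run of a design and applies
#' multiplicative Gaussian noise, `y = f(x) * (1 + e)`, `e ~ N(0, noise_cv)`,
#' independently to each response, clipping at zero. At zero noise the
#' identity chain holds exactly on every row: intracellular per liter equals
#' intracellular per gram times dry weight, total equals intracellular per
#' liter plus extracellular, and the portion is `100 * extra / total`.
#'
#' @param design A `design_spec` (default [default_design()]).
#' @param surface A `true_surface` (default [default_surface()]).
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @param noise_cv Optional override of the surface's noise level.
#' @return A data frame of class `elicitation_dataset`: four input columns,
#'   six response columns, plus `replicate` and `arm`. Attributes record the
#'   seed and noise level.
#' @export
simulate_dataset <- function(design = default_design(),
                             surface = default_surface(), seed = 1,
                             noise_cv = NULL) {
  stopifnot(inherits(design, "design_spec"), inherits(surface, "true_surface"))
  cv <- if (is.null(noise_cv)) surface$noise_cv else noise_cv
  if (cv < 0) stopf("noise_cv must be >= 0")
  grid <- design_grid(design)
  truth <- surface_eval(surface, grid)
  noisy <- withr::with_seed(as.integer(seed), {
    e <- matrix(stats::rnorm(length(truth), sd = cv), nrow(truth), ncol(truth))
    pmax(truth * (1 + e), 0)
  })
  out <- cbind(grid[, input_names()], as.data.frame(noisy),
               grid[, c("replicate", "arm")])
  rownames(out) <- NULL
  structure(out, seed = as.integer(seed), noise_cv = cv,
            class = c("elicitation_dataset", "data.frame"))
}

#' Write / read an elicitation dataset as CSV
#'
#' The interchange format is a plain CSV with the documented header
#' `ce_pct, cf_pct, adding_day, harvest_day, dw_g_l, intra_ug_g, intra_ug_l,
#' extra_ug_l, total_ug_l, portion_pct` (extra columns such as `replicate`
#' are preserved). Comment lines starting with `#` carry provenance.
#'
#' @param x Dataset (data frame with the documented columns).
#' @param path File path.
#' @param provenance Optional named list written as `# key: value` header
#'   comments.
#' @return `write_dataset` returns `path` invisibly; `read_dataset` returns a
#'   validated `elicitation_dataset`.
#' @export
write_dataset <- function(x, path, provenance = NULL) {
  validate_dataset(x)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) {
    for (k in names(provenance)) {
      writeLines(sprintf("# %s: %s", k, provenance[[k]]), con)
    }
  }
  utils::write.csv(as.data.frame(x), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stopf("dataset file not found: %s", path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  validate_dataset(df)
  structure(df, class = c("elicitation_dataset", "data.frame"))
}

#' Validate the dataset schema
#'
#' Checks the documented columns exist, are numeric, finite and non-negative,
#' and that harvest days exceed adding days. Errors name the offending column
#' or rows.
#'
#' @param x Data frame to check.
#' @return `x` invisibly.
#' @export
validate_dataset <- function(x) {
  x <- as.data.frame(x)
  missing_cols <- setdiff(dataset_columns(), colnames(x))
  if (length(missing_cols) > 0) {
    stopf("dataset is missing required column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  for (col in dataset_columns()) {
    v <- x[[col]]
    if (!is.numeric(v)) stopf("column %s must be numeric", col)
    if (anyNA(v) || any(!is.finite(v))) {
      stopf("column %s contains missing or non-finite values (e.g. row %d)",
            col, which(!is.finite(v))[1])
    }
  }
  for (col in response_names()) {
    if (any(x[[col]] < 0)) stopf("column %s must be non-negative", col)
  }
  bad <- which(x$harvest_day <= x$adding_day)
  if (length(bad) > 0) {
    stopf("harvest_day must exceed adding_day (violated at row %d)", bad[1])
  }
  invisible(x)
}

#' Hours elapsed between elicitation and harvest
#'
#' Harvest time is encoded as a culture day; the elapsed exposure is
#' `(harvest_day - adding_day) * 24` hours.
#'
#' @param adding_day,harvest_day Culture days.
#' @return Hours post-elicitation.
#' @export
hours_post_elicitation <- function(adding_day, harvest_day) {
  (harvest_day - adding_day) * 24
}
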