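#' Construct an elicitation experiment design
#'
#' Describes a factorial elicitation experiment on a plant cell suspension
#' culture: fungal elicitor blends of cell extract (CE) and culture filtrate
#' (CF) at several total doses, added on chosen culture days, with cultures
#' harvested at intervals after elicitation.
#'
#' @param elicitor_ratios Numeric vector of CE fractions of the total elicitor
#'   dose (e.g. `1` is pure CE, `0` pure CF).
#' @param dose_levels Total elicitor doses, percent v/v; all must be positive.
#' @param adding_days Culture days on which the elicitor is added.
#' @param harvest_days Named list, one entry per adding day, giving the harvest
#'   (culture) days for cultures elicited on that day. Every harvest day must
#'   exceed its adding day and not exceed `max_day`.
#' @param replicates Number of replicate flasks per treatment combination.
#' @param include_controls If `TRUE`, control arms (water/broth instead of
#'   elicitor, i.e. zero CE and CF) are added for every dose/adding/harvest
#'   combination.
#' @param max_day Last culture day on which harvesting is allowed.
#'
#' @return An object of class `design_spec`.
#' @seealso [default_design()], [design_grid()]
#' @export
elicitation_design <- function(elicitor_ratios, dose_levels, adding_days,
                               harvest_days, replicates = 3,
                               include_controls = FALSE, max_day = 23) {
  if (!is.numeric(elicitor_ratios) || any(elicitor_ratios < 0) ||
      any(elicitor_ratios > 1)) {
    stopf("elicitor_ratios must be CE fractions in [0, 1]")
  }
  if (!is.numeric(dose_levels) || any(dose_levels <= 0)) {
    stopf("all dose levels must be > 0")
  }
  if (!is_count(replicates)) stopf("replicates must be a positive integer")
  if (!is.list(harvest_days) || length(harvest_days) != length(adding_days)) {
    stopf("harvest_days must be a list with one entry per adding day")
  }
  for (i in seq_along(adding_days)) {
    h <- harvest_days[[i]]
    if (any(h <= adding_days[i])) {
      stopf("harvest days must be strictly greater than adding day %s",
            adding_days[i])
    }
    if (any(h > max_day)) stopf("harvest days must not exceed day %s", max_day)
  }
  structure(
    list(elicitor_ratios = elicitor_ratios, dose_levels = dose_levels,
         adding_days = adding_days,
         harvest_days = stats::setNames(harvest_days, adding_days),
         replicates = as.integer(replicates),
         include_controls = isTRUE(include_controls),
         max_day = max_day),
    class = "design_spec")
}

#' Default factorial elicitation design
#'
#' The reference design: five CE:CF blend ratios (100:0, 75:25, 50:50, 25:75,
#' 0:100), three total doses (2.5, 5 and 10 percent v/v), elicitor added at
#' mid (day 13) or late (day 17) log phase, and harvests every two days after
#' elicitation through culture day 23, with three replicates. The elicitor
#' arms of this grid contain 5 x 3 x (5 + 3) x 3 = 360 runs.
#'
#' @param replicates Replicate flasks per treatment (default 3).
#' @param include_controls Add water/broth control arms mapping to zero CE and
#'   CF (default `FALSE`, since controls collapse onto a single input point).
#' @return A `design_spec`.
#' @export
default_design <- function(replicates = 3, include_controls = FALSE) {
  adding <- c(13, 17)
  harvests <- lapply(adding, function(a) seq(a + 2, 23, by = 2))
  elicitation_design(
    elicitor_ratios = c(1, 0.75, 0.5, 0.25, 0),
    dose_levels = c(2.5, 5, 10),
    adding_days = adding,
    harvest_days = harvests,
    replicates = replicates,
    include_controls = include_controls)
}

#' Expand a design into its experimental runs
#'
#' @param design A `design_spec`.
#' @return A data frame with one row per run: `ce_pct`, `cf_pct`,
#'   `adding_day`, `harvest_day`, `replicate` and `arm` ("elicitor" or
#'   "control"). Control runs carry zero CE and CF.
#' @export
design_grid <- function(design) {
  stopifnot(inherits(design, "design_spec"))
  cells <- list()
  for (a in design$adding_days) {
    h <- design$harvest_days[[as.character(a)]]
    cells[[length(cells) + 1L]] <- expand.grid(
      ratio = design$elicitor_ratios, dose = design$dose_levels,
      adding_day = a, harvest_day = h, replicate = seq_len(design$replicates),
      KEEP.OUT.ATTRS = FALSE)
  }
  g <- do.call(rbind, cells)
  out <- data.frame(
    ce_pct = g$dose * g$ratio,
    cf_pct = g$dose * (1 - g$ratio),
    adding_day = g$adding_day,
    harvest_day = g$harvest_day,
    replicate = g$replicate,
    arm = "elicitor",
    stringsAsFactors = FALSE)
  if (design$include_controls) {
    ctl <- out
    ctl$ce_pct <- 0
    ctl$cf_pct <- 0
    ctl$arm <- "control"
    out <- rbind(out, ctl)
  }
  rownames(out) <- NULL
  out
}
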