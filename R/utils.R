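#' @keywords internal
"_PACKAGE"

# Input names used throughout: the four culture inputs, in fixed order.
input_names <- function() c("ce_pct", "cf_pct", "adding_day", "harvest_day")

# Response names in fixed order: dry weight, intracellular (per g DW and per l),
# extracellular, total paclitaxel, extracellular portion.
response_names <- function() {
  c("dw_g_l", "intra_ug_g", "intra_ug_l", "extra_ug_l", "total_ug_l",
    "portion_pct")
}

dataset_columns <- function() c(input_names(), response_names())

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

as_bounds_matrix <- function(bounds, d = NULL) {
  if (is.list(bounds)) bounds <- do.call(rbind, bounds)
  if (is.vector(bounds) && length(bounds) == 2L) bounds <- matrix(bounds, 1L)
  bounds <- as.matrix(bounds)
  if (ncol(bounds) != 2L) stopf("bounds must be a d x 2 matrix of [lo, hi]")
  if (!all(is.finite(bounds))) stopf("bounds must be finite")
  if (any(bounds[, 1] >= bounds[, 2])) stopf("each bound must satisfy lo < hi")
  if (!is.null(d) && nrow(bounds) != d) {
    stopf("bounds has %d rows; expected %d", nrow(bounds), d)
  }
  unname(bounds)
}

# Pairwise squared Euclidean distances between rows of A (n x d) and B (m x d).
pairwise_sqdist <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  D2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  D2[D2 < 0] <- 0
  D2
}

# Stable md5 of any jsonlite-serializable R object, used for provenance stamps.
object_hash <- function(x) {
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(json, tmp)
  unname(tools::md5sum(tmp))
}
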