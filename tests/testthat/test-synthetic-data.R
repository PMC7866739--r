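test_that("the default factorial design matches the reference experiment", {
  design <- default_design()
  expect_setequal(design$dose_levels, c(2.5, 5, 10))
  expect_equal(design$harvest_days[["13"]], c(15, 17, 19, 21, 23))
  expect_equal(design$harvest_days[["17"]], c(19, 21, 23))
  g <- design_grid(design)
  # 5 ratios x 3 doses x (5 + 3) harvests x 3 replicates
  expect_equal(nrow(g), 360)
  expect_true(all(g$harvest_day > g$adding_day))
  # control arms map onto zero elicitor input
  gc <- design_grid(default_design(include_controls = TRUE))
  expect_equal(nrow(gc), 720)
  expect_true(all(gc$ce_pct[gc$arm == "control"] == 0))
  expect_true(all(gc$cf_pct[gc$arm == "control"] == 0))
})

test_that("invalid designs are rejected", {
  expect_error(
    elicitation_design(0.5, 5, adding_days = 17, harvest_days = list(16),
                       replicates = 1),
    "strictly greater")
  expect_error(
    elicitation_design(0.5, 5, adding_days = 13, harvest_days = list(25),
                       replicates = 1),
    "exceed")
  expect_error(
    elicitation_design(0.5, -1, adding_days = 13, harvest_days = list(15),
                       replicates = 1),
    "dose")
})

test_that("response identities hold exactly on noise-free data", {
  d <- simulate_dataset(seed = 3, noise_cv = 0)
  expect_equal(d$intra_ug_l, d$intra_ug_g * d$dw_g_l, tolerance = 1e-12)
  expect_lt(max(abs(d$total_ug_l - d$intra_ug_l - d$extra_ug_l)), 1e-9)
  expect_equal(d$portion_pct, 100 * d$extra_ug_l / d$total_ug_l,
               tolerance = 1e-12)
  expect_true(all(as.matrix(d[, c("dw_g_l", "intra_ug_g", "intra_ug_l",
                                  "extra_ug_l", "total_ug_l",
                                  "portion_pct")]) >= 0))
})

test_that("simulation is deterministic under a seed and responsive to it", {
  d1 <- simulate_dataset(seed = 7)
  d2 <- simulate_dataset(seed = 7)
  d3 <- simulate_dataset(seed = 8)
  expect_identical(d1, d2)
  expect_false(isTRUE(all.equal(d1$dw_g_l, d3$dw_g_l)))
  expect_true(all(as.matrix(d1[, 5:10]) >= 0))
})

test_that("empirical replicate noise matches the configured CV", {
  one_cell <- elicitation_design(
    elicitor_ratios = 0.5, dose_levels = 5, adding_days = 13,
    harvest_days = list(19), replicates = 1000)
  d <- simulate_dataset(one_cell, default_surface(0.1), seed = 11)
  cv_hat <- sd(d$dw_g_l) / mean(d$dw_g_l)
  expect_gt(cv_hat, 0.08)
  expect_lt(cv_hat, 0.12)
})

test_that("the default surface's total-yield peak matches its calibration", {
  am <- true_argmax(default_surface(0), "total_ug_l", resolution = 41)
  expect_equal(am$value, 372.89, tolerance = 0.005)
})

test_that("grid-search argmax recovers randomized peak locations", {
  bounds <- default_input_bounds()
  res <- 21
  steps <- (bounds[, 2] - bounds[, 1]) / (res - 1)
  for (s in 1:10) {
    peak <- withr::with_seed(s, c(runif(2, 2, 8), runif(1, 14, 16),
                                  runif(1, 18, 22)))
    am <- true_argmax(recovery_surface(peak = peak), "total_ug_l",
                      resolution = res)
    expect_true(all(abs(am$par - peak) <= steps + 1e-9),
                info = paste("seed", s))
  }
})

test_that("a near-constant surface reports its constant value", {
  s <- recovery_surface(width = rep(1e6, 4))
  am <- true_argmax(s, "dw_g_l", resolution = 11)
  expect_equal(am$value, 3 + 9.57, tolerance = 1e-6)
})

test_that("datasets round-trip through CSV and schema errors name columns", {
  d <- simulate_dataset(seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset(d, path, provenance = list(seed = 2))
  d2 <- read_dataset(path)
  expect_equal(as.data.frame(d)[, 1:10], as.data.frame(d2)[, 1:10],
               tolerance = 1e-12)

  broken <- as.data.frame(d)
  broken$cf_pct <- NULL
  bad_path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(broken, bad_path, row.names = FALSE)
  expect_error(read_dataset(bad_path), "cf_pct")
})
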