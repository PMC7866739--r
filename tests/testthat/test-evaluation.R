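small_study <- function() fixture("small_study", function() {
  design <- default_design(replicates = 1)
  d <- simulate_dataset(design, default_surface(0.1), seed = 2)
  cfg <- pipeline_config(responses = c("dw_g_l", "total_ug_l"),
                         cv_repeats = 3, seed = 2,
                         foa = foa_config(maxgen = 40, seed = 2))
  list(dataset = d, config = cfg,
       pipeline = evaluate_pipeline(d, cfg))
})

test_that("FOA-tuned sigma matches an exhaustive grid within tolerance", {
  d <- surface_dataset(recovery_surface(), lhs_inputs(150, seed = 3))
  X <- as.matrix(d[, c("ce_pct", "cf_pct", "adding_day", "harvest_day")])
  z <- boxcox_apply(boxcox_fit(d$total_ug_l), d$total_ug_l)
  plan <- make_cv_plan(nrow(X), seed = 3)
  tn <- tune_sigma_foa(X, z, plan, foa = foa_config(seed = 3))
  grid <- exp(seq(log(1e-3), log(10), length.out = 200))
  best_grid <- min(vapply(grid, tn$objective, numeric(1)))
  expect_lte(tn$cv_rmse, 1.05 * best_grid)
  # reproducible under the same seed
  tn2 <- tune_sigma_foa(X, z, plan, foa = foa_config(seed = 3))
  expect_identical(tn$sigma, tn2$sigma)
})

test_that("pure-noise targets drive sigma toward the flat-kernel limit", {
  inst <- withr::with_seed(8, list(X = matrix(runif(400), 100, 4),
                                   y = rnorm(100)))
  plan <- make_cv_plan(100, seed = 8)
  tn <- tune_sigma_foa(inst$X, inst$y, plan, foa = foa_config(seed = 8))
  # the flat-kernel (mean predictor) CV RMSE approaches the target SD
  expect_lt(abs(tn$cv_rmse - sd(inst$y)) / sd(inst$y), 0.15)
  expect_gt(tn$sigma, 1)
})

test_that("near-zero bandwidth interpolates noise-free training data", {
  d <- simulate_dataset(default_design(replicates = 1), default_surface(0),
                        seed = 1)
  X <- as.matrix(d[, c("ce_pct", "cf_pct", "adding_day", "harvest_day")])
  m <- grnn_fit(X, d$total_ug_l, sigma = 1e-5)
  fit <- compute_metrics(d$total_ug_l, predict(m, X))
  expect_gt(fit$r2, 1 - 1e-10)
})

test_that("the fitted pipeline reports coherent per-response summaries", {
  st <- small_study()
  p <- st$pipeline
  expect_s3_class(p, "grnnfoa_pipeline")
  expect_named(p$models, c("dw_g_l", "total_ug_l"))
  expect_equal(nrow(p$metrics), 4)  # 2 responses x {training, testing}
  expect_true(all(p$metrics$rmse >= 0))
  expect_true(all(p$metrics$r2 <= 1))
  expect_true(all(p$metrics$rmse^2 >= p$metrics$mbe^2))
  # training (near-resubstitution) error is no worse than held-out error
  tr <- p$metrics[p$metrics$subset == "training", ]
  te <- p$metrics[p$metrics$subset == "testing", ]
  expect_true(all(tr$rmse <= te$rmse))
  # one sigma per response, shared across folds
  expect_gt(p$models$total_ug_l$sigma, 0)
  expect_match(p$provenance$config_hash, "^[a-f0-9]{32}$")
})

test_that("refitting with an identical configuration replays exactly", {
  st <- small_study()
  p2 <- evaluate_pipeline(st$dataset, st$config)
  expect_equal(st$pipeline$metrics, p2$metrics, tolerance = 1e-15)
  expect_identical(st$pipeline$models$total_ug_l$sigma,
                   p2$models$total_ug_l$sigma)
  q <- c(4, 5, 15, 20)
  expect_identical(predict_response(st$pipeline, "total_ug_l", q),
                   predict_response(p2, "total_ug_l", q))
})

test_that("prediction from a serialized pipeline replays exactly", {
  st <- small_study()
  path <- withr::local_tempfile(fileext = ".json")
  pipeline_to_json(st$pipeline, path)
  p2 <- pipeline_from_json(path)
  q <- rbind(c(4, 5, 15, 20), c(1, 1, 13.5, 22))
  expect_equal(predict_response(st$pipeline, "dw_g_l", q),
               predict_response(p2, "dw_g_l", q), tolerance = 1e-12)
})
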