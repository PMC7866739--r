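test_that("Box-Cox transform reproduces its closed-form special cases", {
  st0 <- structure(list(lambda = 0, shift = 0), class = "boxcox_state")
  expect_equal(boxcox_apply(st0, exp(1)), 1)
  expect_equal(boxcox_invert(st0, 1), exp(1))
  st1 <- structure(list(lambda = 1, shift = 0), class = "boxcox_state")
  expect_equal(boxcox_apply(st1, 4), 3)
  st05 <- structure(list(lambda = 0.5, shift = 0), class = "boxcox_state")
  expect_equal(boxcox_apply(st05, 4), 2 * (sqrt(4) - 1))
})

test_that("fitted lambda agrees with the profile-likelihood oracle", {
  skip_if_not_installed("MASS")
  y <- withr::with_seed(5, exp(rnorm(500)))
  st <- boxcox_fit(y)
  # log-normal data transform to normality at lambda = 0
  expect_lt(abs(st$lambda), 0.15)
  # independent oracle: MASS profile likelihood on an intercept-only model
  prof <- MASS::boxcox(y ~ 1, data = data.frame(y = y),
                       lambda = seq(-1, 1, 0.001), plotit = FALSE)
  expect_lt(abs(st$lambda - prof$x[which.max(prof$y)]), 0.01)
})

test_that("Box-Cox round trip is the identity and range errors are caught", {
  for (s in 1:5) {
    y <- withr::with_seed(s, rgamma(100, shape = 2, scale = 3))
    st <- boxcox_fit(y)
    expect_lt(max(abs(boxcox_invert(st, boxcox_apply(st, y)) - y)), 1e-10)
  }
  # values <= 0 trigger a shift that keeps the transform invertible
  y <- withr::with_seed(6, rnorm(50))
  st <- boxcox_fit(y)
  expect_equal(st$shift, 1 - min(y))
  expect_lt(max(abs(boxcox_invert(st, boxcox_apply(st, y)) - y)), 1e-10)
  # inversion outside the transform's range errors
  st2 <- structure(list(lambda = -1, shift = 0), class = "boxcox_state")
  expect_error(boxcox_invert(st2, 5), "range")
  expect_error(boxcox_fit(rep(3, 10)), "distinct")
})

test_that("input standardization uses training statistics only", {
  X <- withr::with_seed(2, matrix(rnorm(200, mean = 5, sd = 3), 50, 4))
  st <- scaling_fit(X)
  Z <- scaling_apply(st, X)
  expect_lt(max(abs(colMeans(Z))), 1e-10)
  expect_lt(max(abs(apply(Z, 2, sd) - 1)), 1e-10)
  # a held-out row is transformed with the stored statistics
  q <- rep(5, 4)
  expect_equal(as.numeric(scaling_apply(st, matrix(q, 1))),
               (q - st$mean) / st$sd)
  expect_error(scaling_fit(matrix(1, 5, 2)), "standard deviation")
})

test_that("outlier screen is quiet on clean data and catches gross corruption", {
  d <- simulate_dataset(seed = 1)
  tab <- as.data.frame(d)[, c("ce_pct", "cf_pct", "adding_day", "harvest_day",
                              "dw_g_l", "intra_ug_g", "intra_ug_l",
                              "extra_ug_l", "total_ug_l", "portion_pct")]
  # screen on the modeling scale, as the pipeline does
  for (r in c("dw_g_l", "intra_ug_g", "intra_ug_l", "extra_ug_l",
              "total_ug_l", "portion_pct")) {
    tab[[r]] <- boxcox_apply(boxcox_fit(tab[[r]]), tab[[r]])
  }
  expect_length(pca_outliers(tab), 0)

  corrupted <- tab
  corrupted[100, ] <- corrupted[100, ] * 50
  expect_true(100 %in% pca_outliers(corrupted))
})

test_that("outlier flags are invariant to column rescaling", {
  d <- simulate_dataset(seed = 4)
  tab <- as.data.frame(d)[, 1:10]
  tab[57, ] <- tab[57, ] * 40
  f1 <- pca_outliers(tab)
  tab2 <- tab
  tab2$total_ug_l <- tab2$total_ug_l * 1000
  f2 <- pca_outliers(tab2)
  expect_equal(as.integer(f1), as.integer(f2))
  expect_error(pca_outliers(tab[1:5, ]), "10 rows")
})

test_that("cross-validation plans partition the rows reproducibly", {
  plan <- make_cv_plan(10, k = 5, repeats = 3, seed = 2)
  for (r in 1:3) {
    expect_equal(as.vector(table(plan$assignments[, r])), rep(2, 5))
  }
  # identical under the same seed, bit for bit
  expect_identical(plan, make_cv_plan(10, k = 5, repeats = 3, seed = 2))
  # fold sizes differ by at most one when k does not divide n
  plan2 <- make_cv_plan(13, k = 5, repeats = 2, seed = 1)
  sizes <- table(plan2$assignments[, 1])
  expect_lte(max(sizes) - min(sizes), 1)
  expect_error(make_cv_plan(4, k = 5), "at least as many rows")
})

test_that("the reference plan yields 50 distinct training masks", {
  plan <- make_cv_plan(360, k = 5, repeats = 10, seed = 1)
  masks <- vapply(grnnfoa:::cv_folds(plan), function(f) {
    paste(sort(f$test), collapse = ",")
  }, character(1))
  expect_length(masks, 50)
  expect_length(unique(masks), 50)
})
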