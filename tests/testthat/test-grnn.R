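test_that("predictions reproduce hand-computed kernel-regression values", {
  # single stored pattern: weights normalize to the lone target
  m1 <- grnn_fit(matrix(1.7), 4.2, sigma = 0.3, standardize = FALSE)
  expect_equal(predict(m1, 9), 4.2)
  expect_equal(predict(m1, 1.7), 4.2)
  # two symmetric patterns: midpoint query returns the midpoint value
  m2 <- grnn_fit(matrix(c(0, 2)), c(0, 2), sigma = 1, standardize = FALSE)
  expect_equal(predict(m2, 1), 1)
  # hand-computed Nadaraya-Watson value at query 0.5:
  # p = (exp(-0.125), exp(-1.125)) = (0.8824969, 0.3246525),
  # prediction 2 * 0.3246525 / 1.2071494 = 0.5378828
  expect_equal(predict(m2, 0.5), 0.5378828, tolerance = 1e-6)
  expect_equal(predict(m2, 0.5), 0.53789, tolerance = 1e-4)
})

test_that("predictions match the direct double-loop oracle", {
  for (s in 1:25) {
    inst <- withr::with_seed(s, {
      n <- sample(5:50, 1); d <- sample(1:4, 1)
      list(X = matrix(runif(n * d), n, d), y = runif(n, 0, 10),
           sigma = runif(1, 0.3, 3), Q = matrix(runif(8 * d), 8, d))
    })
    m <- grnn_fit(inst$X, inst$y, inst$sigma, standardize = FALSE)
    expect_lt(max(abs(predict(m, inst$Q) -
                        naive_grnn(inst$X, inst$y, inst$sigma, inst$Q))),
              1e-10)
  }
})

test_that("bandwidth limits give interpolation and the target mean", {
  inst <- withr::with_seed(3, list(X = matrix(runif(80), 20, 4),
                                   y = runif(20, -5, 5)))
  m_small <- grnn_fit(inst$X, inst$y, sigma = 1e-6, standardize = FALSE)
  expect_equal(predict(m_small, inst$X), inst$y, tolerance = 1e-12)
  m_big <- grnn_fit(inst$X, inst$y, sigma = 1e6, standardize = FALSE)
  q <- matrix(runif(20), 5, 4)
  expect_lt(max(abs(predict(m_big, q) - mean(inst$y))), 1e-6)
})

test_that("predictions are convex combinations of the training targets", {
  for (s in 1:10) {
    inst <- withr::with_seed(100 + s, {
      list(X = matrix(rnorm(120), 30, 4), y = rnorm(30, sd = 4),
           sigma = 10^runif(1, -2, 2), Q = matrix(rnorm(40, sd = 2), 10, 4))
    })
    m <- grnn_fit(inst$X, inst$y, inst$sigma)
    p <- suppressWarnings(predict(m, inst$Q))
    expect_true(all(p >= min(inst$y) - 1e-12 & p <= max(inst$y) + 1e-12))
  }
})

test_that("permuting the training rows leaves predictions unchanged", {
  inst <- withr::with_seed(9, list(X = matrix(runif(100), 25, 4),
                                   y = runif(25)))
  perm <- withr::with_seed(10, sample(25))
  q <- matrix(runif(12), 3, 4)
  m1 <- grnn_fit(inst$X, inst$y, 0.7)
  m2 <- grnn_fit(inst$X[perm, ], inst$y[perm], 0.7)
  expect_equal(predict(m1, q), predict(m2, q), tolerance = 1e-12)
})

test_that("far queries at tiny bandwidth fall back to the nearest pattern", {
  m <- grnn_fit(matrix(c(0, 1)), c(5, 7), sigma = 1e-3, standardize = FALSE)
  expect_warning(p <- predict(m, 100), "underflow")
  expect_equal(p, 7)
})

test_that("models serialize to JSON and replay exactly", {
  inst <- withr::with_seed(12, list(X = matrix(rnorm(60), 15, 4),
                                    y = rnorm(15)))
  m <- grnn_fit(inst$X, inst$y, 0.5)
  m2 <- grnn_from_json(grnn_to_json(m))
  q <- matrix(rnorm(20), 5, 4)
  expect_equal(predict(m, q), predict(m2, q), tolerance = 1e-12)
})

test_that("fitting rejects degenerate inputs", {
  expect_error(grnn_fit(matrix(numeric(0), 0, 2), numeric(0), 1), "no training")
  expect_error(grnn_fit(matrix(1:4, 2), c(1, 2), sigma = 0), "positive")
  expect_error(grnn_fit(matrix(c(1, NA, 3, 4), 2), c(1, 2), 1), "finite")
  m <- grnn_fit(matrix(1:6, 3, 2), 1:3, 1)
  expect_error(predict(m, matrix(1:3, 1)), "expects")
})
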