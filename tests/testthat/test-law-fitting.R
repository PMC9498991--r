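test_that("noiseless data recover each generating law exactly", {
  x <- seq(0, 5, by = 0.5)
  lin <- fit_law(x, -11.72 * x + 61.55, "linear")
  expect_equal(unname(lin$params), c(-11.72, 61.55), tolerance = 1e-9)
  expect_equal(lin$r2, 1)
  expect_lt(lin$sse, 1e-18)

  m <- seq(0, 28, by = 2)
  ex <- fit_law(m, 62.2 * exp(-0.107 * m), "exponential")
  expect_equal(ex$params[["a"]], 62.2, tolerance = 1e-6)
  expect_equal(ex$params[["b"]], -0.107, tolerance = 1e-6)

  pw <- fit_law(1:10, 3 * (1:10)^0.7, "power")
  expect_equal(unname(pw$params), c(3, 0.7), tolerance = 1e-6)

  qd <- fit_law(x, 2 * x^2 - 3 * x + 1, "quadratic")
  expect_equal(unname(qd$params), c(2, -3, 1), tolerance = 1e-8)
})

test_that("constant response gives zero slope and zero r-squared", {
  f <- fit_law(1:10, rep(5, 10), "linear")
  expect_equal(f$params[["a1"]], 0)
  expect_equal(f$r2, 0)
})

test_that("proportional through-origin fit matches its closed form", {
  x <- seq(1, 42, length.out = 20)
  f <- fit_proportional(x, 1.422 * x)
  expect_equal(f$params[["a1"]], 1.422, tolerance = 1e-12)
  expect_equal(fit_proportional(1, 2)$params[["a1"]], 2)
  expect_equal(fit_proportional(c(1, -1), c(1, 1))$params[["a1"]], 0)
  expect_error(fit_proportional(c(0, 0), c(1, 2)), class = "rs_fit_error")
})

test_that("the linear fit agrees with the closed-form OLS oracle", {
  set.seed(14)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    x <- rnorm(n); y <- 2 + 3 * x + rnorm(n)
    f <- fit_law(x, y, "linear")
    # independent closed form
    slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    intercept <- mean(y) - slope * mean(x)
    expect_equal(f$params[["a1"]], slope, tolerance = 1e-9)
    expect_equal(f$params[["a2"]], intercept, tolerance = 1e-9)
    sse <- sum((y - intercept - slope * x)^2)
    expect_equal(f$sse, sse, tolerance = 1e-9)
    expect_equal(f$rmse, sqrt(sse / (n - 2)), tolerance = 1e-9)
    r2 <- 1 - sse / sum((y - mean(y))^2)
    expect_equal(f$r2_adjusted, 1 - (1 - r2) * (n - 1) / (n - 3),
                 tolerance = 1e-9)
  }
})

test_that("model selection identifies the generating law", {
  set.seed(3)
  x <- seq(0, 5, length.out = 40)
  y_lin <- 61.55 - 11.72 * x + rnorm(40, 0, 1)
  best <- select_best_law(x, y_lin)
  expect_equal(best$law, "linear")
  expect_false(best$complex_flag)

  m <- seq(0, 28, length.out = 40)          # response spans two decades
  y_exp <- 62.2 * exp(-0.107 * m) * exp(rnorm(40, 0, 0.03))
  best_e <- select_best_law(m, y_exp)
  expect_equal(best_e$law, "exponential")
  expect_false(best_e$complex_flag)

  y_noise <- rnorm(40)
  best_n <- select_best_law(x, abs(y_noise) + 0.1)
  expect_true(best_n$complex_flag)
})

test_that("domain and rank requirements raise typed errors", {
  expect_error(fit_law(1:5, c(1, 2, -1, 3, 2), "exponential"),
               class = "rs_domain_error")
  expect_error(fit_law(c(0, 1, 2), c(1, 2, 3), "power"),
               class = "rs_domain_error")
  expect_error(fit_law(rep(2, 5), 1:5, "linear"), class = "rs_fit_error")
  expect_error(fit_law(1:2, 1:2, "linear"),
               class = "rs_insufficient_data_error")
})

test_that("an irrelevant quadratic term does not raise adjusted r-squared", {
  set.seed(21)
  x <- seq(0, 5, length.out = 25)
  delta <- replicate(100, {
    y <- 10 - 2 * x + rnorm(25, 0, 1)
    fit_law(x, y, "quadratic")$r2_adjusted - fit_law(x, y, "linear")$r2_adjusted
  })
  expect_lt(mean(delta), 0.002)   # no expected gain from the extra term
})

test_that("95% confidence intervals cover the truth at the nominal rate", {
  set.seed(5)
  hits <- replicate(500, {
    x <- seq(0, 5, length.out = 20)
    y <- 61.55 - 11.72 * x + rnorm(20, 0, 2)
    ci <- fit_law(x, y, "linear")$ci95
    ci["a1", "lower"] <= -11.72 && -11.72 <= ci["a1", "upper"]
  })
  cover <- mean(hits)
  tol <- 3 * sqrt(0.95 * 0.05 / 500)
  expect_gt(cover, 0.95 - tol)
  expect_lt(cover, 0.95 + tol)
})
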