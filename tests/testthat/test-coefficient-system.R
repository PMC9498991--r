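test_that("coefficients derive from the bounded endpoint values", {
  k <- derive_coefficients(max_sf2 = 62.1, min_sf2 = 3.3,
                           max_mn24h = 27.44, max_h2ax24h = 13.62,
                           max_patmmax = 41.72, min_patmmax = 0)
  expect_equal(k$k0, 11.76, tolerance = 1e-9)
  expect_equal(k$k3, 41.72 / 5, tolerance = 1e-9)
  expect_equal(k$k4, 62.1 / 41.72, tolerance = 1e-9)
  k2b <- derive_coefficients(62.2, 3.3, 27.44, 13.62, 41.72)
  expect_equal(k2b$k1, 0.107, tolerance = 1e-3)
  expect_equal(derive_coefficients(60, 10, 20, 10, 40)$k0, 10)
  expect_error(derive_coefficients(60, 0, 20, 10, 40),
               class = "rs_domain_error")
  expect_error(derive_coefficients(60, 10, -1, 10, 40),
               class = "rs_domain_error")
  expect_error(derive_coefficients(10, 60, 20, 10, 40),
               class = "rs_domain_error")
})

test_that("the default coefficient set matches the fitted-law constants", {
  k <- default_coefficient_set()
  expect_equal(k$k0, 11.72, tolerance = 1e-12)
  expect_equal(k$k1, 0.107, tolerance = 1e-12)
  expect_equal(k$k2, 0.216, tolerance = 1e-12)
  expect_equal(k$k3, 6.78, tolerance = 1e-12)
})

test_that("closed-form predictions evaluate the published relations", {
  k <- default_coefficient_set()
  expect_equal(predict_endpoint("sf2_of_grade", 0, k), k$max_sf2)
  expect_equal(predict_endpoint("sf2_of_grade", 2, k), 38.11,
               tolerance = 1e-9)
  expect_equal(predict_endpoint("patm_of_grade", 5, k), 7.82,
               tolerance = 1e-9)
  expect_equal(predict_endpoint("mn_of_h2ax", 10, k), (0.216 / 0.107) * 10,
               tolerance = 1e-12)
  expect_equal(predict_endpoint("sf2_of_patm", 10, k), k$k4 * 10)
  expect_error(predict_endpoint("sf2_of_grade", 6, k),
               class = "rs_domain_error")
  expect_error(predict_endpoint("sf2_of_mn", -1, k),
               class = "rs_domain_error")
})

test_that("crossed-resolution chains are exact identities", {
  k <- default_coefficient_set()
  g <- seq(0, 5, length.out = 101)
  expect_equal(
    predict_endpoint("sf2_of_mn", predict_endpoint("mn_of_grade", g, k), k),
    predict_endpoint("sf2_of_grade", g, k), tolerance = 1e-9)
  expect_equal(
    predict_endpoint("sf2_of_h2ax",
                     predict_endpoint("h2ax_of_grade", g, k), k),
    predict_endpoint("sf2_of_grade", g, k), tolerance = 1e-9)
  # MN and H2AX inversions are consistent with their linear ratio
  h <- seq(0, k$max_h2ax24h, length.out = 50)
  expect_equal(predict_endpoint("mn_of_h2ax", h, k),
               (k$k2 / k$k1) * h, tolerance = 1e-9)
})

test_that("all closed forms are monotone in the documented direction", {
  k <- default_coefficient_set()
  g <- seq(0, 5, length.out = 60)
  expect_true(all(diff(predict_endpoint("sf2_of_grade", g, k)) < 0))
  expect_true(all(diff(predict_endpoint("patm_of_grade", g, k)) < 0))
  expect_true(all(diff(predict_endpoint("mn_of_grade", g[-60], k)) > 0))
  m <- seq(0, k$max_mn24h, length.out = 60)
  expect_true(all(diff(predict_endpoint("sf2_of_mn", m, k)) < 0))
  x <- seq(0, k$max_h2ax24h, length.out = 60)
  expect_true(all(diff(predict_endpoint("sf2_of_h2ax", x, k)) < 0))
})

test_that("the differential system is numerically consistent", {
  res <- check_ode_consistency(default_coefficient_set())
  expect_named(res, c("dsf2_dgrade", "dsf2_dmn", "dsf2_dh2ax",
                      "dpatm_dgrade", "dsf2_dpatm"))
  expect_true(all(res < 1e-6))
  # holds for arbitrary valid coefficient sets too
  set.seed(6)
  for (i in 1:5) {
    k <- derive_coefficients(max_sf2 = runif(1, 50, 90),
                             min_sf2 = runif(1, 1, 10),
                             max_mn24h = runif(1, 10, 40),
                             max_h2ax24h = runif(1, 5, 25),
                             max_patmmax = runif(1, 30, 60),
                             min_patmmax = runif(1, 0, 10))
    expect_true(all(check_ode_consistency(k) < 1e-6))
  }
})

test_that("the audit reports fitted-vs-derived discrepancies honestly", {
  k <- derive_coefficients(62.1, 3.3, 27.44, 13.62, 41.72, 7.82)
  g <- 0:5
  fits <- list(
    sf2_grade = fit_law(g, 61.55 - 11.72 * g, "linear"),
    patm_grade = fit_law(g, 41.72 - 6.78 * g, "linear"),
    sf2_patm = fit_proportional(1:40, 1.422 * (1:40))
  )
  audit <- audit_internal_consistency(k, fits)
  row_k0 <- audit[audit$quantity == "k0 vs |slope(SF2~grade)|", ]
  expect_equal(row_k0$rel_diff, abs(11.76 - 11.72) / 11.72,
               tolerance = 1e-6)
  expect_false(row_k0$flagged)
  # the published system's own inconsistency: k0/k3 = 1.73 vs fitted 1.422
  row_k4 <- audit[audit$quantity == "k0/k3 vs fitted proportionality", ]
  expect_equal(row_k4$derived, 11.76 / 6.78, tolerance = 1e-9)
  expect_true(row_k4$flagged)

  # identical inputs give zero discrepancies
  k_id <- derive_coefficients(61.55, 61.55 - 5 * 11.72,
                              log(61.55 / 2.95) / 0.107,
                              log(61.55 / 2.95) / 0.216, 41.72, 7.82)
  fits_id <- list(sf2_grade = fit_law(g, 61.55 - 11.72 * g, "linear"),
                  patm_grade = fit_law(g, 41.72 - 6.78 * g, "linear"))
  audit_id <- audit_internal_consistency(k_id, fits_id)
  expect_true(all(audit_id$rel_diff < 1e-9))
})
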