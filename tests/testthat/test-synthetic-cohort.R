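test_that("grade sampling respects the distribution contract", {
  expect_length(sample_grades(0), 0L)
  expect_true(all(sample_grades(500, grade_distribution(c(0, 0, 0, 1, 0, 0)),
                                seed = 1) == 3L))
  expect_error(grade_distribution(c(0.5, 0.5, 0.5, 0, 0, 0)),
               class = "rs_parameter_error")
  expect_error(sample_grades(-1), class = "rs_parameter_error")
  expect_identical(sample_grades(100, seed = 5), sample_grades(100, seed = 5))
  # empirical frequencies close to the configured ones (3 binomial SD)
  g <- sample_grades(20000, seed = 11)
  p <- c(0.65, 0.17, 0.10, 0.05, 0.025, 0.005)
  for (k in 0:5) {
    tol <- 3 * sqrt(p[k + 1] * (1 - p[k + 1]) / 20000)
    expect_lt(abs(mean(g == k) - p[k + 1]), tol)
  }
})

test_that("noiseless generation reproduces the latent laws exactly", {
  p <- noiseless_params()
  for (g in 1:4) {
    r <- simulate_record(g, "wildtype_like", p)
    expect_equal(r$sf2, law_sf2(g), tolerance = 1e-12)
    expect_equal(patmmax(r), law_patm(g), tolerance = 1e-12)
    expect_equal(r$mn_24h, law_mn(r$sf2), tolerance = 1e-9)
    expect_equal(r$h2ax_24h, law_h2ax(r$sf2), tolerance = 1e-9)
  }
  r0 <- simulate_record(0, "wildtype_like", p)
  expect_equal(r0$sf2, 62.1)               # radioresistant anchor
  expect_equal(patmmax(r0), 41.72)
  r2 <- simulate_record(2, "wildtype_like", p)
  expect_equal(r2$sf2, 38.11)              # 61.55 - 2 * 11.72
  expect_error(simulate_record(6, "wildtype_like", p),
               class = "rs_parameter_error")
})

test_that("genotype overrides reproduce the mutant phenotypes", {
  p <- noiseless_params()
  atm <- simulate_record(5, "atm_homozygous", p)
  expect_equal(atm$patm_10min, 0)
  expect_equal(atm$patm_1h, 0)
  expect_equal(atm$h2ax_24h, 0)
  expect_equal(atm$h2ax_10min, 0)
  expect_equal(atm$sf2, 3.3)
  lig4 <- simulate_record(5, "lig4_mutated", p)
  expect_equal(lig4$h2ax_10min, 80)        # 2 Gy x 40 DSB/Gy, normal recognition
  expect_gt(lig4$h2ax_24h, 30)             # gross repair defect
  expect_equal(patmmax(lig4), 41.72)       # normal ATM kinase activity
  expect_equal(lig4$sf2, 3.3)
  # "tiny" convention keeps ATM foci non-nil but small
  tiny <- simulate_record(5, "atm_homozygous",
                          noiseless_params(atm_h2ax_mode = "tiny"))
  expect_gt(tiny$h2ax_24h, 0)
  expect_lt(tiny$h2ax_24h, 1)
})

test_that("cohorts are deterministic in the master seed", {
  a <- simulate_cohort(80, seed = 123)
  b <- simulate_cohort(80, seed = 123)
  expect_identical(a$records, b$records)
  c2 <- simulate_cohort(80, seed = 124)
  expect_false(identical(a$records, c2$records))
  expect_equal(a$provenance$seed, 123)
  expect_error(simulate_cohort(0), class = "rs_parameter_error")
})

test_that("population endpoint trends are monotone in grade", {
  p <- ground_truth_params()
  set.seed(99)
  means <- sapply(0:4, function(g) {
    recs <- replicate(250, simulate_record(g, "wildtype_like", p),
                      simplify = FALSE)
    c(sf2 = mean(sapply(recs, `[[`, "sf2")),
      patm = mean(sapply(recs, patmmax)),
      mn = mean(sapply(recs, `[[`, "mn_24h")),
      h2ax = mean(sapply(recs, `[[`, "h2ax_24h")))
  })
  expect_true(all(diff(means["sf2", ]) < 0))
  expect_true(all(diff(means["patm", ]) < 0))
  expect_true(all(diff(means["mn", ]) > 0))
  expect_true(all(diff(means["h2ax", ]) > 0))
})

test_that("spontaneous micronuclei carry no grade information", {
  co <- simulate_cohort(4000, seed = 31)
  r <- cor(co$records$mn_spont, co$records$ctcae_grade)
  expect_lt(abs(r), 0.05)
})

test_that("grade-5 lines are split into ATM-like and LIG4-like phenotypes", {
  p <- ground_truth_params(grade_dist = grade_distribution(
    c(0.5, 0, 0, 0, 0, 0.5)))
  co <- simulate_cohort(400, p, seed = 17)
  g5 <- co$records[co$records$ctcae_grade == 5L, ]
  expect_true(all(g5$genotype %in% c("atm_homozygous", "lig4_mutated")))
  frac_atm <- mean(g5$genotype == "atm_homozygous")
  expect_gt(frac_atm, 0.6)   # default split is 80/20
  expect_lt(frac_atm, 0.95)
})

test_that("synthesised survival assays honour the LQ ground truth", {
  p <- ground_truth_params()
  a <- simulate_survival_assay(100, p, noiseless = TRUE)
  expect_equal(a$alpha, 0)
  expect_equal(a$beta, 0)
  expect_equal(a$colonies, a$seeded * a$plating_efficiency)
  # expectation check: PE 0.2, 1000 seeded, S = 0.5 -> 100 expected colonies
  b <- simulate_survival_assay(50, ground_truth_params(beta_alpha_ratio = 0),
                               doses = c(0, 2), seeded_cells = 1000,
                               pe = 0.2, noiseless = TRUE)
  expect_equal(b$colonies[2L], 100)
  # noiseless round trip through the LQ fitter recovers alpha and beta
  d <- simulate_survival_assay(44.93, p, doses = c(0, 1, 2, 4, 6),
                               seeded_cells = 1000, noiseless = TRUE)
  fit <- fit_lq_assay(d)
  expect_equal(fit$alpha, d$alpha, tolerance = 1e-6)
  expect_equal(fit$beta, d$beta, tolerance = 1e-6)
  expect_equal(fit$sf2, 44.93, tolerance = 1e-6)
  expect_error(simulate_survival_assay(0, p), class = "rs_parameter_error")
  expect_error(simulate_survival_assay(101, p), class = "rs_parameter_error")
})

test_that("pATM kinetics: radioresistant lines peak at 10 min", {
  p <- ground_truth_params()
  set.seed(7)
  for (i in 1:20) {
    r <- simulate_record(0, "wildtype_like", p)
    expect_lt(r$patm_1h, r$patm_10min)
    expect_equal(patmmax(r), max(r$patm_10min, r$patm_1h))
  }
  # some radiosensitive lines peak at 1 h instead
  set.seed(8)
  slow <- replicate(40, {
    r <- simulate_record(4, "wildtype_like", p)
    r$patm_1h >= r$patm_10min
  })
  expect_gt(mean(slow), 0.2)
  expect_lt(mean(slow), 0.8)
})
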