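# Competing-mortality probability engine: closed forms, risk multipliers,
# monotonicity and quadrature behaviour.

test_that("constant hazards match the closed-form solution", {
  expect_equal(ten_year_probability(constant_hazard(0.05), constant_hazard(0), 60),
               1 - exp(-0.5), tolerance = 1e-10)
  expect_equal(ten_year_probability(constant_hazard(0.01), constant_hazard(0.02), 60),
               closed_form_probability(0.01, 0.02, 10), tolerance = 1e-10)
  expect_equal(lifetime_probability(constant_hazard(0.01), constant_hazard(0.02),
                                    50, max_age = 110),
               closed_form_probability(0.01, 0.02, 60), tolerance = 1e-10)
  # no fracture hazard, no probability
  expect_equal(ten_year_probability(constant_hazard(0), constant_hazard(0.1), 60), 0)
  expect_equal(lifetime_probability(constant_hazard(0), constant_hazard(0), 50), 0)
  expect_error(lifetime_probability(constant_hazard(0.1), constant_hazard(0),
                                    70, max_age = 70), "max_age")
})

test_that("risk multipliers are products of relative risks, BMD and BMI terms", {
  cfg <- toy_risk_config()
  neutral <- risk_profile(70, "female", bmi = 25, tscore = 0)
  expect_equal(risk_multiplier(neutral, cfg, "hip"), 1)
  # two factors: prior fracture (2.0) x glucocorticoids (1.8) for hip
  two <- risk_profile(70, "female", prior_fracture = TRUE, glucocorticoids = TRUE)
  expect_equal(risk_multiplier(two, cfg, "hip"), 2.0 * 1.8)
  # BMD gradient: 2.6 per SD at T-score -2 gives 2.6^2
  bmd <- risk_profile(70, "female", tscore = -2)
  expect_equal(risk_multiplier(bmd, cfg, "hip"), 2.6^2)
  # an explicit 1.8 gradient check on the MOF pathway
  cfg18 <- risk_model_config(cfg$relative_risks,
                             gradient_of_risk = c(hip = 1.8, mof = 1.8),
                             hip_to_mof_ratio = cfg$hip_to_mof_ratio)
  expect_equal(risk_multiplier(bmd, cfg18, "mof"), 1.8^2, tolerance = 1e-12)
})

test_that("secondary osteoporosis is inactivated when BMD is entered", {
  cfg <- toy_risk_config()
  with_bmd <- risk_profile(70, "female", tscore = 0, secondary_osteoporosis = TRUE)
  expect_equal(risk_multiplier(with_bmd, cfg, "hip"), 1)
  without_bmd <- risk_profile(70, "female", secondary_osteoporosis = TRUE)
  expect_equal(risk_multiplier(without_bmd, cfg, "hip"), 1.6)
  # the config flag covers the other reading too
  cfg_off <- risk_model_config(cfg$relative_risks, cfg$gradient_of_risk,
                               secondary_osteoporosis_inactive_with_bmd = FALSE,
                               hip_to_mof_ratio = cfg$hip_to_mof_ratio)
  expect_equal(risk_multiplier(with_bmd, cfg_off, "hip"), 1.6)
})

test_that("MOF hazard is the hip hazard times the configured ratio", {
  m1 <- toy_country_model(ratio = 1)
  expect_equal(mof_hazard(m1, "female", c(55, 75)),
               predict_rate(m1$hip$female, c(55, 75)))
  m4 <- toy_country_model(ratio = 4)
  expect_equal(mof_hazard(m4, "male", 62), 4 * predict_rate(m4$hip$male, 62))
  no_ratio <- m4
  no_ratio$config$hip_to_mof_ratio <- NULL
  expect_error(mof_hazard(no_ratio, "female", 70), "ratio table")
})

test_that("hip hazard 2e-3 with ratio 4 gives MOF hazard 8e-3", {
  m <- toy_country_model(ratio = 4)
  # solve the piecewise model for the age where the female hip hazard is 2e-3
  f <- m$hip$female
  age <- f$knot_age + (log(2e-3) - f$intercept -
                         f$slope_pre * (f$knot_age - 40)) / f$slope_post
  expect_equal(predict_rate(f, age), 2e-3, tolerance = 1e-12)
  expect_equal(mof_hazard(m, "female", age), 8e-3, tolerance = 1e-12)
})

test_that("a neutral profile reproduces the baseline hazard integral", {
  m <- toy_country_model()
  neutral <- risk_profile(65, "female", bmi = 25)
  direct <- ten_year_probability(function(a) predict_rate(m$hip$female, a),
                                 fraxbuild:::death_hazard_fn(m, "female"), 65)
  expect_equal(fracture_probability(m, neutral, "hip", "ten_year"), direct,
               tolerance = 1e-12)
})

test_that("probabilities are monotone in risk factors, hazard scale and horizon", {
  m <- toy_country_model()
  base <- risk_profile(70, "female", tscore = -1)
  p0 <- fracture_probability(m, base, "hip")
  p_rf <- fracture_probability(m, risk_profile(70, "female", tscore = -1,
                                               prior_fracture = TRUE), "hip")
  expect_gt(p_rf, p0)
  # scaled-down incidence lowers every scenario
  m_low <- generate_reference_model(m, 0.4)
  profiles <- list(
    risk_profile(50, "male"), risk_profile(60, "female", tscore = -2.5),
    risk_profile(80, "female", current_smoking = TRUE, alcohol_excess = TRUE)
  )
  for (pr in profiles) {
    for (outcome in c("hip", "mof")) {
      expect_lt(fracture_probability(m_low, pr, outcome),
                fracture_probability(m, pr, outcome))
    }
  }
  # lifetime dominates ten-year from the same start age
  expect_gte(fracture_probability(m, base, "hip", "lifetime"),
             fracture_probability(m, base, "hip", "ten_year"))
  # raising the death hazard strictly lowers the probability
  m_mort <- m
  m_mort$death$hazard <- m_mort$death$hazard * 3
  expect_lt(fracture_probability(m_mort, base, "hip"),
            fracture_probability(m, base, "hip"))
})

test_that("results lie in [0,1] and the quadrature is converged at defaults", {
  m <- toy_country_model()
  pr <- risk_profile(75, "male", tscore = -3, prior_fracture = TRUE,
                     glucocorticoids = TRUE)
  for (horizon in c("ten_year", "lifetime")) {
    p1 <- fracture_probability(m, pr, "mof", horizon, step = 0.01)
    p2 <- fracture_probability(m, pr, "mof", horizon, step = 0.005)
    expect_gte(p1, 0); expect_lte(p1, 1)
    expect_lt(abs(p1 - p2), 1e-8)
  }
})

test_that("hazard scaling preserves scenario rank order exactly", {
  m <- toy_country_model()
  m_low <- generate_reference_model(m, 0.4)
  grid <- build_grid(c("prior_fracture", "current_smoking", "glucocorticoids"),
                     tscores = c(0, -1.5, -3), age = 70, sex = "female")
  pairs <- evaluate_grid(m, m_low, grid, outcome = "hip", step = 0.05)
  expect_identical(rank(pairs$p_a), rank(pairs$p_b))
  expect_equal(cor(pairs$p_a, pairs$p_b, method = "spearman"), 1)
  expect_true(all(pairs$p_b < pairs$p_a))
})

test_that("the vectorized grid integrator agrees with the scalar path", {
  m <- toy_country_model()
  grid <- build_grid(c("prior_fracture", "rheumatoid_arthritis"),
                     tscores = c(0, -2), age = 60, sex = "male")
  pairs <- evaluate_grid(m, m, grid, outcome = "mof", step = 0.02)
  profiles <- fraxbuild:::grid_profiles(grid)
  direct <- vapply(profiles, function(pr) {
    fracture_probability(m, pr, "mof", step = 0.02)
  }, numeric(1))
  expect_equal(pairs$p_a, direct, tolerance = 1e-12)
})

test_that("ten-year outputs are restricted to start ages 40-90", {
  m <- toy_country_model()
  expect_error(fracture_probability(m, risk_profile(95, "female"), "hip"),
               "40-90")
  expect_silent(fracture_probability(m, risk_profile(95, "female"), "hip",
                                     "lifetime"))
})
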