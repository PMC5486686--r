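# Scenario grids, comparison regression, percentile tables, correlations.

test_that("grid cardinality is exactly 2^k * m", {
  g <- build_grid(age = 70, sex = "female")      # six factors, eight T-scores
  expect_identical(nrow(g), 512L)
  expect_identical(nrow(build_grid(character(0), tscores = 0,
                                   age = 50, sex = "male")), 1L)
  expect_identical(nrow(build_grid(c("prior_fracture", "current_smoking",
                                     "alcohol_excess"),
                                   tscores = c(0, -1, -2, -3),
                                   age = 60, sex = "female")), 32L)
  # exhaustive over a range of k and m
  facs <- fraxbuild:::RISK_FACTORS
  for (k in 0:5) for (m in c(1, 3, 8)) {
    g <- build_grid(facs[seq_len(k)], tscores = seq(0, by = -0.25,
                                                    length.out = m),
                    age = 70, sex = "male")
    expect_identical(nrow(g), as.integer(2^k * m))
  }
  expect_error(build_grid(c("prior_fracture", "prior_fracture"),
                          age = 70, sex = "female"), "duplicate")
})

test_that("identical models give identical pairs over the grid", {
  m <- toy_country_model()
  g <- build_grid(c("prior_fracture", "glucocorticoids"), tscores = c(0, -2),
                  age = 70, sex = "female")
  pairs <- evaluate_grid(m, m, g, outcome = "hip", step = 0.05)
  expect_identical(nrow(pairs), 8L)
  expect_equal(pairs$p_a, pairs$p_b)
})

test_that("the comparison regression recovers exact linear relations", {
  x <- seq(0.01, 0.6, length.out = 60)
  ident <- piecewise_compare_regression(data.frame(p_a = x, p_b = x),
                                        knots = c(0.05, 0.20))
  expect_equal(unname(ident$coefficients[["(Intercept)"]]), 0, tolerance = 1e-10)
  expect_equal(ident$segment_slopes, rep(1, 3), tolerance = 1e-10)
  half <- piecewise_compare_regression(data.frame(p_a = x, p_b = 0.5 * x),
                                       knots = c(0.05, 0.20))
  expect_equal(half$segment_slopes, rep(0.5, 3), tolerance = 1e-10)
  expect_error(
    piecewise_compare_regression(data.frame(p_a = rep(0.1, 5),
                                            p_b = runif(5))),
    "identical"
  )
  # knots outside the data range are dropped with a warning
  expect_warning(
    out <- piecewise_compare_regression(data.frame(p_a = x, p_b = x),
                                        knots = c(0.05, 0.9)),
    "outside"
  )
  expect_identical(out$knots, 0.05)
})

test_that("percentile tables interpolate model A and fit model B centrally", {
  x <- seq(0.02, 0.5, length.out = 100)
  tab <- percentile_table(data.frame(p_a = x, p_b = 0.5 * x),
                          knots = c(0.05, 0.2))
  expect_identical(tab$percentile, c(10, 50, 90))
  expect_equal(tab$p_a, quantile(x, c(.1, .5, .9), names = FALSE))
  expect_equal(tab$p_b, 0.5 * tab$p_a, tolerance = 1e-8)
  expect_true(all(tab$ti_low <= tab$ti_high))
  # a degenerate distribution collapses to zero-width intervals
  deg <- percentile_table(data.frame(p_a = rep(0.2, 20), p_b = rep(0.1, 20)))
  expect_equal(deg$p_b, rep(0.1, 3))
  expect_equal(deg$ti_high - deg$ti_low, rep(0, 3))
  expect_error(percentile_table(data.frame(p_a = x[1:5], p_b = x[1:5])),
               "at least 10")
})

test_that("tolerance intervals behave sensibly on noisy monotone relations", {
  set.seed(101)
  x <- sort(runif(512, 0.01, 0.6))
  y <- 0.5 * x * exp(rnorm(512, 0, 0.05))
  pairs <- data.frame(p_a = x, p_b = y)
  tab <- percentile_table(pairs, knots = c(0.05, 0.2))
  # empirical TIs cover ~95% of the neighbourhood scenarios by construction
  pr <- 100 * (rank(x, ties.method = "average") - 0.5) / length(x)
  for (i in seq_len(nrow(tab))) {
    nb <- abs(pr - tab$percentile[i]) <= 2
    cover <- mean(y[nb] >= tab$ti_low[i] & y[nb] <= tab$ti_high[i])
    expect_gte(cover, 0.9)
  }
  # prediction-interval variant contains the central estimate by construction
  tabp <- percentile_table(pairs, knots = c(0.05, 0.2),
                           ti_method = "prediction")
  expect_true(all(tabp$ti_low <= tabp$p_b & tabp$p_b <= tabp$ti_high))
})

test_that("summaries report Pearson r and the signed median relative difference", {
  x <- seq(0.01, 0.5, length.out = 50)
  s <- summarize_comparison(data.frame(p_a = x, p_b = 0.5 * x))
  expect_equal(s$pearson_r, 1)
  expect_equal(s$median_relative_difference_pct, 50)
  expect_error(summarize_comparison(data.frame(p_a = rep(1, 5),
                                               p_b = rep(1, 5))),
               "variance")
})

test_that("monotone relations preserve scenario rank order in the report", {
  x <- runif(100, 0.01, 0.6)
  y <- x^1.3  # any monotone map
  expect_identical(rank(x), rank(y))
})

test_that("report generation is deterministic and covers the requested layout", {
  m <- toy_country_model()
  m_low <- generate_reference_model(m, 0.4)
  rep1 <- compare_models(m, m_low, ages = 70, sexes = "female",
                         outcomes = "hip",
                         risk_factors = c("prior_fracture", "current_smoking"),
                         tscores = c(0, -1.5, -3), step = 0.05,
                         ti_method = "prediction")
  rep2 <- compare_models(m, m_low, ages = 70, sexes = "female",
                         outcomes = "hip",
                         risk_factors = c("prior_fracture", "current_smoking"),
                         tscores = c(0, -1.5, -3), step = 0.05,
                         ti_method = "prediction")
  expect_identical(rep1, rep2)
  expect_identical(nrow(rep1), 3L)  # three percentile rows per age/sex/outcome
  expect_true(all(rep1$p_b < rep1$p_a))
  expect_true(all(rep1$pearson_r > 0.95))
})

test_that("probabilities format as percentages with conventional precision", {
  expect_identical(format_probability_pct(c(0.056, 0.49, 0.081)),
                   c("5.6", "49", "8.1"))
})
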