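# Model-comparison machinery: exhaustive clinical-scenario grids, piecewise
# regression of one model's probabilities on the other's, percentile tables
# with 95% tolerance intervals, and correlations.

#' Build an exhaustive clinical-scenario grid
#'
#' All combinations of `k` binary clinical risk factors and `m` femoral-neck
#' T-score levels at a fixed age, sex and BMI: exactly `2^k * m` scenarios.
#' This is not a population simulation but an array of all possible
#' combinations. Ordering is deterministic: T-score levels outermost, the
#' factor combinations as a binary counter (first factor varying fastest).
#'
#' @param risk_factors character vector of factor names (subset of the seven
#'   supported clinical risk factors); duplicates are an error.
#' @param tscores numeric vector of distinct T-score levels (default 0 to
#'   -3.5 SD in 0.5 SD steps).
#' @param age scenario age in years.
#' @param sex `"female"` or `"male"`.
#' @param bmi BMI in kg/m2, fixed at 25 by default.
#' @return a `scenario_grid`: data frame with one logical column per factor
#'   plus `tscore`, and attributes `age`, `sex`, `bmi`.
#' @export
#' @examples
#' g <- build_grid(setdiff(c("prior_fracture", "parental_hip_fracture",
#'                           "current_smoking", "glucocorticoids",
#'                           "rheumatoid_arthritis", "alcohol_excess"),
#'                         NULL), age = 70, sex = "female")
#' nrow(g)  # 2^6 * 8 = 512
build_grid <- function(risk_factors = default_grid_factors(),
                       tscores = seq(0, -3.5, by = -0.5),
                       age = 70, sex = "female", bmi = 25) {
  if (anyDuplicated(risk_factors)) {
    stop("duplicate risk factor names: ",
         paste(unique(risk_factors[duplicated(risk_factors)]), collapse = ", "))
  }
  bad <- setdiff(risk_factors, RISK_FACTORS)
  if (length(bad)) stop("unknown risk factor(s): ", paste(bad, collapse = ", "))
  stopifnot(length(tscores) >= 1L, !anyDuplicated(tscores))
  check_sex(sex)
  cols <- c(stats::setNames(rep(list(c(FALSE, TRUE)), length(risk_factors)),
                            risk_factors),
            list(tscore = tscores))
  grid <- do.call(expand.grid, c(cols, KEEP.OUT.ATTRS = FALSE))
  structure(grid, class = c("scenario_grid", "data.frame"),
            age = age, sex = sex, bmi = bmi,
            risk_factors = risk_factors)
}

#' Default six-factor comparison grid
#'
#' The six dichotomous factors used with BMD entered (secondary osteoporosis
#' is omitted because its effect is taken as mediated by BMD when a T-score
#' is input), giving the canonical `2^6 * 8 = 512` scenario grid.
#'
#' @return character vector of six factor names.
#' @export
default_grid_factors <- function() {
  setdiff(RISK_FACTORS, "secondary_osteoporosis")
}

grid_profiles <- function(grid) {
  age <- attr(grid, "age"); sex <- attr(grid, "sex"); bmi <- attr(grid, "bmi")
  factors <- attr(grid, "risk_factors")
  lapply(seq_len(nrow(grid)), function(i) {
    args <- c(list(age = age, sex = sex, bmi = bmi,
                   tscore = grid$tscore[i]),
              as.list(grid[i, factors, drop = FALSE]))
    do.call(risk_profile, args)
  })
}

#' Evaluate two models over a scenario grid
#'
#' Computes the paired 10-year probabilities `(p_a, p_b)` for every scenario
#' in the grid under two country models, in the grid's scenario order.
#'
#' @param model_a,model_b [country_model()] objects.
#' @param grid a [build_grid()] scenario grid.
#' @param outcome `"hip"` or `"mof"`.
#' @param horizon `"ten_year"` (default) or `"lifetime"`.
#' @param step quadrature step in years.
#' @return data frame: the grid columns plus `p_a`, `p_b`; attributes copied
#'   from the grid plus `outcome`.
#' @export
evaluate_grid <- function(model_a, model_b, grid, outcome = c("hip", "mof"),
                          horizon = c("ten_year", "lifetime"), step = 0.01) {
  outcome <- match.arg(outcome)
  horizon <- match.arg(horizon)
  stopifnot(inherits(model_a, "country_model"),
            inherits(model_b, "country_model"),
            inherits(grid, "scenario_grid"))
  profiles <- grid_profiles(grid)
  out <- as.data.frame(grid)
  out$p_a <- grid_probabilities(model_a, profiles, outcome, horizon, step)
  out$p_b <- grid_probabilities(model_b, profiles, outcome, horizon, step)
  attr(out, "age") <- attr(grid, "age")
  attr(out, "sex") <- attr(grid, "sex")
  attr(out, "outcome") <- outcome
  out
}

# All grid scenarios share the baseline hazard at a given (model, sex, age,
# outcome); only the multiplicative risk adjustment varies, so the competing
# integral is vectorized over multipliers.
grid_probabilities <- function(model, profiles, outcome, horizon, step) {
  sex <- profiles[[1L]]$sex
  age <- profiles[[1L]]$age
  base <- if (outcome == "hip") {
    hip_hazard_fn(model, sex)
  } else {
    function(a) mof_hazard(model, sex, a)
  }
  mult <- vapply(profiles, risk_multiplier, numeric(1),
                 config = model$config, outcome = outcome)
  h_death <- death_hazard_fn(model, sex)
  horizon_years <- if (horizon == "ten_year") 10 else 110 - age
  integrate_competing_scaled(base, h_death, age, horizon_years, mult,
                             step = step)
}

#' Piecewise linear regression of one model's probabilities on the other's
#'
#' Fits a continuous piecewise-linear least-squares regression of `p_b` on
#' `p_a` with hinge terms at fixed knots. Conventional knots are at
#' probabilities of 0.50 and 0.70 for major osteoporotic fracture and 0.05
#' and 0.20 for hip fracture, reflecting the different probability
#' distributions of the two outcomes. Knots outside the observed `p_a` range
#' delimit empty segments and are dropped with a warning.
#'
#' @param pairs data frame with columns `p_a`, `p_b` (from
#'   [evaluate_grid()]), or anything coercible.
#' @param knots increasing probability values (fractions).
#' @return list of class `piecewise_compare` with `coefficients`,
#'   `knots` (those used), `segment_slopes`, `fitted`, and the underlying
#'   `lm` fit.
#' @export
piecewise_compare_regression <- function(pairs, knots = c(0.05, 0.20)) {
  check_columns(pairs, c("p_a", "p_b"), "pairs")
  stopifnot(nrow(pairs) >= 3L, !is.unsorted(knots, strictly = TRUE))
  if (stats::var(pairs$p_a) == 0) {
    stop("all p_a values identical: no regression possible")
  }
  inside <- knots > min(pairs$p_a) & knots < max(pairs$p_a)
  if (any(!inside)) {
    warning("dropping knot(s) outside the observed p_a range: ",
            paste(knots[!inside], collapse = ", "), call. = FALSE)
    knots <- knots[inside]
  }
  dat <- data.frame(y = pairs$p_b, x = pairs$p_a)
  if (length(knots)) {
    hinges <- sapply(knots, function(k) pmax(dat$x - k, 0))
    colnames(hinges) <- paste0("h", seq_along(knots))
    dat <- cbind(dat, hinges)
  }
  fit <- stats::lm(y ~ ., data = dat)
  cf <- stats::coef(fit)
  slopes <- cumsum(c(cf[["x"]], cf[grep("^h", names(cf))]))
  structure(
    list(coefficients = cf, knots = knots,
         segment_slopes = unname(slopes),
         fitted = unname(stats::fitted(fit)), fit = fit),
    class = "piecewise_compare"
  )
}

#' @export
print.piecewise_compare <- function(x, ...) {
  cat("Piecewise linear comparison regression\n")
  cat("  knots (p_a):", if (length(x$knots)) paste(x$knots, collapse = ", ")
      else "none", "\n")
  cat("  segment slopes:", paste(signif(x$segment_slopes, 4), collapse = ", "),
      "\n")
  invisible(x)
}

predict_piecewise_compare <- function(object, p_a) {
  cf <- object$coefficients
  y <- cf[["(Intercept)"]] + cf[["x"]] * p_a
  for (i in seq_along(object$knots)) {
    y <- y + cf[[paste0("h", i)]] * pmax(p_a - object$knots[i], 0)
  }
  unname(y)
}

#' Percentile comparison table with 95% tolerance intervals
#'
#' For each requested percentile of the model-A probability distribution
#' (linear interpolation between order statistics): the model-A value, the
#' model-B central estimate (the fitted value of the piecewise comparison
#' regression at that point), and a 95% tolerance interval for model-B
#' probabilities. The default tolerance interval is the empirical
#' 2.5th-97.5th percentile range of model-B probabilities among scenarios
#' whose model-A probability falls within +/- `rank_window` percentile ranks
#' of the target percentile; `ti_method = "prediction"` instead uses the 95%
#' regression prediction interval.
#'
#' @param pairs data frame with `p_a`, `p_b`.
#' @param percentiles percentiles of the model-A distribution (default
#'   10, 50, 90).
#' @param knots knots for the comparison regression (probability fractions).
#' @param ti_method `"empirical"` (order-statistic neighbourhood, default)
#'   or `"prediction"` (regression prediction interval).
#' @param rank_window half-width of the percentile-rank neighbourhood used
#'   by the empirical method (percentile points, default 2).
#' @return data frame: `percentile`, `p_a`, `p_b`, `ti_low`, `ti_high`.
#' @export
percentile_table <- function(pairs, percentiles = c(10, 50, 90),
                             knots = c(0.05, 0.20),
                             ti_method = c("empirical", "prediction"),
                             rank_window = 2) {
  ti_method <- match.arg(ti_method)
  check_columns(pairs, c("p_a", "p_b"), "pairs")
  n <- nrow(pairs)
  if (n < 10L) stop("need at least 10 scenario pairs to form intervals")
  degenerate <- stats::var(pairs$p_a) == 0
  q_a <- stats::quantile(pairs$p_a, percentiles / 100, type = 7, names = FALSE)
  if (degenerate) {
    # all scenarios identical: every percentile is that value, zero width
    return(data.frame(percentile = percentiles, p_a = q_a,
                      p_b = rep(pairs$p_b[1L], length(percentiles)),
                      ti_low = rep(pairs$p_b[1L], length(percentiles)),
                      ti_high = rep(pairs$p_b[1L], length(percentiles))))
  }
  reg <- piecewise_compare_regression(pairs, knots = knots)
  central <- predict_piecewise_compare(reg, q_a)
  pr <- 100 * (rank(pairs$p_a, ties.method = "average") - 0.5) / n
  ti <- vapply(seq_along(percentiles), function(i) {
    if (ti_method == "empirical") {
      nb <- abs(pr - percentiles[i]) <= rank_window
      if (sum(nb) < 2L) stop("fewer than 2 scenarios within the percentile ",
                             "neighbourhood; widen rank_window")
      stats::quantile(pairs$p_b[nb], c(0.025, 0.975), type = 7, names = FALSE)
    } else {
      nd <- data.frame(x = q_a[i])
      for (j in seq_along(reg$knots)) {
        nd[[paste0("h", j)]] <- pmax(q_a[i] - reg$knots[j], 0)
      }
      as.numeric(stats::predict(reg$fit, newdata = nd,
                                interval = "prediction", level = 0.95))[2:3]
    }
  }, numeric(2))
  data.frame(percentile = percentiles, p_a = q_a, p_b = central,
             ti_low = ti[1, ], ti_high = ti[2, ])
}

#' Correlation and median relative difference between paired probabilities
#'
#' @param pairs data frame with `p_a`, `p_b`.
#' @return list with `pearson_r` and `median_relative_difference_pct`, the
#'   median over scenarios of `100 * (p_a - p_b) / p_a` (positive when model
#'   B runs lower than model A).
#' @export
summarize_comparison <- function(pairs) {
  check_columns(pairs, c("p_a", "p_b"), "pairs")
  if (nrow(pairs) < 3L) stop("need at least 3 pairs")
  if (stats::var(pairs$p_a) == 0 || stats::var(pairs$p_b) == 0) {
    stop("zero variance in one of the probability sets")
  }
  list(
    pearson_r = stats::cor(pairs$p_a, pairs$p_b),
    median_relative_difference_pct =
      stats::median(100 * (pairs$p_a - pairs$p_b) / pairs$p_a)
  )
}

#' Full two-model comparison report
#'
#' Runs the scenario grid at each requested age and sex for both outcomes
#' and assembles the long-format report: percentile rows with tolerance
#' intervals plus the Pearson correlation, mirroring the tabular layout used
#' to compare two national models.
#'
#' @param model_a,model_b [country_model()] objects (model A is the
#'   reference whose percentiles anchor the table).
#' @param ages comparison ages (default 50, 60, 70, 80).
#' @param sexes sexes to compare.
#' @param outcomes outcomes to compare.
#' @param risk_factors,tscores grid settings (see [build_grid()]).
#' @param mof_knots,hip_knots regression knots per outcome (probability
#'   fractions).
#' @param step quadrature step in years.
#' @param ti_method tolerance-interval method, see [percentile_table()].
#' @return data frame of class `comparison_report`: `age`, `sex`, `outcome`,
#'   `percentile`, `p_a`, `p_b`, `ti_low`, `ti_high`, `pearson_r`,
#'   `median_relative_difference_pct` (probabilities as fractions).
#' @export
compare_models <- function(model_a, model_b,
                           ages = c(50, 60, 70, 80),
                           sexes = c("female", "male"),
                           outcomes = c("mof", "hip"),
                           risk_factors = default_grid_factors(),
                           tscores = seq(0, -3.5, by = -0.5),
                           mof_knots = c(0.50, 0.70),
                           hip_knots = c(0.05, 0.20),
                           step = 0.01,
                           ti_method = c("empirical", "prediction")) {
  ti_method <- match.arg(ti_method)
  rows <- list()
  for (sex in sexes) for (age in ages) {
    grid <- build_grid(risk_factors, tscores, age = age, sex = sex)
    for (outcome in outcomes) {
      pairs <- evaluate_grid(model_a, model_b, grid, outcome = outcome,
                             step = step)
      knots <- if (outcome == "mof") mof_knots else hip_knots
      tab <- suppressWarnings(
        percentile_table(pairs, knots = knots, ti_method = ti_method)
      )
      s <- summarize_comparison(pairs)
      tab$age <- age; tab$sex <- sex; tab$outcome <- outcome
      tab$pearson_r <- s$pearson_r
      tab$median_relative_difference_pct <- s$median_relative_difference_pct
      rows[[length(rows) + 1L]] <- tab
    }
  }
  out <- do.call(rbind, rows)
  out <- out[, c("age", "sex", "outcome", "percentile", "p_a", "p_b",
                 "ti_low", "ti_high", "pearson_r",
                 "median_relative_difference_pct")]
  rownames(out) <- NULL
  class(out) <- c("comparison_report", "data.frame")
  out
}

#' Render report probabilities as display percentages
#'
#' Probabilities are handled as fractions internally; for display they are
#' conventionally shown as percentages with 0 decimal places above 10% and 1
#' below.
#'
#' @param p probabilities as fractions.
#' @return character vector of formatted percentages.
#' @export
format_probability_pct <- function(p) {
  pct <- 100 * p
  ifelse(pct >= 10, sprintf("%.0f", pct), sprintf("%.1f", pct))
}
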