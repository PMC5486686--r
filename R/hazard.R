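# Competing-mortality fracture-probability engine: risk-factor-adjusted
# hazards integrated against the death hazard over 10-year or remaining
# lifetime horizons.

#' Risk-model configuration
#'
#' Holds the multiplicative machinery that turns a baseline population hazard
#' into an individual's hazard: one relative risk per dichotomous clinical
#' risk factor and outcome, a gradient of risk (relative risk per SD decrease
#' in femoral-neck T-score), a BMI effect, and the hip-to-MOF ratio table
#' used to impute major-osteoporotic-fracture incidence from hip incidence
#' (assumed transportable, as in Swedish-ratio imputation).
#'
#' The true coefficients of the deployed FRAX tools are proprietary and are
#' not reproduced here; supply relative risks of the intended magnitude
#' (e.g. from published meta-analyses) via this configuration.
#'
#' @param relative_risks data frame with columns `factor`, `hip`, `mof`
#'   giving the relative risk of each clinical risk factor for each outcome.
#'   Factor names must be among the seven supported: prior_fracture,
#'   parental_hip_fracture, current_smoking, glucocorticoids,
#'   rheumatoid_arthritis, secondary_osteoporosis, alcohol_excess.
#' @param gradient_of_risk named numeric, relative risk per SD decrease in
#'   femoral-neck T-score for outcomes `hip` and `mof`.
#' @param reference_tscore T-score at which the BMD multiplier is 1 (SD,
#'   default 0).
#' @param rr_per_bmi_unit relative risk per kg/m2 of BMI above the neutral
#'   point of 25 kg/m2 (default 1: neutral, since model comparisons fix BMI
#'   at 25).
#' @param secondary_osteoporosis_inactive_with_bmd when `TRUE` (default) the
#'   secondary-osteoporosis factor contributes no multiplier if a T-score is
#'   entered, its effect being assumed mediated by BMD.
#' @param hip_to_mof_ratio data frame `sex`, `age`, `ratio` mapping hip
#'   hazard to MOF hazard (ratios >= 1); the nearest tabulated age is used
#'   between entries.
#' @return an object of class `risk_model_config`.
#' @export
risk_model_config <- function(relative_risks,
                              gradient_of_risk = c(hip = 1, mof = 1),
                              reference_tscore = 0,
                              rr_per_bmi_unit = 1,
                              secondary_osteoporosis_inactive_with_bmd = TRUE,
                              hip_to_mof_ratio = NULL) {
  check_columns(relative_risks, c("factor", "hip", "mof"), "relative_risks")
  bad <- setdiff(relative_risks$factor, RISK_FACTORS)
  if (length(bad)) stop("unknown risk factor(s): ", paste(bad, collapse = ", "))
  if (any(relative_risks$hip <= 0) || any(relative_risks$mof <= 0)) {
    stop("all relative risks must be > 0")
  }
  stopifnot(all(c("hip", "mof") %in% names(gradient_of_risk)),
            all(gradient_of_risk > 0), rr_per_bmi_unit > 0)
  if (!is.null(hip_to_mof_ratio)) {
    check_columns(hip_to_mof_ratio, c("sex", "age", "ratio"), "hip_to_mof_ratio")
    check_sex(hip_to_mof_ratio$sex)
    if (any(hip_to_mof_ratio$ratio < 1)) stop("hip:MOF ratios must be >= 1")
  }
  structure(
    list(relative_risks = relative_risks,
         gradient_of_risk = gradient_of_risk,
         reference_tscore = reference_tscore,
         rr_per_bmi_unit = rr_per_bmi_unit,
         secondary_osteoporosis_inactive_with_bmd =
           isTRUE(secondary_osteoporosis_inactive_with_bmd),
         hip_to_mof_ratio = hip_to_mof_ratio),
    class = "risk_model_config"
  )
}

#' Individual risk-factor profile
#'
#' @param age age in years (40-90 for 10-year outputs).
#' @param sex `"female"` or `"male"`.
#' @param bmi body mass index in kg/m2 (default 25).
#' @param tscore femoral-neck BMD T-score in SD, or `NULL` if not measured.
#' @param prior_fracture,parental_hip_fracture,current_smoking,glucocorticoids,rheumatoid_arthritis,secondary_osteoporosis,alcohol_excess
#'   the seven dichotomous clinical risk factors.
#' @return an object of class `risk_profile`.
#' @export
#' @examples
#' risk_profile(70, "female", tscore = -2.5, prior_fracture = TRUE)
risk_profile <- function(age, sex, bmi = 25, tscore = NULL,
                         prior_fracture = FALSE, parental_hip_fracture = FALSE,
                         current_smoking = FALSE, glucocorticoids = FALSE,
                         rheumatoid_arthritis = FALSE,
                         secondary_osteoporosis = FALSE,
                         alcohol_excess = FALSE) {
  check_sex(sex)
  stopifnot(is.numeric(age), length(age) == 1L, age >= 40, age <= 110,
            is.numeric(bmi), bmi > 0,
            is.null(tscore) || is.numeric(tscore))
  structure(
    list(age = age, sex = sex, bmi = bmi, tscore = tscore,
         prior_fracture = isTRUE(prior_fracture),
         parental_hip_fracture = isTRUE(parental_hip_fracture),
         current_smoking = isTRUE(current_smoking),
         glucocorticoids = isTRUE(glucocorticoids),
         rheumatoid_arthritis = isTRUE(rheumatoid_arthritis),
         secondary_osteoporosis = isTRUE(secondary_osteoporosis),
         alcohol_excess = isTRUE(alcohol_excess)),
    class = "risk_profile"
  )
}

#' Assemble a country-specific fracture-probability model
#'
#' Bundles the sex-specific smoothed hip hazard, the national death hazard
#' and a risk-model configuration into a deployable model.
#'
#' @param hip named list of [piecewise_loglinear()] models, one per sex
#'   (`female`, `male`).
#' @param death death-hazard table: columns `sex`, `age` (single years
#'   covering 40-110), `hazard` (per person-year).
#' @param config a [risk_model_config()].
#' @return an object of class `country_model`.
#' @export
country_model <- function(hip, death, config) {
  stopifnot(is.list(hip), all(SEXES %in% names(hip)))
  for (s in SEXES) stopifnot(inherits(hip[[s]], "piecewise_loglinear"))
  check_columns(death, c("sex", "age", "hazard"), "death hazard table")
  check_sex(death$sex)
  if (any(death$hazard < 0)) stop("death hazards must be >= 0")
  for (s in SEXES) {
    ages <- death$age[death$sex == s]
    if (length(ages) == 0L || min(ages) > 40 || max(ages) < 110) {
      stop("death hazard table must cover ages 40-110 for ", s)
    }
  }
  stopifnot(inherits(config, "risk_model_config"))
  structure(list(hip = hip[SEXES], death = death, config = config),
            class = "country_model")
}

#' @export
print.country_model <- function(x, ...) {
  cat("Country-specific fracture-probability model\n")
  for (s in SEXES) {
    m <- x$hip[[s]]
    cat(sprintf("  %-6s hip log-rate(40) %.3f, slopes %.4f / %.4f (knot %g y)\n",
                s, m$intercept, m$slope_pre, m$slope_post, m$knot_age))
  }
  cat("  death hazard:", length(unique(x$death$age)), "tabulated ages\n")
  cat("  hip:MOF ratio table:",
      if (is.null(x$config$hip_to_mof_ratio)) "absent" else "present", "\n")
  invisible(x)
}

# Death hazard as a function of age: log-linear interpolation between the
# tabulated single years (linear fallback when zeros are present).
death_hazard_fn <- function(model, sex) {
  tab <- model$death[model$death$sex == sex, , drop = FALSE]
  tab <- tab[order(tab$age), ]
  if (all(tab$hazard > 0)) {
    f <- stats::approxfun(tab$age, log(tab$hazard), rule = 2)
    function(a) exp(f(a))
  } else {
    stats::approxfun(tab$age, tab$hazard, rule = 2)
  }
}

hip_hazard_fn <- function(model, sex) {
  pw <- model$hip[[sex]]
  function(a) predict_rate(pw, a)
}

#' Major-osteoporotic-fracture hazard imputed from the hip hazard
#'
#' Multiplies the hip hazard at the given sex and age by the configured
#' hip:MOF ratio, looked up at the nearest tabulated age for that sex.
#'
#' @param model a [country_model()].
#' @param sex `"female"` or `"male"`.
#' @param age ages in years.
#' @return MOF hazard per person-year; at least the hip hazard whenever the
#'   ratio table respects the `ratio >= 1` invariant.
#' @export
mof_hazard <- function(model, sex, age) {
  predict_rate(model$hip[[sex]], age) * mof_ratio_at(model$config, sex, age)
}

mof_ratio_at <- function(config, sex, age) {
  tab <- config$hip_to_mof_ratio
  if (is.null(tab)) {
    stop("no hip:MOF ratio table configured; supply one via risk_model_config()")
  }
  tab <- tab[tab$sex == sex, , drop = FALSE]
  if (nrow(tab) == 0L) stop("hip:MOF ratio table has no rows for sex ", sex)
  tab$ratio[vapply(age, function(a) which.min(abs(tab$age - a)), integer(1))]
}

#' Multiplicative hazard adjustment for an individual profile
#'
#' The individual's hazard is the baseline hazard times the product of the
#' relative risks of the factors present, a BMD term
#' `gradient^(reference - tscore)` when a T-score is entered, and a BMI term
#' `rr_per_bmi_unit^(bmi - 25)`. When a T-score is entered and the
#' configuration flags secondary osteoporosis as BMD-mediated, that factor
#' contributes no multiplier.
#'
#' @param baseline a hazard function of age (per person-year).
#' @param profile a [risk_profile()].
#' @param config a [risk_model_config()].
#' @param outcome `"hip"` or `"mof"`.
#' @return a hazard function of age.
#' @seealso [risk_multiplier()] for the scalar multiplier itself.
#' @export
adjusted_hazard <- function(baseline, profile, config, outcome = c("hip", "mof")) {
  m <- risk_multiplier(profile, config, match.arg(outcome))
  function(a) m * baseline(a)
}

#' @rdname adjusted_hazard
#' @export
risk_multiplier <- function(profile, config, outcome = c("hip", "mof")) {
  outcome <- match.arg(outcome)
  stopifnot(inherits(profile, "risk_profile"), inherits(config, "risk_model_config"))
  rr <- stats::setNames(config$relative_risks[[outcome]],
                        config$relative_risks$factor)
  mult <- 1
  for (f in names(rr)) {
    if (!isTRUE(profile[[f]])) next
    if (f == "secondary_osteoporosis" && !is.null(profile$tscore) &&
        config$secondary_osteoporosis_inactive_with_bmd) next
    mult <- mult * rr[[f]]
  }
  if (!is.null(profile$tscore)) {
    mult <- mult * config$gradient_of_risk[[outcome]]^
      (config$reference_tscore - profile$tscore)
  }
  mult * config$rr_per_bmi_unit^(profile$bmi - 25)
}

# Core quadrature. Hazards are treated as piecewise-constant on a fine age
# grid (hazard evaluated at step midpoints); within each step the joint
# survival and the fracture contribution then have the exact closed form
#   hf/(hf+hd) * S_start * (1 - exp(-(hf+hd) dt)),
# so constant hazards integrate exactly and smooth hazards are O(step^2).
eval_hazard <- function(f, x) {
  v <- f(x)
  if (length(v) == length(x)) return(as.numeric(v))
  if (length(v) == 1L) return(rep(as.numeric(v), length(x)))
  vapply(x, function(xx) as.numeric(f(xx))[[1L]], numeric(1))
}

integrate_competing <- function(h_frac, h_death, start_age, horizon,
                                step = 0.01) {
  stopifnot(horizon > 0, step > 0)
  n <- ceiling(horizon / step)
  dt <- horizon / n
  mid <- start_age + (seq_len(n) - 0.5) * dt
  hf <- eval_hazard(h_frac, mid)
  hd <- eval_hazard(h_death, mid)
  if (any(!is.finite(hf)) || any(!is.finite(hd))) {
    stop("hazards undefined (non-finite) on the integration range")
  }
  if (any(hf < 0) || any(hd < 0)) stop("hazards must be non-negative")
  htot <- hf + hd
  Hprev <- c(0, cumsum(htot * dt))[seq_len(n)]
  frac <- ifelse(htot > 0, hf / pmax(htot, .Machine$double.xmin), 0)
  contrib <- ifelse(htot > 0,
                    frac * exp(-Hprev) * (1 - exp(-htot * dt)),
                    0)
  sum(contrib)
}

# Vectorized over a set of multipliers applied to the same baseline fracture
# hazard (used for scenario grids, where only the multiplier varies).
integrate_competing_scaled <- function(base_frac, h_death, start_age, horizon,
                                       multipliers, step = 0.01) {
  n <- ceiling(horizon / step)
  dt <- horizon / n
  mid <- start_age + (seq_len(n) - 0.5) * dt
  bf <- eval_hazard(base_frac, mid)
  hd <- eval_hazard(h_death, mid)
  hf <- outer(multipliers, bf)              # n_mult x n_steps
  htot <- hf + rep(hd, each = length(multipliers))
  Hprev <- cbind(0, t(apply(htot * dt, 1L, cumsum)))[, seq_len(n), drop = FALSE]
  contrib <- hf / pmax(htot, .Machine$double.xmin) *
    exp(-Hprev) * (1 - exp(-htot * dt))
  rowSums(contrib)
}

#' Ten-year fracture probability under competing mortality
#'
#' Computes `P = int_0^10 h_f(a0+u) exp(-int_0^u [h_f + h_d](a0+v) dv) du`,
#' the probability of sustaining the fracture within 10 years given the
#' competing risk of death, by quadrature on a fine age grid.
#'
#' @param h_frac fracture hazard, a function of age (per person-year).
#' @param h_death death hazard, a function of age (per person-year).
#' @param start_age starting age in years.
#' @param step quadrature step in years (default 0.01).
#' @return a probability in `[0, 1]`.
#' @export
#' @examples
#' # constant hazards have the closed form hf/(hf+hd) * (1 - exp(-10(hf+hd)))
#' ten_year_probability(function(a) 0.01, function(a) 0.02, 60)
ten_year_probability <- function(h_frac, h_death, start_age, step = 0.01) {
  integrate_competing(h_frac, h_death, start_age, horizon = 10, step = step)
}

#' Remaining-lifetime fracture probability
#'
#' Same integrand as [ten_year_probability()] with the horizon extended from
#' the starting age to `max_age`.
#'
#' @inheritParams ten_year_probability
#' @param max_age upper integration age in years (default 110).
#' @return a probability in `[0, 1]`.
#' @export
lifetime_probability <- function(h_frac, h_death, start_age, max_age = 110,
                                 step = 0.01) {
  if (max_age <= start_age) stop("max_age must exceed start_age")
  integrate_competing(h_frac, h_death, start_age,
                      horizon = max_age - start_age, step = step)
}

#' Fracture probability for an individual profile under a country model
#'
#' Composes the baseline hazard (hip, or MOF imputed through the hip:MOF
#' ratio), the profile's multiplicative risk adjustment and the competing
#' mortality integral.
#'
#' @param model a [country_model()].
#' @param profile a [risk_profile()]; its `age` is the starting age.
#' @param outcome `"hip"` or `"mof"`.
#' @param horizon `"ten_year"` or `"lifetime"`.
#' @param max_age upper age bound for the lifetime horizon (default 110).
#' @param step quadrature step in years.
#' @return a probability in `[0, 1]`.
#' @export
#' @examples
#' model <- example_country_model()
#' fracture_probability(model, risk_profile(70, "female", tscore = -2.5),
#'                      outcome = "mof", horizon = "ten_year")
fracture_probability <- function(model, profile,
                                 outcome = c("hip", "mof"),
                                 horizon = c("ten_year", "lifetime"),
                                 max_age = 110, step = 0.01) {
  outcome <- match.arg(outcome)
  horizon <- match.arg(horizon)
  stopifnot(inherits(model, "country_model"), inherits(profile, "risk_profile"))
  if (horizon == "ten_year" && (profile$age < 40 || profile$age > 90)) {
    stop("ten-year probabilities are supported for start ages 40-90")
  }
  base <- if (outcome == "hip") {
    hip_hazard_fn(model, profile$sex)
  } else {
    function(a) mof_hazard(model, profile$sex, a)
  }
  h_frac <- adjusted_hazard(base, profile, model$config, outcome)
  h_death <- death_hazard_fn(model, profile$sex)
  if (horizon == "ten_year") {
    ten_year_probability(h_frac, h_death, profile$age, step = step)
  } else {
    lifetime_probability(h_frac, h_death, profile$age, max_age = max_age,
                         step = step)
  }
}
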