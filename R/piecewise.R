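# Piecewise log-linear smoothing of banded incidence into a continuous-age
# hazard: two log-linear segments joined continuously at a fixed knot.

#' Piecewise log-linear incidence model
#'
#' Represents a continuous-age fracture hazard whose log is linear in age on
#' each side of a fixed knot (breakpoint), with continuity enforced at the
#' knot. The intercept is the log rate at the reference age of 40 years.
#'
#' @param sex `"female"` or `"male"`.
#' @param intercept log rate (per person-year) at age 40.
#' @param slope_pre per-year slope of the log rate below the knot.
#' @param slope_post per-year slope of the log rate at and above the knot.
#' @param knot_age knot (breakpoint) age in years; default 67.
#' @param rss residual sum of squares of the fit, if fitted (else `NA`).
#' @param n_bands number of bands used in the fit, if fitted.
#' @return an object of class `piecewise_loglinear`.
#' @seealso [fit_piecewise_loglinear()], [predict_rate()]
#' @export
#' @examples
#' m <- piecewise_loglinear("female", intercept = -8, slope_pre = 0.05,
#'                          slope_post = 0.12)
#' predict_rate(m, c(50, 67, 80))
piecewise_loglinear <- function(sex, intercept, slope_pre, slope_post,
                                knot_age = 67, rss = NA_real_,
                                n_bands = NA_integer_) {
  check_sex(sex)
  stopifnot(is.numeric(intercept), is.numeric(slope_pre), is.numeric(slope_post),
            is.numeric(knot_age), knot_age > 40, knot_age < 110)
  structure(
    list(sex = sex, knot_age = knot_age, intercept = intercept,
         slope_pre = slope_pre, slope_post = slope_post,
         rss = rss, n_bands = n_bands),
    class = "piecewise_loglinear"
  )
}

#' @export
print.piecewise_loglinear <- function(x, ...) {
  cat("Piecewise log-linear incidence model (", x$sex, ")\n", sep = "")
  cat(sprintf("  log rate(40)  : %.6f  (rate %.3g /py)\n", x$intercept, exp(x$intercept)))
  cat(sprintf("  slope < %g y  : %.6f /y\n", x$knot_age, x$slope_pre))
  cat(sprintf("  slope >= %g y : %.6f /y\n", x$knot_age, x$slope_post))
  if (!is.na(x$rss)) cat(sprintf("  fit: %d bands, RSS %.4g\n", x$n_bands, x$rss))
  invisible(x)
}

#' Predict the incidence rate at exact ages
#'
#' Evaluates the piecewise-linear log rate and exponentiates, so risk can be
#' computed at any specific age rather than in 5-year intervals.
#'
#' @param model a [piecewise_loglinear()] model.
#' @param age ages in years; must lie in `[40, 110]`.
#' @return rates per person-year (strictly positive), one per age.
#' @export
predict_rate <- function(model, age) {
  stopifnot(inherits(model, "piecewise_loglinear"))
  if (any(age < 40 | age > 110)) {
    stop("age outside the supported range [40, 110]: ",
         paste(age[age < 40 | age > 110], collapse = ", "))
  }
  exp(log_rate_at(model, age))
}

log_rate_at <- function(model, age) {
  model$intercept +
    model$slope_pre * (pmin(age, model$knot_age) - 40) +
    model$slope_post * pmax(age - model$knot_age, 0)
}

#' Fit a piecewise log-linear model to banded incidence
#'
#' Least-squares regression of log incidence rate on band-midpoint age with a
#' continuous change of slope at a fixed knot (a hinge term). Fits are
#' performed separately for each sex present in the table. Zero-rate bands
#' cannot enter a log-scale fit and are dropped with a warning.
#'
#' @param table an incidence table as produced by [tabulate_incidence()] or
#'   [amalgamate_incidence()]: columns `sex`, `age_band`, `n_cases`,
#'   `person_years`, `rate`.
#' @param knot_age fixed breakpoint age in years (default 67).
#' @param weights `"none"` for ordinary least squares (default) or `"cases"`
#'   to weight bands by their case counts.
#' @return a named list of [piecewise_loglinear()] models, one per sex in the
#'   table.
#' @export
#' @examples
#' tab <- data.frame(
#'   sex = "female", age_band = age_bands(),
#'   n_cases = 100, person_years = 1e5,
#'   rate = exp(-8 + 0.05 * pmin(band_midpoint(age_bands()) - 40, 27) +
#'              0.12 * pmax(band_midpoint(age_bands()) - 67, 0))
#' )
#' fit_piecewise_loglinear(tab)$female
fit_piecewise_loglinear <- function(table, knot_age = 67,
                                    weights = c("none", "cases")) {
  weights <- match.arg(weights)
  check_columns(table, c("sex", "age_band", "rate"), "incidence table")
  check_sex(table$sex)
  out <- lapply(split(table, table$sex), function(tab) {
    fit_one_sex(tab, knot_age = knot_age, weights = weights)
  })
  out[order(match(names(out), SEXES))]
}

fit_one_sex <- function(tab, knot_age, weights) {
  sex <- tab$sex[[1L]]
  keep <- tab$rate > 0
  if (any(!keep)) {
    warning(sum(!keep), " zero-rate band(s) dropped from the log-scale fit for ",
            sex, ": ", paste(tab$age_band[!keep], collapse = ", "), call. = FALSE)
    tab <- tab[keep, , drop = FALSE]
  }
  if (nrow(tab) < 3L) {
    stop("fewer than 3 positive-rate bands for ", sex,
         ": the piecewise fit is underdetermined")
  }
  x <- band_midpoint(tab$age_band)
  y <- log(tab$rate)
  hinge <- pmax(x - knot_age, 0)
  w <- if (weights == "cases") tab$n_cases else rep(1, nrow(tab))
  dat <- data.frame(y = y, x0 = x - 40, hinge = hinge)
  # With no data above (or below) the knot the hinge column is constant and
  # the slope change is unidentifiable; that is an input problem, not a fit.
  if (length(unique(hinge)) < 2L || length(unique(dat$x0[hinge == 0])) < 2L) {
    stop("need positive-rate bands on both sides of the knot at ", knot_age,
         " years for ", sex)
  }
  fit <- stats::lm(y ~ x0 + hinge, data = dat, weights = w)
  cf <- stats::coef(fit)
  piecewise_loglinear(
    sex = sex, knot_age = knot_age,
    intercept = unname(cf[["(Intercept)"]]),
    slope_pre = unname(cf[["x0"]]),
    slope_post = unname(cf[["x0"]] + cf[["hinge"]]),
    rss = sum(stats::residuals(fit)^2),
    n_bands = nrow(tab)
  )
}

#' Plot observed band rates against the smoothed curve
#'
#' A log-scale incidence-by-age figure: observed band rates as symbols and
#' the fitted single-year rates as lines, by sex.
#'
#' @param x named list of [piecewise_loglinear()] models (as returned by
#'   [fit_piecewise_loglinear()]).
#' @param table optional incidence table of observed band rates to overlay.
#' @param ... passed to [graphics::matplot()].
#' @return invisibly, the matrix of predicted rates by age and sex.
#' @export
plot_incidence <- function(x, table = NULL, ...) {
  ages <- 40:100
  pred <- sapply(x, predict_rate, age = ages)
  graphics::matplot(ages, pred, type = "l", lty = 1, log = "y",
                    xlab = "Age (years)", ylab = "Hip fracture rate (/person-year)",
                    col = seq_along(x), ...)
  if (!is.null(table)) {
    for (i in seq_along(x)) {
      tab <- table[table$sex == names(x)[i] & table$rate > 0, , drop = FALSE]
      graphics::points(band_midpoint(tab$age_band), tab$rate, col = i, pch = 16)
    }
  }
  graphics::legend("topleft", legend = names(x), col = seq_along(x),
                   lty = 1, bty = "n")
  invisible(pred)
}
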