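# Synthetic multi-source registry generator with known ground truth:
# Poisson case counts from a piecewise log-linear incidence surface, plus
# planted duplicates, neoplasia cases, unspecified-site codes, prior-year
# fractures and hospitalization refusals. Everything downstream of the
# ascertainment rules can be tested against the recorded truth.

#' Configuration for the synthetic registry generator
#'
#' The defaults describe a three-catchment retrospective study: case counts
#' per (region, sex, 5-year band) are Poisson with mean
#' `rate(band midpoint) * population`, ages uniform within the band, and a
#' configurable share of registry pathology planted on top. Plant categories
#' are mutually exclusive at the case level, so their fractions must sum to
#' at most 1.
#'
#' @param regions character vector of region identifiers.
#' @param population data frame `region`, `sex`, `age_band`, `person_count`
#'   (bands as in [age_bands()]); `NULL` builds a default age pyramid via
#'   [default_population()].
#' @param true_incidence named list (`female`, `male`) of
#'   [piecewise_loglinear()] models generating the true rates.
#' @param planted_duplicate_fraction share of true cases re-admitted 1-60
#'   days later for the same fracture (same site code).
#' @param planted_neoplasia_fraction share (relative to true cases) of extra
#'   neoplasia-associated records.
#' @param planted_s729_fraction share of S72.9 (unspecified femoral site)
#'   plants; of these, `s729_surgery_fraction` are true cases recoded to
#'   S72.9 with hip surgery documented (still ascertainable), the rest extra
#'   non-ascertainable rows.
#' @param s729_surgery_fraction sub-proportion of S72.9 plants with hip
#'   surgery.
#' @param planted_prioryear_fraction share of true cases given an additional
#'   same-site admission in the previous calendar year (within 365 days), so
#'   the index-year admission must be excluded by the prior-year rule.
#' @param refused_hospitalization_fraction share of true cases recorded as
#'   ambulance contacts with hospitalization refused (these remain valid
#'   cases).
#' @param year calendar year of the simulated registry (default 2011).
#' @param seed integer random seed.
#' @return an object of class `registry_sim_config`.
#' @export
registry_sim_config <- function(regions = c("vinnitsa_city", "uzhgorod",
                                            "vinnitsa_area"),
                                population = NULL,
                                true_incidence = default_true_incidence(),
                                planted_duplicate_fraction = 0.05,
                                planted_neoplasia_fraction = 0.02,
                                planted_s729_fraction = 0.03,
                                s729_surgery_fraction = 0.5,
                                planted_prioryear_fraction = 0.01,
                                refused_hospitalization_fraction = 0.10,
                                year = 2011,
                                seed = 1L) {
  stopifnot(length(regions) >= 1L, !anyDuplicated(regions))
  if (is.null(population)) population <- default_population(regions, year = year)
  check_columns(population, c("region", "sex", "age_band", "person_count"),
                "population")
  check_sex(population$sex)
  if (any(population$person_count < 0)) stop("populations must be non-negative")
  stopifnot(is.list(true_incidence), all(SEXES %in% names(true_incidence)))
  for (s in SEXES) stopifnot(inherits(true_incidence[[s]], "piecewise_loglinear"))
  fracs <- c(duplicate = planted_duplicate_fraction,
             neoplasia = planted_neoplasia_fraction,
             s729 = planted_s729_fraction,
             prioryear = planted_prioryear_fraction,
             refused = refused_hospitalization_fraction)
  if (any(fracs < 0) || any(fracs > 1) ||
      s729_surgery_fraction < 0 || s729_surgery_fraction > 1) {
    stop("all planted fractions must lie in [0, 1]")
  }
  # duplicate/prior-year/refused/recoded-S72.9 plants are drawn without
  # replacement from the true cases, hence must jointly fit.
  exclusive <- planted_duplicate_fraction + planted_prioryear_fraction +
    refused_hospitalization_fraction +
    planted_s729_fraction * s729_surgery_fraction
  if (exclusive > 1) {
    stop("mutually exclusive planted fractions sum to more than 1 (",
         signif(exclusive, 3), ")")
  }
  structure(
    list(regions = regions, population = population,
         true_incidence = true_incidence[SEXES],
         planted_duplicate_fraction = planted_duplicate_fraction,
         planted_neoplasia_fraction = planted_neoplasia_fraction,
         planted_s729_fraction = planted_s729_fraction,
         s729_surgery_fraction = s729_surgery_fraction,
         planted_prioryear_fraction = planted_prioryear_fraction,
         refused_hospitalization_fraction = refused_hospitalization_fraction,
         year = year, seed = as.integer(seed)),
    class = "registry_sim_config"
  )
}

#' Default sex-specific incidence surfaces for simulation
#'
#' Low-incidence-country hip-fracture hazards: men exceed women below the
#' mid-60s, after which the female rate rises more steeply — the qualitative
#' age-by-sex pattern seen in Eastern European registry data.
#'
#' @return named list of [piecewise_loglinear()] models.
#' @export
default_true_incidence <- function() {
  list(
    female = piecewise_loglinear("female", intercept = log(1.0e-4),
                                 slope_pre = 0.040, slope_post = 0.130),
    male = piecewise_loglinear("male", intercept = log(1.5e-4),
                               slope_pre = 0.025, slope_post = 0.090)
  )
}

#' Default catchment population pyramid
#'
#' A plausible regional age pyramid from 40 years: band populations decline
#' roughly geometrically with age, women outnumbering men increasingly at
#' older ages.
#'
#' @param regions region identifiers.
#' @param base persons in the 40-44 band per sex and region.
#' @param year calendar year recorded in the table.
#' @return population table (`region`, `sex`, `age_band`, `person_count`,
#'   `year`).
#' @export
default_population <- function(regions, base = 12000, year = 2011) {
  bands <- age_bands()
  k <- seq_along(bands) - 1L
  male <- round(base * 0.92^k * 0.97^pmax(k - 4, 0))
  female <- round(base * 0.95^k)
  do.call(rbind, lapply(regions, function(r) {
    data.frame(region = r,
               sex = rep(SEXES, each = length(bands)),
               age_band = rep(bands, 2L),
               person_count = c(female, male),
               year = year)
  }))
}

#' Generate a synthetic registry with known ground truth
#'
#' Emits one row per admission/contact, including the planted registry
#' pathology, together with a `sim_truth` record of exactly what was
#' planted. Re-running with the same config (and its seed) reproduces the
#' registry exactly.
#'
#' @param config a [registry_sim_config()].
#' @return list with components `registry` (data frame in registry format,
#'   see [read_registry()]) and `truth` (class `sim_truth`: `n_true_cases`
#'   per region/sex/band, `n_planted_exclusions` per category, `n_rows`).
#' @export
#' @examples
#' sim <- generate_registry(registry_sim_config(seed = 42))
#' sim$truth$n_planted_exclusions
generate_registry <- function(config) {
  stopifnot(inherits(config, "registry_sim_config"))
  set.seed(config$seed)
  pop <- config$population
  year <- config$year
  year_start <- as.Date(sprintf("%d-01-01", year))
  year_days <- as.integer(as.Date(sprintf("%d-12-31", year)) - year_start) + 1L

  rows <- vector("list", nrow(pop))
  id_counter <- 0L
  for (i in seq_len(nrow(pop))) {
    sex <- pop$sex[i]
    band <- pop$age_band[i]
    mid <- band_midpoint(band)
    rate <- predict_rate(config$true_incidence[[sex]], min(mid, 110))
    if (pop$person_count[i] == 0) {
      if (rate > 0) {
        stop("zero population with nonzero incidence in band ", band,
             " (", sex, ", ", pop$region[i], ")")
      }
      next
    }
    n <- stats::rpois(1L, rate * pop$person_count[i])
    if (n == 0L) next
    lo <- band_lower(band)
    ages <- lo + sample.int(5L, n, replace = TRUE) - 1L
    dates <- year_start + sample.int(year_days, n, replace = TRUE) - 1L
    ids <- sprintf("%s-%06d", pop$region[i], id_counter + seq_len(n))
    id_counter <- id_counter + n
    rows[[i]] <- data.frame(
      patient_id = ids, region = pop$region[i], sex = sex, age_years = ages,
      admission_date = dates,
      icd10_code = sample(HIP_CODES, n, replace = TRUE,
                          prob = c(0.45, 0.45, 0.10)),
      hip_surgery = stats::runif(n) < 0.85,
      neoplasia = FALSE,
      refused_hospitalization = FALSE,
      source = sample(c("hospital", "outpatient"), n, replace = TRUE,
                      prob = c(0.8, 0.2))
    )
  }
  cases <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(cases)) cases <- empty_registry()
  n_true <- nrow(cases)

  truth_cases <- if (n_true > 0) {
    stats::aggregate(
      list(n = rep(1L, n_true)),
      by = list(region = cases$region, sex = cases$sex,
                age_band = band_of_age(cases$age_years)),
      FUN = sum
    )
  } else {
    data.frame(region = character(0), sex = character(0),
               age_band = character(0), n = integer(0))
  }

  # Assign mutually exclusive plant roles to distinct true cases.
  n_dup <- as.integer(round(config$planted_duplicate_fraction * n_true))
  n_prior <- as.integer(round(config$planted_prioryear_fraction * n_true))
  n_refus <- as.integer(round(config$refused_hospitalization_fraction * n_true))
  n_s729 <- as.integer(round(config$planted_s729_fraction * n_true))
  n_s729_surg <- as.integer(round(config$s729_surgery_fraction * n_s729))
  n_s729_extra <- n_s729 - n_s729_surg
  n_neo <- as.integer(round(config$planted_neoplasia_fraction * n_true))

  picks <- if (n_true > 0) sample.int(n_true) else integer(0)
  take <- function(k) {
    out <- utils::head(picks, k)
    picks <<- utils::tail(picks, -k)
    out
  }
  i_dup <- take(n_dup); i_prior <- take(n_prior)
  i_refus <- take(n_refus); i_surg <- take(n_s729_surg)

  if (n_refus > 0) {
    cases$source[i_refus] <- "ambulance"
    cases$refused_hospitalization[i_refus] <- TRUE
  }
  if (n_s729_surg > 0) {
    cases$icd10_code[i_surg] <- UNSPECIFIED_CODE
    cases$hip_surgery[i_surg] <- TRUE
  }

  extras <- list()
  if (n_dup > 0) {
    dup <- cases[i_dup, , drop = FALSE]
    # re-admission 1-60 days later, capped at year end so the pair stays a
    # same-year duplicate rather than straddling into the next calendar year
    dup$admission_date <- pmin(
      dup$admission_date + sample(1:60, n_dup, replace = TRUE),
      as.Date(sprintf("%d-12-31", year))
    )
    dup$source <- "hospital"
    extras$dup <- dup
  }
  if (n_prior > 0) {
    # clamp leap-year day 366 so the prior-year admission stays within the
    # 365-day exclusion window of the index admission
    late <- i_prior[as.integer(cases$admission_date[i_prior] - year_start) + 1L > 365L]
    cases$admission_date[late] <- year_start + 364L
    pri <- cases[i_prior, , drop = FALSE]
    doy <- as.integer(pri$admission_date - year_start) + 1L
    slack <- pmax(364L - doy, 0L)
    back <- vapply(slack, function(s) sample.int(s + 1L, 1L) - 1L, integer(1))
    pri$admission_date <- as.Date(sprintf("%d-12-31", year - 1L)) - back
    pri$age_years <- pmax(pri$age_years - 1L, 40L)
    pri$source <- "hospital"
    extras$prior <- pri
  }
  if (n_neo > 0) {
    src <- cases[sample.int(n_true, n_neo, replace = TRUE), , drop = FALSE]
    src$patient_id <- sprintf("neo-%06d", seq_len(n_neo))
    src$neoplasia <- TRUE
    extras$neo <- src
  }
  if (n_s729_extra > 0) {
    src <- cases[sample.int(n_true, n_s729_extra, replace = TRUE), , drop = FALSE]
    src$patient_id <- sprintf("s729-%06d", seq_len(n_s729_extra))
    src$icd10_code <- UNSPECIFIED_CODE
    src$hip_surgery <- FALSE
    extras$s729 <- src
  }

  registry <- do.call(rbind, c(list(cases), unname(extras)))
  rownames(registry) <- NULL
  truth <- structure(
    list(
      n_true_cases = truth_cases,
      n_planted_exclusions = c(duplicate_same_fracture = n_dup,
                               neoplasia = n_neo,
                               s729_no_surgery = n_s729_extra,
                               prior_year_same_site = n_prior),
      n_refused_retained = n_refus,
      n_rows = nrow(registry)
    ),
    class = "sim_truth"
  )
  stopifnot(truth$n_rows == n_true + n_dup + n_prior + n_neo + n_s729_extra)
  list(registry = registry, truth = truth)
}

empty_registry <- function() {
  data.frame(patient_id = character(0), region = character(0),
             sex = character(0), age_years = integer(0),
             admission_date = as.Date(character(0)),
             icd10_code = character(0), hip_surgery = logical(0),
             neoplasia = logical(0), refused_hospitalization = logical(0),
             source = character(0))
}

#' Emit the catchment population table of a simulation config
#'
#' @param config a [registry_sim_config()].
#' @return the population table (`region`, `sex`, `age_band`,
#'   `person_count`, `year`), one row per (region, sex, band).
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "registry_sim_config"))
  pop <- config$population
  if (!"year" %in% names(pop)) pop$year <- config$year
  rownames(pop) <- NULL
  pop
}

#' Generate a Gompertz death-hazard table
#'
#' Tabulates `h_d(a) = alpha * exp(beta * a)` per single year of age 40-110
#' for each sex, a Gompertz-like stand-in for national life-table mortality.
#'
#' @param alpha baseline hazard at age 0 (per person-year); scalar or one
#'   value per sex.
#' @param beta log-hazard slope per year of age; scalar or one per sex.
#' @param sexes sexes to tabulate.
#' @return death-hazard table (`sex`, `age`, `hazard`).
#' @export
#' @examples
#' generate_mortality(1e-5, 0.1)[1:3, ]
generate_mortality <- function(alpha, beta, sexes = c("female", "male")) {
  check_sex(sexes)
  if (any(alpha <= 0)) stop("alpha must be > 0")
  if (any(beta < 0)) stop("beta must be >= 0")
  alpha <- rep_len(alpha, length(sexes))
  beta <- rep_len(beta, length(sexes))
  ages <- 40:110
  do.call(rbind, lapply(seq_along(sexes), function(i) {
    data.frame(sex = sexes[i], age = ages,
               hazard = alpha[i] * exp(beta[i] * ages))
  }))
}

#' Derive a reference model by scaling the hip hazard
#'
#' Returns a copy of `base` whose hip hazard is multiplied by
#' `incidence_scale` at every age (the intercepts shift by
#' `log(incidence_scale)`); the death hazard and risk-model configuration
#' are untouched. Used to construct pairs of models that differ only in
#' their incidence calibration, the situation that arises when a model
#' borrowed from another country is compared with an authentic one.
#'
#' @param base a [country_model()].
#' @param incidence_scale positive multiplicative factor.
#' @return a [country_model()].
#' @export
generate_reference_model <- function(base, incidence_scale) {
  stopifnot(inherits(base, "country_model"),
            is.numeric(incidence_scale), incidence_scale > 0)
  out <- base
  for (s in SEXES) {
    out$hip[[s]]$intercept <- out$hip[[s]]$intercept + log(incidence_scale)
  }
  out
}
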