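# Case ascertainment: registry inclusion/exclusion rules, banded incidence
# per region, and population-weighted amalgamation across catchments.

#' Apply registry case inclusion and exclusion rules
#'
#' Retains hip-fracture cases defined by ICD-10 codes S72.0 (femoral neck),
#' S72.1 (trochanter) and S72.2 (subtrochanter), plus S72.9 (unspecified site
#' of femoral fracture) when a surgical procedure indicated surgery on the
#' hip. Cases associated with neoplasia are excluded, as are patients below
#' the minimum ascertainment age. Multiple admissions for the same fracture
#' — the same patient and site code within 365 days — are collapsed to the
#' earliest admission; a later admission is logged as a duplicate when the
#' earlier one falls in the same calendar year and as a prior-year same-site
#' fracture when it falls in the previous calendar year. Ambulance contacts
#' where the patient refused hospitalization are retained, and no
#' residence-based exclusion is applied (cases count irrespective of region
#' or country of origin).
#'
#' @param records data frame of case records with columns `patient_id`,
#'   `region`, `sex`, `age_years`, `admission_date` (`Date` or ISO-8601
#'   string), `icd10_code`, `hip_surgery`, `neoplasia`,
#'   `refused_hospitalization`, `source`.
#' @param min_age minimum ascertainment age in years (default 40, the lower
#'   age limit of FRAX-style models).
#' @return a list with components
#'   \describe{
#'     \item{included}{data frame of retained case records,}
#'     \item{excluded}{data frame of dropped records with a `reason` column,
#'       one reason per record, drawn from `duplicate_same_fracture`,
#'       `neoplasia`, `s729_no_surgery`, `prior_year_same_site`,
#'       `non_hip_code`, `under_age`.}
#'   }
#'   Always `nrow(included) + nrow(excluded) == nrow(records)`.
#' @export
#' @examples
#' reg <- read_registry(system.file("extdata", "registry_fixture.csv",
#'                                  package = "fraxbuild"))
#' res <- filter_cases(reg)
#' table(res$excluded$reason)
filter_cases <- function(records, min_age = 40) {
  records <- validate_registry(records)
  n <- nrow(records)
  if (n == 0L) {
    return(list(included = records,
                excluded = cbind(records, reason = character(0))))
  }
  reason <- rep(NA_character_, n)

  qualifying_code <- records$icd10_code %in% HIP_CODES |
    (records$icd10_code == UNSPECIFIED_CODE & records$hip_surgery)
  reason[!(records$icd10_code %in% c(HIP_CODES, UNSPECIFIED_CODE))] <- "non_hip_code"
  reason[is.na(reason) & records$neoplasia] <- "neoplasia"
  reason[is.na(reason) & !qualifying_code] <- "s729_no_surgery"
  reason[is.na(reason) & records$age_years < min_age] <- "under_age"

  # Deduplicate the remaining qualifying admissions: one fracture per
  # (patient, site code) per 365-day window, earliest admission retained.
  cand <- which(is.na(reason))
  key <- paste(records$patient_id[cand], records$icd10_code[cand], sep = "\r")
  for (idx in split(cand, key)) {
    if (length(idx) < 2L) next
    o <- idx[order(records$admission_date[idx], idx)]
    last_kept <- o[1L]
    for (j in o[-1L]) {
      gap <- as.numeric(records$admission_date[j] -
                          records$admission_date[last_kept])
      if (gap <= 365) {
        same_year <- format(records$admission_date[j], "%Y") ==
          format(records$admission_date[last_kept], "%Y")
        reason[j] <- if (same_year) "duplicate_same_fracture" else "prior_year_same_site"
      } else {
        last_kept <- j  # a genuine re-fracture more than a year later
      }
    }
  }

  excl <- !is.na(reason)
  excluded <- records[excl, , drop = FALSE]
  excluded$reason <- reason[excl]
  list(included = records[!excl, , drop = FALSE], excluded = excluded)
}

validate_registry <- function(records) {
  check_columns(records, c("patient_id", "region", "sex", "age_years",
                           "admission_date", "icd10_code", "hip_surgery",
                           "neoplasia", "refused_hospitalization", "source"),
                "registry")
  if (!inherits(records$admission_date, "Date")) {
    parsed <- as.Date(as.character(records$admission_date), format = "%Y-%m-%d")
    bad <- which(is.na(parsed) & !is.na(records$admission_date))
    if (length(bad)) {
      stop("unparseable admission_date at row(s) ",
           paste(utils::head(bad, 5), collapse = ", "),
           ": expected ISO-8601 (YYYY-MM-DD)")
    }
    records$admission_date <- parsed
  }
  if (anyNA(records$admission_date)) {
    stop("missing admission_date at row(s) ",
         paste(utils::head(which(is.na(records$admission_date)), 5), collapse = ", "))
  }
  bad_sex <- which(!(records$sex %in% SEXES))
  if (length(bad_sex)) {
    stop("unknown sex value at row(s) ", paste(utils::head(bad_sex, 5), collapse = ", "),
         ": must be one of ", paste(SEXES, collapse = "/"))
  }
  if (any(records$age_years < 0, na.rm = TRUE) || anyNA(records$age_years)) {
    stop("age_years must be a non-negative integer for every record")
  }
  for (col in c("hip_surgery", "neoplasia", "refused_hospitalization")) {
    records[[col]] <- as.logical(records[[col]])
    if (anyNA(records[[col]])) stop("column ", col, " must be logical (TRUE/FALSE)")
  }
  records
}

#' Tabulate incidence by sex and 5-year age band
#'
#' Rates are the number of ascertained cases in each 5-year age interval
#' divided by the age- and sex-specific catchment population, expressed per
#' person-year. The population table supplies one observation year of
#' denominator; multi-year observation windows multiply the person-years.
#'
#' @param included data frame of filtered case records (see [filter_cases()]).
#' @param population population table: columns `region`, `sex`, `age_band`,
#'   `person_count` (and optionally `year`).
#' @param region region identifier; cases and population are restricted to
#'   it. `NULL` pools all regions in both numerator and denominator.
#' @param years length of the observation window in years (default 1).
#' @return an incidence table: columns `sex`, `age_band`, `n_cases`,
#'   `person_years`, `rate`, with attribute `region`.
#' @export
tabulate_incidence <- function(included, population, region = NULL, years = 1) {
  check_columns(population, c("region", "sex", "age_band", "person_count"),
                "population table")
  stopifnot(is.numeric(years), years > 0)
  if (!is.null(region)) {
    included <- included[included$region == region, , drop = FALSE]
    population <- population[population$region == region, , drop = FALSE]
    if (nrow(population) == 0L) stop("no population rows for region ", region)
  } else if (length(unique(population$region)) > 1L) {
    population <- stats::aggregate(person_count ~ sex + age_band,
                                   data = population, FUN = sum)
    population$region <- "pooled"
  }
  bands <- unique(population$age_band)
  from <- min(band_lower(bands))
  top <- max(band_lower(bands))

  tab <- population[, c("sex", "age_band", "person_count")]
  tab$n_cases <- 0L
  if (nrow(included) > 0L) {
    case_band <- band_of_age(included$age_years, from = from, top = top)
    counts <- table(paste(included$sex, case_band, sep = "\r"))
    key <- paste(tab$sex, tab$age_band, sep = "\r")
    hit <- match(names(counts), key)
    if (anyNA(hit)) {
      missing <- names(counts)[is.na(hit)]
      stop("case(s) fall in a (sex, band) with no population row: ",
           paste(gsub("\r", " ", missing), collapse = "; "))
    }
    tab$n_cases[hit] <- as.integer(counts)
  }
  zero_pop <- tab$person_count <= 0 & tab$n_cases > 0
  if (any(zero_pop)) {
    stop("case(s) in band(s) with zero recorded population: ",
         paste(paste(tab$sex[zero_pop], tab$age_band[zero_pop]), collapse = "; "))
  }
  tab$person_years <- tab$person_count * years
  tab$rate <- ifelse(tab$person_years > 0, tab$n_cases / tab$person_years, 0)
  tab <- tab[order(match(tab$sex, SEXES), band_lower(tab$age_band)),
             c("sex", "age_band", "n_cases", "person_years", "rate")]
  rownames(tab) <- NULL
  attr(tab, "region") <- region %||% "pooled"
  attr(tab, "years") <- years
  tab
}

#' Amalgamate regional incidence tables weighted by catchment population
#'
#' Pools regional rates per (sex, age band) as the catchment-population
#' weighted mean: `sum(rate_r * pop_r) / sum(pop_r)`. When every region has
#' the same observation-window length this equals pooling raw numerators and
#' person-years. Numerators and person-years are carried through by
#' summation.
#'
#' @param tables list of incidence tables from [tabulate_incidence()], each
#'   carrying its `region` attribute.
#' @param populations population table covering every (region, sex, band) in
#'   `tables`.
#' @return a pooled incidence table (attribute `region = "pooled"`).
#' @export
amalgamate_incidence <- function(tables, populations) {
  stopifnot(length(tables) >= 1L)
  check_columns(populations, c("region", "sex", "age_band", "person_count"),
                "population table")
  ref <- tables[[1L]][, c("sex", "age_band")]
  for (tab in tables[-1L]) {
    if (!identical(tab[, c("sex", "age_band")], ref)) {
      stop("incidence tables have mismatched (sex, age_band) structures")
    }
  }
  if (length(tables) == 1L) return(tables[[1L]])

  key <- paste(ref$sex, ref$age_band, sep = "\r")
  wsum <- num <- cases <- py <- rep(0, nrow(ref))
  for (tab in tables) {
    region <- attr(tab, "region")
    pop <- populations[populations$region == region, , drop = FALSE]
    if (nrow(pop) == 0L) stop("no population rows for region ", region)
    w <- pop$person_count[match(key, paste(pop$sex, pop$age_band, sep = "\r"))]
    if (anyNA(w)) stop("population table does not cover every band of region ", region)
    num <- num + tab$rate * w
    wsum <- wsum + w
    cases <- cases + tab$n_cases
    py <- py + tab$person_years
  }
  out <- data.frame(sex = ref$sex, age_band = ref$age_band,
                    n_cases = cases, person_years = py,
                    rate = ifelse(wsum > 0, num / wsum, 0))
  attr(out, "region") <- "pooled"
  out
}
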