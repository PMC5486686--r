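# Internal helpers: age-band arithmetic, argument checks.

SEXES <- c("female", "male")
HIP_CODES <- c("S72.0", "S72.1", "S72.2")
UNSPECIFIED_CODE <- "S72.9"
RISK_FACTORS <- c(
  "prior_fracture", "parental_hip_fracture", "current_smoking",
  "glucocorticoids", "rheumatoid_arthritis", "secondary_osteoporosis",
  "alcohol_excess"
)
EXCLUSION_REASONS <- c(
  "duplicate_same_fracture", "neoplasia", "s729_no_surgery",
  "prior_year_same_site", "non_hip_code", "under_age"
)

#' Standard 5-year age bands
#'
#' Bands are half-open `[lo, lo + 5)` from `from` upwards, with an open-ended
#' top band labelled `"<top>+"` (default `95+`).
#'
#' @param from lower edge of the first band (years).
#' @param top lower edge of the open-ended top band (years).
#' @return character vector of band labels, e.g. `"40-44"`, ..., `"95+"`.
#' @export
#' @examples
#' age_bands()
age_bands <- function(from = 40, top = 95) {
  stopifnot(top > from, (top - from) %% 5 == 0)
  los <- seq(from, top - 5, by = 5)
  c(sprintf("%d-%d", los, los + 4), sprintf("%d+", top))
}

#' Assign integer ages to 5-year bands
#'
#' @param age integer ages in years.
#' @param from,top band structure as in [age_bands()].
#' @return character band labels (ages at or above `top` map to the top band).
#' @export
band_of_age <- function(age, from = 40, top = 95) {
  if (any(age < from)) {
    stop("age below the lowest band (", from, "): ", paste(age[age < from], collapse = ", "))
  }
  lo <- pmin(from + 5 * ((age - from) %/% 5), top)
  ifelse(lo >= top, sprintf("%d+", top), sprintf("%d-%d", lo, lo + 4))
}

#' Band midpoint age used as the regression abscissa
#'
#' Closed bands `[lo, lo+5)` map to `lo + 2.5`; the open top band also uses
#' `lo + 2.5` so a single rule covers the whole table.
#'
#' @param band character band labels (`"40-44"` or `"95+"` style).
#' @return numeric midpoints in years.
#' @export
band_midpoint <- function(band) {
  lo <- band_lower(band)
  lo + 2.5
}

band_lower <- function(band) {
  out <- suppressWarnings(as.numeric(sub("^(\\d+)[-+].*$", "\\1", paste0(band, "-"))))
  if (any(is.na(out))) {
    stop("unparseable age band label(s): ", paste(unique(band[is.na(out)]), collapse = ", "))
  }
  out
}

is_top_band <- function(band) grepl("\\+$", band)

check_sex <- function(sex, where = "sex") {
  bad <- !(sex %in% SEXES)
  if (any(bad)) {
    stop(where, " must be one of ", paste(SEXES, collapse = "/"),
         "; got: ", paste(unique(sex[bad]), collapse = ", "))
  }
  invisible(sex)
}

check_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(what, " is missing column(s): ", paste(miss, collapse = ", "))
  }
  invisible(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
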