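# Ascertainment rules, banded incidence, and population-weighted pooling.

test_that("the packaged fixture yields 5 retained cases and 5 distinct exclusions", {
  res <- filter_cases(fixture_registry())
  expect_identical(nrow(res$included), 5L)
  expect_identical(nrow(res$excluded), 5L)
  expect_setequal(res$excluded$reason,
                  c("duplicate_same_fracture", "neoplasia", "s729_no_surgery",
                    "prior_year_same_site", "non_hip_code"))
  # the right records survive: earliest admissions, the S72.9-with-surgery
  # case, the ambulance refusal, and the prior-year anchor fracture
  expect_setequal(
    paste(res$included$patient_id, res$included$admission_date),
    c("P001 2011-03-14", "P002 2011-05-02", "P003 2010-08-16",
      "P006 2011-08-17", "P007 2011-11-29")
  )
})

test_that("empty and all-clean inputs pass through the filter unchanged", {
  empty <- fixture_registry()[0, ]
  res <- filter_cases(empty)
  expect_identical(nrow(res$included), 0L)
  expect_identical(nrow(res$excluded), 0L)

  clean <- fixture_registry()[c(1, 2, 8), ]  # distinct patients, clean codes
  res <- filter_cases(clean)
  expect_identical(nrow(res$included), 3L)
  expect_identical(nrow(res$excluded), 0L)
})

test_that("filtering conserves records, is order-independent and idempotent", {
  set.seed(31)
  sim <- generate_registry(registry_sim_config(seed = 31))
  reg <- sim$registry
  res <- filter_cases(reg)
  expect_identical(nrow(res$included) + nrow(res$excluded), nrow(reg))

  perm <- reg[sample.int(nrow(reg)), ]
  res_perm <- filter_cases(perm)
  key <- function(df) sort(paste(df$patient_id, df$admission_date, df$icd10_code))
  expect_identical(key(res_perm$included), key(res$included))

  again <- filter_cases(res$included)
  expect_identical(nrow(again$excluded), 0L)
  expect_identical(key(again$included), key(res$included))
})

test_that("a re-fracture more than a year later is a new case", {
  reg <- fixture_registry()[c(1, 1), ]
  reg$admission_date[2] <- reg$admission_date[1] + 400
  res <- filter_cases(reg)
  expect_identical(nrow(res$included), 2L)
})

test_that("invalid sex or dates raise errors naming the row", {
  reg <- fixture_registry()
  reg$sex[4] <- "unknown"
  expect_error(filter_cases(reg), "row\\(s\\) 4")
  reg2 <- read.csv(system.file("extdata", "registry_fixture.csv",
                               package = "fraxbuild"))
  reg2$admission_date[7] <- "not-a-date"
  expect_error(filter_cases(reg2), "row\\(s\\) 7")
})

test_that("banded rates are cases over person-years", {
  pop <- data.frame(region = "r1",
                    sex = rep(c("female", "male"), each = 12),
                    age_band = rep(age_bands(), 2),
                    person_count = 10000)
  cases <- data.frame(
    patient_id = sprintf("c%d", 1:5), region = "r1", sex = "female",
    age_years = c(70, 71, 72, 73, 74),
    admission_date = as.Date("2011-06-01") + 0:4,
    icd10_code = "S72.0", hip_surgery = TRUE, neoplasia = FALSE,
    refused_hospitalization = FALSE, source = "hospital"
  )
  tab <- tabulate_incidence(cases, pop, region = "r1", years = 1)
  row <- tab[tab$sex == "female" & tab$age_band == "70-74", ]
  expect_equal(row$rate, 5e-4)
  expect_identical(row$n_cases, 5L)
  # bands with no cases get rate zero, not NA
  expect_true(all(tab$rate[tab$age_band == "40-44"] == 0))
  # a 2-year observation window halves the rate for the same counts
  tab2 <- tabulate_incidence(cases, pop, region = "r1", years = 2)
  expect_equal(tab2$rate[tab2$sex == "female" & tab2$age_band == "70-74"],
               2.5e-4)
  # a case in a band with zero recorded population cannot form a rate
  pop0 <- pop
  pop0$person_count[pop0$sex == "female" & pop0$age_band == "70-74"] <- 0
  expect_error(tabulate_incidence(cases, pop0, region = "r1"),
               "zero recorded population")
})

test_that("amalgamation is the catchment-population weighted mean of rates", {
  bands <- age_bands()
  mk <- function(region, rate, pop_n) {
    tab <- data.frame(sex = rep(c("female", "male"), each = 12),
                      age_band = rep(bands, 2),
                      n_cases = as.integer(round(rate * pop_n)),
                      person_years = pop_n, rate = rate)
    attr(tab, "region") <- region
    tab
  }
  # rates 100 and 300 per 100,000 with populations 200,000 and 600,000
  pops <- rbind(
    data.frame(region = "a", sex = rep(c("female", "male"), each = 12),
               age_band = rep(bands, 2), person_count = 200000),
    data.frame(region = "b", sex = rep(c("female", "male"), each = 12),
               age_band = rep(bands, 2), person_count = 600000)
  )
  pooled <- amalgamate_incidence(
    list(mk("a", 100 / 1e5, 200000), mk("b", 300 / 1e5, 600000)), pops
  )
  expect_equal(unique(pooled$rate), 250 / 1e5)
  # identical rates pool to themselves
  pooled_eq <- amalgamate_incidence(
    list(mk("a", 2e-3, 200000), mk("b", 2e-3, 600000)), pops
  )
  expect_equal(unique(pooled_eq$rate), 2e-3)
  # a single region is returned unchanged
  one <- mk("a", 1e-3, 1000)
  expect_identical(amalgamate_incidence(list(one), pops), one)
  # mismatched band structures are rejected
  short <- mk("b", 1e-3, 1000)[-1, ]
  expect_error(amalgamate_incidence(list(one, short), pops), "mismatched")
})

test_that("weighted amalgamation equals raw pooling for equal-length windows", {
  set.seed(17)
  bands <- age_bands()
  template <- data.frame(sex = rep(c("female", "male"), each = 12),
                         age_band = rep(bands, 2))
  for (rep_i in 1:25) {
    n_regions <- sample(2:4, 1)
    tabs <- list()
    pops <- list()
    for (r in seq_len(n_regions)) {
      region <- paste0("r", r)
      pop_n <- sample(5000:500000, nrow(template), replace = TRUE)
      cases <- rpois(nrow(template), lambda = runif(nrow(template), 0, 50))
      tab <- cbind(template,
                   n_cases = cases, person_years = pop_n,
                   rate = cases / pop_n)
      attr(tab, "region") <- region
      tabs[[r]] <- tab
      pops[[r]] <- cbind(region = region, template, person_count = pop_n)
    }
    pops <- do.call(rbind, pops)
    pooled <- amalgamate_incidence(tabs, pops)
    raw_cases <- Reduce(`+`, lapply(tabs, `[[`, "n_cases"))
    raw_py <- Reduce(`+`, lapply(tabs, `[[`, "person_years"))
    expect_equal(pooled$rate, raw_cases / raw_py, tolerance = 1e-12)
  }
})
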