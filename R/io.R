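# Readers and writers for the pipeline's CSV/JSON artifacts, the packaged
# example configuration, and the end-to-end pipeline driver.

REGISTRY_COLUMNS <- c("patient_id", "region", "sex", "age_years",
                      "admission_date", "icd10_code", "hip_surgery",
                      "neoplasia", "refused_hospitalization", "source")

#' Read and write registry CSV files
#'
#' The registry format is one row per admission/contact with columns
#' `patient_id`, `region`, `sex`, `age_years`, `admission_date` (ISO-8601),
#' `icd10_code`, `hip_surgery`, `neoplasia`, `refused_hospitalization`,
#' `source`. Errors name the offending row and column.
#'
#' @param path CSV file path.
#' @return `read_registry()`: a validated registry data frame with parsed
#'   dates and logical flags.
#' @export
read_registry <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, REGISTRY_COLUMNS, paste0("registry file ", path))
  validate_registry(df)
}

#' @rdname read_registry
#' @param registry a registry data frame.
#' @export
write_registry <- function(registry, path) {
  check_columns(registry, REGISTRY_COLUMNS, "registry")
  out <- registry[, REGISTRY_COLUMNS]
  out$admission_date <- format(as.Date(out$admission_date), "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read and write population tables
#'
#' @param path CSV file path.
#' @return `read_population()`: data frame `region`, `sex`, `age_band`,
#'   `person_count` (+ `year` when present).
#' @export
read_population <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("region", "sex", "age_band", "person_count"),
                paste0("population file ", path))
  check_sex(df$sex)
  band_lower(df$age_band)  # validates labels
  if (any(df$person_count < 0)) stop("negative person_count in ", path)
  df
}

#' @rdname read_population
#' @param population a population table.
#' @export
write_population <- function(population, path) {
  utils::write.csv(population, path, row.names = FALSE)
  invisible(path)
}

#' Read and write death-hazard tables
#'
#' @param path CSV file path with columns `sex`, `age`, `hazard`.
#' @return `read_mortality()`: validated death-hazard data frame.
#' @export
read_mortality <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("sex", "age", "hazard"), paste0("mortality file ", path))
  check_sex(df$sex)
  if (any(df$hazard < 0)) stop("negative death hazard in ", path)
  df
}

#' @rdname read_mortality
#' @param mortality a death-hazard table.
#' @export
write_mortality <- function(mortality, path) {
  utils::write.csv(mortality, path, row.names = FALSE)
  invisible(path)
}

#' Read and write incidence tables
#'
#' @param path CSV file path.
#' @return `read_incidence()`: incidence table with its `region` attribute
#'   restored from the `region` column.
#' @export
read_incidence <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("sex", "age_band", "n_cases", "person_years", "rate"),
                paste0("incidence file ", path))
  region <- if ("region" %in% names(df)) unique(df$region)[1L] else "pooled"
  out <- df[, c("sex", "age_band", "n_cases", "person_years", "rate")]
  attr(out, "region") <- region
  out
}

#' @rdname read_incidence
#' @param incidence an incidence table (see [tabulate_incidence()]).
#' @export
write_incidence <- function(incidence, path) {
  out <- cbind(region = attr(incidence, "region") %||% "pooled",
               as.data.frame(incidence))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a fitted piecewise model (set) to JSON
#'
#' @param models named list of [piecewise_loglinear()] models (per sex).
#' @param path JSON file path.
#' @return `read_piecewise()`: named list of models.
#' @export
write_piecewise <- function(models, path) {
  payload <- lapply(models, function(m) {
    m[c("sex", "knot_age", "intercept", "slope_pre", "slope_post",
        "rss", "n_bands")]
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_piecewise
#' @export
read_piecewise <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(payload, function(p) {
    piecewise_loglinear(p$sex, p$intercept, p$slope_pre, p$slope_post,
                        knot_age = p$knot_age,
                        rss = p$rss %||% NA_real_,
                        n_bands = p$n_bands %||% NA_integer_)
  })
}

#' Serialize a country model to a single JSON document
#'
#' The document carries the per-sex piecewise hip-hazard parameters, the
#' tabulated death hazard and the full risk-model configuration, so a saved
#' model is deployable on its own.
#'
#' @param model a [country_model()].
#' @param path JSON file path.
#' @return `read_country_model()`: the reconstructed [country_model()].
#' @export
write_country_model <- function(model, path) {
  stopifnot(inherits(model, "country_model"))
  cfg <- model$config
  payload <- list(
    hip = lapply(model$hip, function(m) {
      m[c("sex", "knot_age", "intercept", "slope_pre", "slope_post")]
    }),
    death = model$death,
    config = list(
      relative_risks = cfg$relative_risks,
      gradient_of_risk = as.list(cfg$gradient_of_risk),
      reference_tscore = cfg$reference_tscore,
      rr_per_bmi_unit = cfg$rr_per_bmi_unit,
      secondary_osteoporosis_inactive_with_bmd =
        cfg$secondary_osteoporosis_inactive_with_bmd,
      hip_to_mof_ratio = cfg$hip_to_mof_ratio
    )
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_country_model
#' @export
read_country_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  hip <- lapply(p$hip, function(h) {
    piecewise_loglinear(h$sex, h$intercept, h$slope_pre, h$slope_post,
                        knot_age = h$knot_age)
  })
  cfg <- risk_model_config(
    relative_risks = as.data.frame(p$config$relative_risks),
    gradient_of_risk = unlist(p$config$gradient_of_risk),
    reference_tscore = p$config$reference_tscore,
    rr_per_bmi_unit = p$config$rr_per_bmi_unit,
    secondary_osteoporosis_inactive_with_bmd =
      p$config$secondary_osteoporosis_inactive_with_bmd,
    hip_to_mof_ratio = if (is.null(p$config$hip_to_mof_ratio)) NULL
                       else as.data.frame(p$config$hip_to_mof_ratio)
  )
  country_model(hip = hip, death = as.data.frame(p$death), config = cfg)
}

#' Load the packaged example risk-model configuration
#'
#' Reads the synthetic-example relative-risk table and hip:MOF ratio table
#' shipped under `inst/extdata/`. These carry published-meta-analysis-scale
#' magnitudes but are synthetic examples, not the proprietary coefficients
#' of any deployed FRAX tool; realistic work should substitute
#' literature-derived values.
#'
#' @return a [risk_model_config()].
#' @export
example_risk_model_config <- function() {
  cfg <- jsonlite::read_json(
    system.file("extdata", "synthetic_example_risk_model.json",
                package = "fraxbuild"),
    simplifyVector = TRUE
  )
  ratios <- utils::read.csv(
    system.file("extdata", "synthetic_example_hip_mof_ratios.csv",
                package = "fraxbuild"),
    stringsAsFactors = FALSE
  )
  risk_model_config(
    relative_risks = as.data.frame(cfg$relative_risks),
    gradient_of_risk = unlist(cfg$gradient_of_risk),
    reference_tscore = cfg$reference_tscore,
    rr_per_bmi_unit = cfg$rr_per_bmi_unit,
    secondary_osteoporosis_inactive_with_bmd =
      cfg$secondary_osteoporosis_inactive_with_bmd,
    hip_to_mof_ratio = ratios
  )
}

#' A ready-made example country model
#'
#' The default synthetic incidence surfaces, a Gompertz death hazard and the
#' packaged example risk-model configuration, assembled into a deployable
#' model — convenient for examples and demonstrations.
#'
#' @param mortality_alpha,mortality_beta Gompertz parameters per sex (female
#'   first), see [generate_mortality()].
#' @return a [country_model()].
#' @export
#' @examples
#' model <- example_country_model()
#' fracture_probability(model, risk_profile(65, "female", prior_fracture = TRUE),
#'                      outcome = "hip", horizon = "ten_year")
example_country_model <- function(mortality_alpha = c(4e-6, 1.2e-5),
                                  mortality_beta = c(0.105, 0.095)) {
  country_model(
    hip = default_true_incidence(),
    death = generate_mortality(mortality_alpha, mortality_beta),
    config = example_risk_model_config()
  )
}

#' Run the whole pipeline end to end
#'
#' Simulate (or load) a registry, apply the ascertainment rules per region,
#' tabulate and amalgamate incidence, smooth it into a continuous-age
#' hazard, assemble the country model, derive a scaled reference model and
#' compare the two over scenario grids. All artifacts plus a reproducibility
#' manifest are written to `out_dir`.
#'
#' @param config list with components
#'   \describe{
#'     \item{out_dir}{output directory (created if needed).}
#'     \item{seed}{integer seed (used for simulation).}
#'     \item{simulate}{`TRUE` (default) to generate synthetic inputs via
#'       [registry_sim_config()]; or a ready `registry_sim_config`.}
#'     \item{registry, population, mortality}{input CSV paths when
#'       `simulate = FALSE`.}
#'     \item{risk_config}{path to a risk-model JSON + ratio CSV pair, or
#'       `NULL` for the packaged example.}
#'     \item{knot_age}{smoothing breakpoint (default 67).}
#'     \item{observation_years}{length of the registry window (default 1).}
#'     \item{reference_scale}{hip-hazard scale of the comparison reference
#'       model (default 0.4).}
#'     \item{ages}{comparison ages (default 50, 60, 70, 80).}
#'     \item{mortality_alpha, mortality_beta}{Gompertz parameters used when
#'       simulating mortality.}
#'   }
#' @return invisibly, a list with the fitted models, the pooled incidence
#'   table, the comparison report and the manifest.
#' @export
run_pipeline <- function(config) {
  cfg <- utils::modifyList(
    list(out_dir = "fraxbuild-run", seed = 1L, simulate = TRUE,
         registry = NULL, population = NULL, mortality = NULL,
         risk_config = NULL, knot_age = 67, observation_years = 1,
         reference_scale = 0.4, ages = c(50, 60, 70, 80),
         mortality_alpha = c(4e-6, 1.2e-5), mortality_beta = c(0.105, 0.095),
         step = 0.02),
    config
  )
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  sim_year <- NULL
  inputs <- stage("simulate-or-load", {
    if (isTRUE(cfg$simulate) || inherits(cfg$simulate, "registry_sim_config")) {
      sim_cfg <- if (inherits(cfg$simulate, "registry_sim_config")) {
        cfg$simulate
      } else {
        registry_sim_config(seed = cfg$seed)
      }
      sim_year <<- sim_cfg$year
      sim <- generate_registry(sim_cfg)
      mort <- generate_mortality(cfg$mortality_alpha, cfg$mortality_beta)
      write_registry(sim$registry, file.path(cfg$out_dir, "registry.csv"))
      write_population(generate_population(sim_cfg),
                       file.path(cfg$out_dir, "population.csv"))
      write_mortality(mort, file.path(cfg$out_dir, "mortality.csv"))
      jsonlite::write_json(unclass(sim$truth),
                           file.path(cfg$out_dir, "sim_truth.json"),
                           auto_unbox = TRUE, digits = NA)
      list(registry = sim$registry,
           population = generate_population(sim_cfg), mortality = mort)
    } else {
      list(registry = read_registry(cfg$registry),
           population = read_population(cfg$population),
           mortality = read_mortality(cfg$mortality))
    }
  })

  asc <- stage("ascertain", {
    res <- filter_cases(inputs$registry)
    included <- res$included
    if (!is.null(sim_year)) {
      # restrict the numerator to the simulated observation year (prior-year
      # anchor admissions are genuine fractures but fall outside the window)
      included <- included[format(included$admission_date, "%Y") ==
                             as.character(sim_year), , drop = FALSE]
    }
    excl <- res$excluded
    excl$admission_date <- format(excl$admission_date, "%Y-%m-%d")
    utils::write.csv(excl, file.path(cfg$out_dir, "exclusions.csv"),
                     row.names = FALSE)
    list(included = included, excluded = res$excluded)
  })

  pooled <- stage("tabulate-amalgamate", {
    regions <- unique(inputs$population$region)
    tables <- lapply(regions, function(r) {
      tabulate_incidence(asc$included, inputs$population, region = r,
                         years = cfg$observation_years)
    })
    pooled <- amalgamate_incidence(tables, inputs$population)
    write_incidence(pooled, file.path(cfg$out_dir, "incidence.csv"))
    pooled
  })

  fits <- stage("fit-incidence", {
    fits <- fit_piecewise_loglinear(pooled, knot_age = cfg$knot_age)
    write_piecewise(fits, file.path(cfg$out_dir, "incidence_model.json"))
    fits
  })

  model <- stage("build-model", {
    risk_cfg <- if (is.null(cfg$risk_config)) {
      example_risk_model_config()
    } else {
      read_country_model(cfg$risk_config)$config
    }
    m <- country_model(hip = fits, death = inputs$mortality, config = risk_cfg)
    write_country_model(m, file.path(cfg$out_dir, "model.json"))
    m
  })

  report <- stage("compare", {
    reference <- generate_reference_model(model, 1 / cfg$reference_scale)
    rep <- compare_models(reference, model, ages = cfg$ages, step = cfg$step)
    utils::write.csv(rep, file.path(cfg$out_dir, "report.csv"),
                     row.names = FALSE)
    jsonlite::write_json(rep, file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    rep
  })

  manifest <- stage("manifest", {
    hashed <- cfg[setdiff(sort(names(cfg)), "out_dir")]
    cfg_json <- jsonlite::toJSON(hashed, auto_unbox = TRUE,
                                 digits = NA, null = "null", force = TRUE)
    outputs <- list.files(cfg$out_dir, pattern = "\\.(csv|json)$",
                          full.names = TRUE)
    outputs <- setdiff(outputs, file.path(cfg$out_dir, "manifest.json"))
    man <- list(
      package = "fraxbuild",
      version = as.character(utils::packageVersion("fraxbuild")),
      r_version = as.character(getRversion()),
      seed = cfg$seed,
      config_md5 = unname(md5_string(cfg_json)),
      outputs = stats::setNames(as.list(unname(tools::md5sum(outputs))),
                                basename(outputs))
    )
    jsonlite::write_json(man, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    man
  })

  invisible(list(model = model, incidence = pooled, fits = fits,
                 report = report, manifest = manifest,
                 exclusions = asc$excluded))
}

md5_string <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(x), tf)
  tools::md5sum(tf)
}
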