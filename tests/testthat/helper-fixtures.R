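# Shared builders for tests: small deterministic models and tables.

fixture_registry <- function() {
  read_registry(system.file("extdata", "registry_fixture.csv",
                            package = "fraxbuild"))
}

# A minimal risk-model config with hand-picked round numbers.
toy_risk_config <- function(ratio = 4) {
  risk_model_config(
    relative_risks = data.frame(
      factor = c("prior_fracture", "parental_hip_fracture", "current_smoking",
                 "glucocorticoids", "rheumatoid_arthritis",
                 "secondary_osteoporosis", "alcohol_excess"),
      hip = c(2.0, 1.5, 1.3, 1.8, 1.4, 1.6, 1.7),
      mof = c(1.8, 1.4, 1.25, 1.6, 1.35, 1.4, 1.5)
    ),
    gradient_of_risk = c(hip = 2.6, mof = 1.6),
    hip_to_mof_ratio = data.frame(
      sex = rep(c("female", "male"), each = 2),
      age = rep(c(50, 80), 2),
      ratio = rep(ratio, 4)
    )
  )
}

toy_country_model <- function(scale = 1, ratio = 4) {
  generate_reference_model(
    country_model(
      hip = default_true_incidence(),
      death = generate_mortality(c(4e-6, 1.2e-5), c(0.105, 0.095)),
      config = toy_risk_config(ratio)
    ),
    incidence_scale = scale
  )
}

# Exact band rates generated from a piecewise log-linear surface.
noiseless_incidence <- function(sex = "female", intercept = -8,
                                slope_pre = 0.05, slope_post = 0.12,
                                knot = 67) {
  bands <- age_bands()
  mid <- band_midpoint(bands)
  lr <- intercept + slope_pre * (pmin(mid, knot) - 40) +
    slope_post * pmax(mid - knot, 0)
  data.frame(sex = sex, age_band = bands, n_cases = 100,
             person_years = 100 / exp(lr), rate = exp(lr))
}

constant_hazard <- function(h) function(a) rep(h, length(a))

closed_form_probability <- function(hf, hd, horizon) {
  if (hf + hd == 0) return(0)
  hf / (hf + hd) * (1 - exp(-horizon * (hf + hd)))
}
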