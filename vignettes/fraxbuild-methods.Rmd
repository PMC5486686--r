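---
title: "Building and comparing country-specific fracture-probability models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and comparing country-specific fracture-probability models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fraxbuild)
```

# The problem

FRAX-style tools report an individual's 10-year probability of hip fracture
and of major osteoporotic fracture (MOF: hip, clinical spine, proximal
humerus, distal forearm) from age, sex, BMI, seven dichotomous clinical risk
factors and, optionally, femoral-neck BMD. Because hip-fracture incidence
varies more than tenfold between countries, such tools must be calibrated
per country from the national epidemiology of hip fracture and death. Where
no national register exists, incidence is assembled from regional
hospital/ambulance registries, which brings registry pathology with it:
double-counted admissions, pathological (neoplasia-associated) fractures,
unspecified-site codes, re-admissions for last year's fracture.

`fraxbuild` implements that construction end to end — ascertainment rules,
banded incidence, population-weighted pooling across catchments, piecewise
log-linear smoothing, a competing-mortality probability engine, and the
machinery for comparing two models over exhaustive clinical-scenario grids —
together with a synthetic registry generator so that every stage can be
validated against known ground truth.

# Case ascertainment

A record is a retained hip-fracture case when its ICD-10 code is S72.0
(femoral neck), S72.1 (trochanteric) or S72.2 (subtrochanteric), or S72.9
(unspecified femoral site) with documented hip surgery; neoplasia-associated
cases are excluded, as are patients under the minimum ascertainment age
(default 40, the lower operational limit of this model class). Ambulance
contacts where the patient refused hospitalization are retained, and no
residence criterion is applied: non-resident cases enter the numerator while
the denominator remains the catchment population — a deliberate fidelity to
common registry practice that is a known, documented source of upward bias.

Two rules collapse repeat admissions. The registry sources state their
intent (one fracture, one case) but not an operational window, so the
package uses: the same patient and site code within 365 days is one
fracture, and the earliest admission is kept. The reason logged for a
dropped later admission distinguishes the same-year duplicate
(`duplicate_same_fracture`) from an index admission following a fracture of
the same site in the previous calendar year (`prior_year_same_site`). A
second fracture of the same site more than a year later is a new case.
Every dropped record carries exactly one reason, so
`included + excluded = input` always holds, filtering is idempotent, and the
result is invariant to row order.

Rates are cases per person-year in half-open 5-year bands `[lo, lo+5)` from
age 40 with an open-ended 95+ band. Multi-region studies are pooled by the
catchment-population weighted mean of regional rates,
`sum(rate_r * pop_r) / sum(pop_r)`, which for equal observation windows is
algebraically the pooled-numerator/pooled-denominator rate (a property the
test suite checks numerically on random configurations). Observation-window
length is an explicit argument (`years`) rather than something inferred,
because multi-study amalgamations typically mix windows of different
lengths and denominator years; the caller decides.

# Piecewise log-linear smoothing

For continuous-age risk calculation, log band rates are regressed on band
midpoint age with a continuous change of slope at a fixed knot, default 67
years:

$$\log h(a) = \beta_0 + \beta_1 (a - 40) + \beta_2 \, (a - 67)_+ .$$

Design choices, all surfaced as arguments:

* **Continuity at the knot** is enforced with a hinge term — one intercept,
  two slopes. A discontinuous two-piece fit would produce a jump in hazard
  at 67 with no epidemiological meaning.
* **Abscissae** are band midpoints (42.5 for `40-44`); the open 95+ band
  uses 97.5 so a single rule covers the table.
* **Zero-rate bands** have no log rate and are dropped with a warning. With
  realistic catchments this only affects the youngest bands, where rates
  are small; the alternative (a continuity correction) would bias the
  intercept and was rejected.
* **Weighting** is unweighted least squares by default with an optional
  case-count weighting (`weights = "cases"`); the knot can be moved but is
  never estimated from the data. Both choices follow the fixed-breakpoint
  convention of this model class; data-driven knot selection is out of
  scope.
* Fewer than three positive-rate bands, or no positive band on one side of
  the knot, leaves the three parameters unidentifiable and is an error, not
  a silent fit.

A noiseless generate-then-fit round trip recovers parameters to 1e-8; under
Poisson sampling with thousands of cases per band the parameters are
recovered to within a few percent (the suite uses an expectation of 5,000
cases per band over 200 replicates, comfortably above the ~200/band floor
at which log-rates become stable).

# The probability engine

The probability of sustaining the index fracture between ages $a_0$ and
$a_0 + T$, given the competing risk of death, is

$$P = \int_0^T h_f(a_0+u) \,
      \exp\!\Big(-\!\int_0^u [h_f + h_d](a_0+v)\, dv\Big)\, du ,$$

with $T = 10$ for 10-year probabilities and $T = 110 - a_0$ for remaining
lifetime. The fracture hazard $h_f$ is the smoothed hip hazard (or the MOF
hazard imputed from it), scaled by the individual's multiplier

$$m = \prod_i RR_i \times g^{(t_{\mathrm{ref}} - t)} \times
      r_{\mathrm{BMI}}^{(\mathrm{BMI} - 25)},$$

where $RR_i$ are the relative risks of the factors present, $g$ the gradient
of risk (RR per SD decrease of femoral-neck T-score, applied only when a
T-score is entered), and the BMI term defaults to neutral ($r = 1$) because
model comparisons conventionally fix BMI at 25 kg/m². When a T-score is
entered, secondary osteoporosis contributes no multiplier by default (its
effect is taken as mediated by BMD); the flag
`secondary_osteoporosis_inactive_with_bmd = FALSE` covers the opposite
reading. The engine applies no population recalibration of the baseline for
risk-factor prevalence — deployed national tools calibrate so that the
baseline represents an average-risk person; this simplification is
deliberate and documented, and the configuration object is the hook for
adding it.

MOF hazard is the hip hazard times a sex- and age-specific hip:MOF ratio
looked up at the nearest tabulated age. The packaged ratio table
(`synthetic_example_hip_mof_ratios.csv`) is a synthetic example with the
qualitative shape of published ratio tables (large at 50, approaching ~2 in
extreme old age); realistic work must substitute literature ratios, which is
why the table is part of the configuration rather than a constant. The
packaged relative risks are likewise magnitude-realistic synthetic examples:
the coefficients of deployed FRAX tools are proprietary, so exact
replication of any national tool's output is explicitly not claimed.

**Numerics.** Hazards are treated as piecewise-constant on a fine age grid
(default step 0.01 years), evaluated at step midpoints. Within a step the
joint survival and fracture contribution then have the exact closed form
$\frac{h_f}{h_f+h_d} S \,(1 - e^{-(h_f+h_d)\Delta})$, so constant hazards
integrate to machine precision — the suite checks agreement with
$\frac{h_f}{h_f+h_d}(1-e^{-T(h_f+h_d)})$ to 1e-8 across a grid of hazard
pairs — and smooth Gompertz-like hazards carry $O(\Delta^2)$ error: halving
the default step changes results by less than 1e-8. The death hazard is
interpolated log-linearly between tabulated single years of age. Ten-year
outputs are supported for start ages 40–90, the operational range of this
tool class.

# Comparing two models

The comparison machinery reproduces the standard design for auditing one
national model against another: at each age (50, 60, 70, 80) and sex, an
exhaustive grid of all combinations of six binary risk factors and eight
T-score levels (0 to −3.5 SD in 0.5 steps) at BMI 25 — 512 scenarios, an
array of combinations, not a population simulation. Six factors rather than
seven because BMD is entered in the grid and secondary osteoporosis is
inert in that case (the ambiguity is configurable). Scenario order is
deterministic: factor combinations as a binary counter, T-score outermost.

The relation of model-B to model-A probabilities is summarised three ways:

* a continuous piecewise-linear regression of $p_B$ on $p_A$ with fixed
  knots — by convention at 50% and 70% for MOF and at 5% and 20% for hip,
  the outcomes' probability distributions being very different;
* a percentile table: at the 10th, 50th and 90th percentile of the model-A
  distribution (linear interpolation between order statistics — the
  definition is stated because none is standard), the model-A value, the
  model-B central estimate (the regression's fitted value), and a 95%
  tolerance interval;
* the Pearson correlation and the signed median relative difference
  $\mathrm{med}\,100(p_A - p_B)/p_A$.

**Tolerance intervals** are the empirical 2.5th–97.5th percentile range of
model-B probabilities among the scenarios whose model-A percentile rank
falls within ±2 percentile points of the target percentile. This
order-statistic construction is nonparametric and reproducible and gives
narrow intervals when the two models are near-monotone transforms of each
other; whether published comparison tables used this or a
regression-prediction interval is generally not stated, so both are
implemented (`ti_method = "empirical"` / `"prediction"`) with the empirical
construction as the documented default. The empirical interval covers ≥ 95%
of its neighbourhood scenarios by construction; the regression's central
estimate can fall marginally outside it where the relation curves within a
segment, whereas the prediction-interval variant contains it by
construction. With fewer than ~100 scenarios the ±2-point neighbourhood
empties and the empirical method errors; small grids should use the
prediction method.

When model B is model A with its hip hazard scaled by a constant
$\lambda < 1$, both probabilities are strictly increasing functions of the
scenario multiplier, so $p_B$ is a monotone transform of $p_A$: scenario
rank order is preserved exactly (Spearman correlation 1), every scenario is
lower under model B, and the Pearson correlation stays above 0.95 even with
5% multiplicative profile-level noise on model B's hazard scale. This is
the structural signature of a borrowed model that misstates absolute risk
while stratifying it correctly, and it is what the acceptance suite
verifies on synthetic model pairs at scale 0.4.

# The synthetic registry generator

`generate_registry()` emulates a multi-source retrospective registry over
one calendar year in several catchments. True cases are Poisson per
(region, sex, band) with mean `rate(band midpoint) × population`, uniform
integer ages within the band and uniform admission dates; site codes are
drawn 45/45/10 over S72.0/.1/.2 — the approximate cervical/trochanteric
dominance of real series. On top of the true cases it plants, in mutually
exclusive roles: exact re-admissions 1–60 days later (duplicates, capped at
year end so the pair stays in the index year), neoplasia-associated
records, S72.9 codings (a sub-proportion with hip surgery, recoded from
true cases so they remain ascertainable; the rest extra non-cases),
same-site admissions in the previous calendar year within the 365-day
window (so the index admission must be excluded), and ambulance contacts
with hospitalization refused (retained). The `sim_truth` record reconciles
exactly with the emitted rows, and the filter must recover each planted
category count — this is the generator's contract and is tested directly.

Defaults: three catchments; a declining age pyramid from 12,000 per sex per
band at 40–44, women outnumbering men at older ages; female incidence
rising from 1e-4/year at 40 with slopes 0.040/0.130 per year around the
knot, male from 1.5e-4 with 0.025/0.090 — so male rates exceed female below
the mid-60s and the female curve rises more steeply after, the pattern
characteristic of Eastern European data; plant fractions 5% duplicates, 2%
neoplasia, 3% S72.9 (half with surgery), 1% prior-year, 10% refusals —
chosen once as registry-realistic magnitudes. Mortality is Gompertz,
$h_d(a) = \alpha e^{\beta a}$, with sex-specific defaults giving
life-table-like hazards (~1% per year at 70 for women).

The generator does **not** emulate seasonality, urban/rural gradients,
secular trends, age heaping, misspelled identifiers or miscoded sites.
Passing tests therefore demonstrate the correctness of the pipeline's
logic under clean stochastic structure, not robustness to the full
messiness of real registries — probabilistic record linkage in particular
is out of scope.

# Problem sizes and determinism

The test suite and the acceptance script run everything at desk scale: the
default three-region simulation yields roughly a thousand registry rows;
the parameter-recovery study uses 200 replicates at an expectation of 5,000
cases per band; grid comparisons use the full 512-scenario grids at ages
50–80 with a 0.02–0.05-year quadrature step (the engine's results change
by well under 1e-6 between these and the 0.01 default). All randomness
flows from a single integer seed: a fixed seed reproduces registries,
reports and the pipeline manifest (which records MD5 hashes of every
artifact) bit for bit.

# Known limitations

* Baseline hazards are not recalibrated for risk-factor prevalence, so a
  "no-factor, reference-BMD" profile carries the population-average hazard,
  not the below-average hazard a calibrated national tool would assign.
* The packaged relative risks and hip:MOF ratios are synthetic examples;
  outputs are structurally, not numerically, comparable with deployed
  tools.
* Incidence smoothing assumes the two-segment log-linear shape; populations
  with non-monotone mid-life incidence would need a different smoother.
* The non-resident numerator bias and the observation-window/denominator
  mismatch in amalgamated multi-study data are faithfully reproduced, not
  corrected.
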