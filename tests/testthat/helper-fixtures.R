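# small in-code fixtures shared across tests

# three-age, two-outcome bundle small enough for fast Monte Carlo loops
tiny_bundle <- function(intake_mean = 9, intake_sd = 4,
                        rr_by_age = c(1.03, 1.025, 1.02)) {
  ages <- c("15-19", "45-49", "65-69")
  sexes <- c("male", "female")
  sgrid <- expand.grid(age_group = ages, sex = sexes, stringsAsFactors = FALSE)
  strata <- tibble::tibble(sex = sgrid$sex, age_group = sgrid$age_group,
                           population = c(1000, 900, 700, 1000, 950, 800))
  rgrid <- expand.grid(age_group = ages, sex = sexes,
                       outcome = c("CHD", "stroke"), stringsAsFactors = FALSE)
  rr_table <- tibble::tibble(outcome = rgrid$outcome, sex = rgrid$sex,
                             age_group = rgrid$age_group,
                             rr_per_mmHg = rep(rr_by_age, 4))
  cgrid <- expand.grid(sex = sexes, disease = c("CHD", "stroke"),
                       service = c("hospitalization", "consultation"),
                       stringsAsFactors = FALSE)
  cost_table <- tibble::tibble(
    disease = cgrid$disease, service = cgrid$service, sex = cgrid$sex,
    annual_cost_usd = c(8, 6, 5, 4, 3, 2.5, 1.5, 1.2) * 1e6,
    available = TRUE)
  mgrid <- expand.grid(age_group = ages, sex = sexes,
                       outcome = c("CHD", "stroke"), stringsAsFactors = FALSE)
  age_mid <- c(`15-19` = 17.5, `45-49` = 47.5, `65-69` = 67.5)
  mortality <- tibble::tibble(
    outcome = mgrid$outcome, sex = mgrid$sex, age_group = mgrid$age_group,
    age_at_death = unname(age_mid[mgrid$age_group]),
    n_deaths = rep(c(1, 5, 10), 4),
    residual_life_expectancy = unname(
      ifelse(mgrid$sex == "male", 77.5, 82.6) - age_mid[mgrid$age_group]))
  structure(list(
    strata = strata,
    baseline = intake_distribution(intake_mean, intake_sd),
    counterfactual = intake_distribution(5, 2.65),
    rr_table = rr_table, cost_table = cost_table, mortality = mortality,
    labor = labor_params(), currency = currency_rate(),
    dose_response = dose_response_spec(), bins = bin_scheme()
  ), class = "salt_bundle")
}

# independent oracle: truncated-normal bin masses computed directly from the
# normal CDF, without going through discretize()
oracle_masses <- function(mean, sd, lower, upper) {
  denom <- 1 - pnorm(0, mean, sd)
  (pnorm(upper, mean, sd) - pnorm(lower, mean, sd)) / denom
}

# independent oracle: multi-category attributable fraction
oracle_paf_multicat <- function(p_exposed, rr_exposed) {
  s <- sum(p_exposed * (rr_exposed - 1))
  100 * s / (s + 1)
}
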