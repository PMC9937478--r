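# productivity module: years of life lost, working-years truncation, and
# human-capital monetization of premature cardiovascular mortality

#' Labor-market parameters for the human-capital approach
#'
#' @param participation_rate labor-force participation as a fraction
#'   (default 0.62).
#' @param monthly_wage average wage of the economically active population,
#'   currency/month (default USD 765). Treated as monthly and annualized by
#'   `annualization_factor`; national statistical institutes report this
#'   figure monthly.
#' @param pension_age_female,pension_age_male retirement ages in years
#'   (defaults 60 and 65).
#' @param working_age_start first working age in years (default 15).
#' @param annualization_factor months per year applied to the wage
#'   (default 12).
#' @param discount_rate annual discount rate applied to future working years;
#'   default 0 (no discounting, no age-weighting).
#' @return a `labor_params` object.
#' @export
labor_params <- function(participation_rate = 0.62, monthly_wage = 765,
                         pension_age_female = 60, pension_age_male = 65,
                         working_age_start = 15, annualization_factor = 12,
                         discount_rate = 0) {
  check_number(participation_rate, "labor.participation_rate", 0, 1)
  check_number(monthly_wage, "labor.monthly_wage", lower = 0)
  check_number(working_age_start, "labor.working_age_start", lower = 0)
  check_number(pension_age_female, "labor.pension_age_female",
               lower = working_age_start, strict_lower = TRUE)
  check_number(pension_age_male, "labor.pension_age_male",
               lower = working_age_start, strict_lower = TRUE)
  check_number(annualization_factor, "labor.annualization_factor",
               lower = 0, strict_lower = TRUE)
  check_number(discount_rate, "labor.discount_rate", 0, 1)
  structure(list(participation_rate = participation_rate,
                 monthly_wage = monthly_wage,
                 pension_age_female = pension_age_female,
                 pension_age_male = pension_age_male,
                 working_age_start = working_age_start,
                 annualization_factor = annualization_factor,
                 discount_rate = discount_rate),
            class = "labor_params")
}

pension_age <- function(sex, labor) {
  ifelse(sex == "female", labor$pension_age_female, labor$pension_age_male)
}

#' Years of life lost
#'
#' `YLL = N x L`: deaths times the standard residual life expectancy at the
#' age of death.
#'
#' @param n_deaths number of deaths (vectorized, >= 0).
#' @param residual_life_expectancy years of life remaining at the age of
#'   death (vectorized, >= 0).
#' @return years of life lost.
#' @export
yll <- function(n_deaths, residual_life_expectancy) {
  if (any(n_deaths < 0)) abort_invalid("must be >= 0", "n_deaths")
  if (any(residual_life_expectancy < 0)) {
    abort_invalid("must be >= 0", "residual_life_expectancy")
  }
  n_deaths * residual_life_expectancy
}

#' Potential working years lost by one death
#'
#' Years between the age at death (floored at the first working age) and the
#' sex-specific pension age; zero for deaths at or past pension age.
#'
#' @param age_at_death age in years (vectorized).
#' @param sex `"male"` or `"female"` (vectorized).
#' @param labor a [labor_params()].
#' @return years, >= 0.
#' @export
#' @examples
#' working_years_lost(50, "male")    # 15
#' working_years_lost(58, "female")  # 2
working_years_lost <- function(age_at_death, sex, labor = labor_params()) {
  if (any(age_at_death < 0)) abort_invalid("must be >= 0", "age_at_death")
  pmax(0, pension_age(sex, labor) -
         pmax(age_at_death, labor$working_age_start))
}

#' Monetize productive years lost (human-capital approach)
#'
#' `ypll x monthly_wage x annualization_factor x participation_rate`,
#' optionally discounting a stream of `ypll` years at `labor$discount_rate`
#' (off by default).
#'
#' @param ypll years of potential productive life lost (vectorized, >= 0).
#' @param labor a [labor_params()].
#' @return productivity loss in currency units.
#' @export
productivity_loss <- function(ypll, labor = labor_params()) {
  if (any(ypll < 0)) abort_invalid("must be >= 0", "ypll")
  annual <- labor$monthly_wage * labor$annualization_factor *
    labor$participation_rate
  if (labor$discount_rate > 0) {
    r <- labor$discount_rate
    # present value of a ypll-year annuity of one annual wage
    annual * (1 - (1 + r)^(-ypll)) / r
  } else {
    ypll * annual
  }
}

#' Per-stratum productivity losses from a mortality table
#'
#' Mortality records are attributable deaths by outcome x sex x age group
#' (deaths enter the model as an input table from an upstream mortality
#' model). For each record: YLL = deaths x residual life expectancy, YPLL =
#' deaths x working years lost at the age of death, loss = monetized YPLL.
#'
#' @param mortality tibble with columns `outcome`, `sex`, `age_group`,
#'   `age_at_death`, `n_deaths`, `residual_life_expectancy`.
#' @param labor a [labor_params()].
#' @return tibble with `yll`, `ypll`, `loss_usd` per record.
#' @export
productivity_table <- function(mortality, labor = labor_params()) {
  check_columns(mortality, c("outcome", "sex", "age_group", "age_at_death",
                             "n_deaths", "residual_life_expectancy"),
                "mortality")
  wyl <- working_years_lost(mortality$age_at_death, mortality$sex, labor)
  tibble(
    outcome = mortality$outcome, sex = mortality$sex,
    age_group = mortality$age_group,
    yll = yll(mortality$n_deaths, mortality$residual_life_expectancy),
    ypll = mortality$n_deaths * wyl,
    loss_usd = productivity_loss(mortality$n_deaths * wyl, labor)
  )
}

#' Aggregate productivity losses by outcome and sex
#'
#' Same aggregation contract as [cost_report()]: full-precision totals,
#' integer-percent shares, rounding only at rendering. Also carries total YLL
#' and YPLL.
#'
#' @param results tibble from [productivity_table()], or any tibble with
#'   `outcome`, `sex` and `loss_usd` columns (`yll`/`ypll` optional).
#' @return a `cost_report` with `yll_total` and `ypll_total` elements.
#' @export
productivity_report <- function(results) {
  if (nrow(results) == 0) {
    rep <- cost_report(tibble(disease = character(), sex = character(),
                              value = numeric()))
  } else {
    check_columns(results, c("outcome", "sex", "loss_usd"), "productivity_report")
    cells <- results |>
      group_by(.data$outcome, .data$sex) |>
      summarise(value = sum(.data$loss_usd), .groups = "drop") |>
      rename(disease = "outcome")
    rep <- cost_report(cells)
  }
  rep$yll_total <- if ("yll" %in% names(results)) sum(results$yll) else NA_real_
  rep$ypll_total <- if ("ypll" %in% names(results)) sum(results$ypll) else NA_real_
  rep
}
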