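# uncertainty module: log-normal input sampling and Monte Carlo propagation
# of input uncertainty through the full pipeline

#' Method-of-moments log-normal parameters
#'
#' Returns `(mu, sigma)` of the log-normal distribution with the given
#' arithmetic mean and standard deviation:
#' `sigma^2 = ln(1 + sd^2/mean^2)`, `mu = ln(mean) - sigma^2/2`.
#' `sd = 0` gives the degenerate distribution (`sigma = 0`).
#'
#' @param mean arithmetic mean, > 0.
#' @param sd arithmetic standard deviation, >= 0.
#' @return list with elements `mu` and `sigma`.
#' @export
#' @examples
#' lognormal_params(10, 5.4)
lognormal_params <- function(mean, sd) {
  check_number(mean, "lognormal.mean", lower = 0, strict_lower = TRUE)
  check_number(sd, "lognormal.sd", lower = 0)
  sigma2 <- log1p((sd / mean)^2)
  list(mu = log(mean) - sigma2 / 2, sigma = sqrt(sigma2))
}

# n log-normal draws with given arithmetic mean/sd; exact mean when sd = 0
rlnorm_mean_sd <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  p <- lognormal_params(mean, sd)
  rlnorm(n, meanlog = p$mu, sdlog = p$sigma)
}

#' Percentile uncertainty interval
#'
#' Order-statistic percentiles with linear interpolation (the type-7 sample
#' quantile: the p-th percentile sits at rank `1 + p (n - 1)`, interpolating
#' between adjacent order statistics). A 95% level returns the 2.5th and
#' 97.5th percentiles.
#'
#' @param samples non-empty numeric vector.
#' @param level interval level in (0, 1); default 0.95.
#' @return named numeric vector `c(low, high)`.
#' @export
#' @examples
#' percentile_interval(1:1000)  # c(25.975, 975.025)
percentile_interval <- function(samples, level = 0.95) {
  if (length(samples) == 0) abort_invalid("must be non-empty", "samples")
  check_number(level, "ui_level", 0, 1, strict_lower = TRUE,
               strict_upper = TRUE)
  a <- (1 - level) / 2
  q <- quantile(samples, probs = c(a, 1 - a), type = 7, names = FALSE)
  c(low = q[1], high = q[2])
}

#' Monte Carlo configuration
#'
#' Controls the probabilistic sensitivity analysis. Each draw resamples the
#' baseline mean salt intake, every available cost cell, every per-mmHg
#' relative risk, and (optionally) every death count from log-normal
#' distributions around their point values, reruns the full pipeline, and
#' records all outputs; 95% uncertainty intervals come from the 2.5th and
#' 97.5th percentiles of the draws and the point estimate is the median of
#' draws (percentile bootstrap).
#'
#' The input spreads are coefficients of variation; sources rarely publish
#' standard errors for these inputs, so the defaults are explicit package
#' choices. Setting every cv to 0 makes the simulation degenerate and
#' reproduces the deterministic pipeline exactly.
#'
#' @param draws number of Monte Carlo draws (default 10000).
#' @param seed integer seed; one global seed feeds a deterministic substream
#'   per input cell, so adding an output never perturbs existing streams.
#' @param ui_level uncertainty-interval level (default 0.95).
#' @param intake_mean_cv cv of the sampling distribution of the mean baseline
#'   intake (default 0.05). The per-person intake SD stays fixed in the
#'   discretization; only the mean is resampled.
#' @param cost_cv cv of each cost cell (default 0.05).
#' @param rr_log_se_frac standard error of `ln(RR)` as a fraction of
#'   `ln(RR)` (default 0.10).
#' @param deaths_cv cv of each mortality-record death count (default 0.05);
#'   set to 0 to treat deaths as fixed inputs.
#' @return an `mc_config` object.
#' @export
mc_config <- function(draws = 10000, seed = 1, ui_level = 0.95,
                      intake_mean_cv = 0.05, cost_cv = 0.05,
                      rr_log_se_frac = 0.10, deaths_cv = 0.05) {
  check_number(draws, "mc.draws", lower = 1)
  check_number(seed, "mc.seed")
  check_number(ui_level, "mc.ui_level", 0, 1, strict_lower = TRUE,
               strict_upper = TRUE)
  check_number(intake_mean_cv, "mc.intake_mean_cv", lower = 0)
  check_number(cost_cv, "mc.cost_cv", lower = 0)
  check_number(rr_log_se_frac, "mc.rr_log_se_frac", lower = 0)
  check_number(deaths_cv, "mc.deaths_cv", lower = 0)
  structure(list(draws = as.integer(draws), seed = as.integer(seed),
                 ui_level = ui_level, intake_mean_cv = intake_mean_cv,
                 cost_cv = cost_cv, rr_log_se_frac = rr_log_se_frac,
                 deaths_cv = deaths_cv),
            class = "mc_config")
}

# canonical output-column naming shared by the deterministic pipeline and the
# Monte Carlo engine
output_names <- function(bundle) {
  services <- sort(unique(bundle$cost_table$service[bundle$cost_table$available]))
  diseases <- sort(unique(bundle$cost_table$disease[bundle$cost_table$available]))
  outcomes <- sort(unique(bundle$mortality$outcome))
  list(services = services, diseases = diseases, outcomes = outcomes,
       cols = c("direct_total_usd",
                paste0("direct_", services, "_usd"),
                paste0("direct_", diseases, "_usd"),
                "direct_male_usd", "direct_female_usd",
                "productivity_total_usd",
                paste0("productivity_", outcomes, "_usd"),
                "productivity_male_usd", "productivity_female_usd",
                "yll_total_years", "ypll_total_years"))
}

# Vectorized pipeline evaluation: one row per draw, one column per output.
# intake_means: D; lnrr: D x R; cost_draws: D x C (available cells only);
# death_draws: D x M.
mc_outputs <- function(bundle, intake_means, lnrr, cost_draws, death_draws,
                       mode = "distribution") {
  D <- length(intake_means)
  bins <- bundle$bins
  sd_b <- bundle$baseline$sd
  e <- bins$exposed
  shift_e <- sbp_shift(bins$midpoint[e] - bins$reference,
                       bundle$dose_response)

  # baseline exposed-bin masses, D x |e|, truncated-normal renormalized
  if (sd_b == 0) {
    W <- vapply(which(e), function(b) {
      as.numeric(intake_means > bins$lower[b] & intake_means <= bins$upper[b])
    }, numeric(D))
    W <- matrix(W, nrow = D)
  } else {
    denom <- 1 - pnorm(0, intake_means, sd_b)
    W <- vapply(which(e), function(b) {
      (pnorm(bins$upper[b], intake_means, sd_b) -
         pnorm(bins$lower[b], intake_means, sd_b)) / denom
    }, numeric(D))
    W <- matrix(W, nrow = D)
  }
  P_base <- rowSums(W)

  prev_cf <- discretize(bundle$counterfactual, bins)
  w_cf <- prev_cf$mass[e]
  P_cf <- sum(w_cf)

  rrt <- bundle$rr_table
  R <- nrow(rrt)
  par_net <- matrix(0, nrow = D, ncol = R)
  for (r in seq_len(R)) {
    rrmat <- exp(outer(lnrr[, r], shift_e))          # D x |e|
    RRb <- ifelse(P_base > 0, rowSums(W * rrmat) / P_base, 1)
    xb <- P_base * (RRb - 1)
    par_b <- 100 * xb / (xb + 1)
    if (mode == "threshold" || P_cf == 0) {
      par_net[, r] <- par_b
    } else {
      RRc <- as.vector(rrmat %*% w_cf) / P_cf
      xc <- P_cf * (RRc - 1)
      par_net[, r] <- par_b - 100 * xc / (xc + 1)
    }
  }

  # pool stratum PARs to outcome x sex with population weights
  strata <- bundle$strata
  pop <- strata$population[match(paste(rrt$sex, rrt$age_group),
                                 paste(strata$sex, strata$age_group))]
  grp <- paste(rrt$outcome, rrt$sex, sep = "|")
  groups <- unique(grp)
  Wmat <- vapply(groups, function(g) {
    w <- ifelse(grp == g, pop, 0)
    w / sum(w)
  }, numeric(R))
  pooled <- par_net %*% Wmat                          # D x G, named groups

  nm <- output_names(bundle)
  out <- matrix(0, nrow = D, ncol = length(nm$cols),
                dimnames = list(NULL, nm$cols))

  cells <- bundle$cost_table[bundle$cost_table$available, ]
  gidx <- match(paste(cells$disease, cells$sex, sep = "|"), groups)
  if (anyNA(gidx)) {
    abort_invalid("cost table contains disease x sex cells with no pooled PAR",
                  "run_monte_carlo")
  }
  att <- cost_draws * pooled[, gidx, drop = FALSE] / 100   # D x C
  out[, "direct_total_usd"] <- rowSums(att)
  for (s in nm$services) {
    out[, paste0("direct_", s, "_usd")] <-
      rowSums(att[, cells$service == s, drop = FALSE])
  }
  for (d in nm$diseases) {
    out[, paste0("direct_", d, "_usd")] <-
      rowSums(att[, cells$disease == d, drop = FALSE])
  }
  for (s in c("male", "female")) {
    out[, paste0("direct_", s, "_usd")] <-
      rowSums(att[, cells$sex == s, drop = FALSE])
  }

  mort <- bundle$mortality
  wyl <- working_years_lost(mort$age_at_death, mort$sex, bundle$labor)
  annual <- bundle$labor$monthly_wage * bundle$labor$annualization_factor *
    bundle$labor$participation_rate
  loss <- death_draws * matrix(wyl * annual, nrow = D, ncol = nrow(mort),
                               byrow = TRUE)
  out[, "productivity_total_usd"] <- rowSums(loss)
  for (o in nm$outcomes) {
    out[, paste0("productivity_", o, "_usd")] <-
      rowSums(loss[, mort$outcome == o, drop = FALSE])
  }
  for (s in c("male", "female")) {
    out[, paste0("productivity_", s, "_usd")] <-
      rowSums(loss[, mort$sex == s, drop = FALSE])
  }
  out[, "yll_total_years"] <-
    as.vector(death_draws %*% mort$residual_life_expectancy)
  out[, "ypll_total_years"] <- as.vector(death_draws %*% wyl)
  out
}

mc_draws <- function(bundle, config) {
  D <- config$draws
  seed <- config$seed

  intake_means <- with_seed(substream_seed(seed, "intake_mean"), {
    rlnorm_mean_sd(D, bundle$baseline$mean,
                   config$intake_mean_cv * bundle$baseline$mean)
  })

  rrt <- bundle$rr_table
  lnrr <- matrix(0, nrow = D, ncol = nrow(rrt))
  for (r in seq_len(nrow(rrt))) {
    mu <- log(rrt$rr_per_mmHg[r])
    se <- config$rr_log_se_frac * abs(mu)
    tag <- paste("rr", rrt$outcome[r], rrt$sex[r], rrt$age_group[r], sep = "/")
    lnrr[, r] <- if (se == 0) rep(mu, D) else {
      with_seed(substream_seed(seed, tag), rnorm(D, mu, se))
    }
  }

  cells <- bundle$cost_table[bundle$cost_table$available, ]
  cost_draws <- matrix(0, nrow = D, ncol = nrow(cells))
  for (cc in seq_len(nrow(cells))) {
    tag <- paste("cost", cells$disease[cc], cells$service[cc], cells$sex[cc],
                 sep = "/")
    cost_draws[, cc] <- with_seed(substream_seed(seed, tag), {
      rlnorm_mean_sd(D, cells$annual_cost_usd[cc],
                     config$cost_cv * cells$annual_cost_usd[cc])
    })
  }

  mort <- bundle$mortality
  death_draws <- matrix(0, nrow = D, ncol = nrow(mort))
  for (m in seq_len(nrow(mort))) {
    n <- mort$n_deaths[m]
    tag <- paste("deaths", mort$outcome[m], mort$sex[m], mort$age_group[m],
                 sep = "/")
    death_draws[, m] <- if (n == 0) rep(0, D) else {
      with_seed(substream_seed(seed, tag),
                rlnorm_mean_sd(D, n, config$deaths_cv * n))
    }
  }

  list(intake_means = intake_means, lnrr = lnrr, cost_draws = cost_draws,
       death_draws = death_draws)
}

#' Monte Carlo uncertainty propagation through the full pipeline
#'
#' Resamples the uncertain inputs per [mc_config()], reruns
#' exposure -> risk -> costs -> productivity for every draw (vectorized
#' across draws), and summarizes each output as the median of draws with a
#' percentile uncertainty interval. Deterministic for a fixed seed.
#'
#' @param bundle a validated `salt_bundle`.
#' @param config an [mc_config()].
#' @param mode counterfactual handling, `"distribution"` (default) or
#'   `"threshold"`; see [stratum_paf()].
#' @param keep_draws if `TRUE`, attach the draws matrix as attribute
#'   `"draws"` (per-draw audit trace).
#' @return an `mc_summary` tibble with columns `quantity`, `point` (median),
#'   `ui_low`, `ui_high`, `n_draws`.
#' @export
run_monte_carlo <- function(bundle, config = mc_config(),
                            mode = c("distribution", "threshold"),
                            keep_draws = FALSE) {
  mode <- match.arg(mode)
  validate_bundle(bundle)
  stopifnot(inherits(config, "mc_config"))
  if (config$draws < 1) abort_invalid("must be >= 1", "mc.draws")
  d <- mc_draws(bundle, config)
  out <- mc_outputs(bundle, d$intake_means, d$lnrr, d$cost_draws,
                    d$death_draws, mode = mode)
  ui <- apply(out, 2, percentile_interval, level = config$ui_level)
  summary <- tibble(
    quantity = colnames(out),
    point = apply(out, 2, median),
    ui_low = ui["low", ],
    ui_high = ui["high", ],
    n_draws = config$draws
  )
  class(summary) <- c("mc_summary", class(summary))
  if (keep_draws) attr(summary, "draws") <- out
  summary
}
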