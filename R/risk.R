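# risk module: per-bin relative risks, combined RR over the exposure
# distribution, population attributable risk (PAR)

#' Rescale a per-mmHg relative risk to an exposure bin
#'
#' Relative risks for cardiovascular outcomes are parameterized per 1 mmHg of
#' systolic blood pressure. A bin's risk relative to the reference intake is
#' obtained by log-linear rescaling: the per-mmHg RR raised to the SBP shift
#' implied by the salt difference between the bin midpoint and the reference
#' (`RR^deltaSBP`, the standard comparative-risk-assessment convention). The
#' reference bin has RR exactly 1.
#'
#' @param rr_per_mmHg relative risk per 1 mmHg higher SBP (vectorized); must
#'   be > 0.
#' @param bin_midpoint bin midpoint intake, g/day.
#' @param reference reference intake, g/day.
#' @param spec a [dose_response_spec()].
#' @return dimensionless relative risk at the bin.
#' @export
#' @examples
#' rr_at_bin(1.02, bin_midpoint = 11, reference = 5)  # 1.02^5.8
rr_at_bin <- function(rr_per_mmHg, bin_midpoint, reference,
                      spec = dose_response_spec()) {
  if (any(!is.finite(rr_per_mmHg)) || any(rr_per_mmHg <= 0)) {
    abort_invalid("must be > 0", "rr_per_mmHg")
  }
  rr_per_mmHg^sbp_shift(bin_midpoint - reference, spec)
}

#' Combine per-bin relative risks over the exposure distribution
#'
#' Yields the (`P`, `RR`) pair the binary PAR formula consumes: `P` is the
#' total mass in exposed bins and `RR` the prevalence-weighted arithmetic mean
#' of per-bin RRs among exposed bins (weights renormalized over exposed
#' bins). This definition makes the binary formula algebraically identical to
#' the multi-category attributable fraction
#' `100 * sum(p_i (RR_i - 1)) / (sum(p_i (RR_i - 1)) + 1)`. When `P = 0` the
#' combined RR is 1 by convention.
#'
#' @param prev exposure-prevalence table ([discretize()]).
#' @param per_bin_rr numeric vector of per-bin RRs, aligned with `prev` rows;
#'   values in unexposed (reference) bins are ignored.
#' @return a list with elements `P` and `RR`.
#' @export
combined_rr <- function(prev, per_bin_rr) {
  check_columns(prev, c("mass", "exposed"), "combined_rr")
  if (length(per_bin_rr) != nrow(prev)) {
    abort_invalid(sprintf("per_bin_rr has length %d but prev has %d bins",
                          length(per_bin_rr), nrow(prev)), "combined_rr")
  }
  w <- prev$mass[prev$exposed]
  P <- sum(w)
  RR <- if (P == 0) 1 else sum(w * per_bin_rr[prev$exposed]) / P
  list(P = P, RR = RR)
}

#' Population attributable risk (percent)
#'
#' `PAR = 100 * P * (RR - 1) / (P * (RR - 1) + 1)`: the percentage of the
#' disease burden that would be removed if the exposed fraction `P` dropped to
#' the reference exposure. A protective exposure (`RR < 1`) yields a negative
#' PAR, passed through with a warning.
#'
#' @param P exposure prevalence in \[0, 1\] (vectorized).
#' @param RR combined relative risk, > 0 (vectorized).
#' @return PAR in percent.
#' @export
#' @examples
#' par_percent(0.5, 3)  # 50
par_percent <- function(P, RR) {
  if (any(P < 0 | P > 1)) abort_invalid("must be in [0, 1]", "P")
  if (any(RR <= 0)) abort_invalid("must be > 0", "RR")
  x <- P * (RR - 1)
  if (any(x == -1)) {
    abort_invalid("P * (RR - 1) = -1: attributable fraction is singular", "par")
  }
  if (any(RR < 1 & P > 0)) {
    warning("protective exposure (RR < 1): negative PAR passed through",
            call. = FALSE)
  }
  100 * x / (x + 1)
}

#' Stratum-level attributable risk for every outcome
#'
#' For each relative-risk record (outcome x sex x age group), rescales the
#' per-mmHg RR across the exposure bins, combines it with the baseline (and
#' optionally counterfactual) exposure prevalences, and evaluates the PAR.
#' The net PAR is `PAR(baseline) - PAR(counterfactual)` under the default
#' `"distribution"` mode — both scenarios are scored against the same
#' reference intake — or simply `PAR(baseline)` under `"threshold"` mode,
#' where the counterfactual is defined as burden-free.
#'
#' @param rr_table tibble with columns `outcome`, `sex`, `age_group`,
#'   `rr_per_mmHg`; one row per outcome x stratum.
#' @param prev_baseline baseline exposure-prevalence table.
#' @param prev_counterfactual counterfactual exposure-prevalence table, or
#'   `NULL` (equivalent to `"threshold"` mode).
#' @param spec a [dose_response_spec()].
#' @param mode `"distribution"` or `"threshold"` counterfactual handling.
#' @return tibble with the `rr_table` keys plus `P`, `RR`, `par_baseline`,
#'   `par_counterfactual`, `par_net` (all percents except `P`, `RR`).
#' @export
stratum_paf <- function(rr_table, prev_baseline, prev_counterfactual = NULL,
                        spec = dose_response_spec(),
                        mode = c("distribution", "threshold")) {
  mode <- match.arg(mode)
  check_columns(rr_table, c("outcome", "sex", "age_group", "rr_per_mmHg"),
                "rr_table")
  if (anyDuplicated(rr_table[, c("outcome", "sex", "age_group")])) {
    abort_invalid("duplicate outcome x stratum records", "rr_table")
  }
  reference <- attr(prev_baseline, "reference")
  shift <- sbp_shift(prev_baseline$midpoint - reference, spec)
  # R x B matrix of per-bin RRs, log-linear in the SBP shift
  rrmat <- exp(outer(log(rr_table$rr_per_mmHg), shift))

  paf_one <- function(prev) {
    w <- prev$mass[prev$exposed]
    P <- sum(w)
    RR <- if (P == 0) rep(1, nrow(rrmat))
          else as.vector(rrmat[, prev$exposed, drop = FALSE] %*% w) / P
    list(P = P, RR = RR, par = par_percent(rep(P, nrow(rrmat)), RR))
  }

  base <- paf_one(prev_baseline)
  out <- tibble(
    outcome = rr_table$outcome, sex = rr_table$sex,
    age_group = rr_table$age_group, rr_per_mmHg = rr_table$rr_per_mmHg,
    P = base$P, RR = base$RR, par_baseline = base$par
  )
  if (mode == "threshold" || is.null(prev_counterfactual)) {
    out$par_counterfactual <- 0
  } else {
    out$par_counterfactual <- paf_one(prev_counterfactual)$par
  }
  out$par_net <- out$par_baseline - out$par_counterfactual
  out
}

#' Pool stratum PARs to outcome x sex
#'
#' National cost tables are disease x service x sex, without an age dimension,
#' so age-specific PARs are pooled within sex using population weights.
#'
#' @param paf tibble from [stratum_paf()].
#' @param strata tibble with columns `sex`, `age_group`, `population`.
#' @return tibble with columns `outcome`, `sex`, `par_pct` (net pooled PAR)
#'   and `par_baseline_pct`.
#' @export
pooled_par <- function(paf, strata) {
  check_columns(strata, c("sex", "age_group", "population"), "strata")
  joined <- left_join(paf, strata, by = c("sex", "age_group"))
  if (anyNA(joined$population)) {
    abort_invalid("rr_table contains strata absent from the strata table",
                  "pooled_par")
  }
  joined |>
    group_by(.data$outcome, .data$sex) |>
    summarise(
      par_pct = sum(.data$par_net * .data$population) / sum(.data$population),
      par_baseline_pct = sum(.data$par_baseline * .data$population) /
        sum(.data$population),
      .groups = "drop"
    )
}
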