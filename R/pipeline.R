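# pipeline: deterministic end-to-end run tying exposure, risk, costs and
# productivity together, with optional Monte Carlo uncertainty

#' Run the full attributable-burden pipeline
#'
#' Discretizes the baseline and counterfactual intake distributions,
#' computes stratum-level attributable risks for every outcome, pools them to
#' outcome x sex, applies them to the national cost table, monetizes
#' premature mortality, and assembles report tables. With an [mc_config()]
#' the Monte Carlo engine additionally attaches uncertainty intervals.
#'
#' @param bundle a `salt_bundle` ([default_fixture()],
#'   [generate_random_bundle()], or [read_bundle()]).
#' @param mc an [mc_config()], or `NULL` for a purely deterministic run.
#' @param counterfactual_mode `"distribution"` (attributable burden =
#'   baseline burden minus counterfactual burden, both against the reference
#'   intake) or `"threshold"` (counterfactual burden defined as zero).
#' @return a `salt_result` list: `paf` (stratum attributable risks),
#'   `pooled_par`, `direct_cells`, `direct_report`, `productivity`,
#'   `productivity_report`, `outputs` (named vector of headline quantities),
#'   `mc` (an `mc_summary` or `NULL`), and the input `bundle`.
#' @export
#' @examples
#' res <- run_pipeline(default_fixture())
#' res$outputs["direct_total_usd"]
run_pipeline <- function(bundle, mc = NULL,
                         counterfactual_mode = c("distribution", "threshold")) {
  counterfactual_mode <- match.arg(counterfactual_mode)
  validate_bundle(bundle)

  prev_b <- discretize(bundle$baseline, bundle$bins)
  prev_c <- if (counterfactual_mode == "distribution") {
    discretize(bundle$counterfactual, bundle$bins)
  } else NULL

  paf <- stratum_paf(bundle$rr_table, prev_b, prev_c,
                     spec = bundle$dose_response, mode = counterfactual_mode)
  pooled <- pooled_par(paf, bundle$strata)
  cells <- attributable_costs(pooled, bundle$cost_table, bundle$currency)
  direct_report <- cost_report(
    mutate(cells, value = .data$attributable_usd))
  prod_tbl <- productivity_table(bundle$mortality, bundle$labor)
  prod_report <- productivity_report(prod_tbl)

  nm <- output_names(bundle)
  outputs <- setNames(numeric(length(nm$cols)), nm$cols)
  outputs["direct_total_usd"] <- direct_report$grand_total
  for (s in nm$services) {
    outputs[paste0("direct_", s, "_usd")] <-
      sum(cells$attributable_usd[cells$service == s])
  }
  for (d in nm$diseases) {
    outputs[paste0("direct_", d, "_usd")] <-
      sum(cells$attributable_usd[cells$disease == d])
  }
  for (s in c("male", "female")) {
    outputs[paste0("direct_", s, "_usd")] <-
      sum(cells$attributable_usd[cells$sex == s])
    outputs[paste0("productivity_", s, "_usd")] <-
      sum(prod_tbl$loss_usd[prod_tbl$sex == s])
  }
  outputs["productivity_total_usd"] <- sum(prod_tbl$loss_usd)
  for (o in nm$outcomes) {
    outputs[paste0("productivity_", o, "_usd")] <-
      sum(prod_tbl$loss_usd[prod_tbl$outcome == o])
  }
  outputs["yll_total_years"] <- sum(prod_tbl$yll)
  outputs["ypll_total_years"] <- sum(prod_tbl$ypll)

  mc_summary <- if (!is.null(mc)) {
    run_monte_carlo(bundle, mc, mode = counterfactual_mode)
  } else NULL

  structure(list(paf = paf, pooled_par = pooled, direct_cells = cells,
                 direct_report = direct_report, productivity = prod_tbl,
                 productivity_report = prod_report, outputs = outputs,
                 mc = mc_summary, mc_config = mc, bundle = bundle,
                 counterfactual_mode = counterfactual_mode),
            class = "salt_result")
}

#' @export
print.salt_result <- function(x, ...) {
  cat("Salt-attributable burden\n")
  cat(sprintf("  direct costs:        %s thousand USD\n",
              format(render_thousands(x$outputs["direct_total_usd"]),
                     big.mark = ",")))
  cat(sprintf("  productivity losses: %s thousand USD (%s YPLL)\n",
              format(render_thousands(x$outputs["productivity_total_usd"]),
                     big.mark = ","),
              format(round_half_away(x$outputs["ypll_total_years"]),
                     big.mark = ",")))
  if (!is.null(x$mc)) {
    tot <- x$mc[x$mc$quantity == "direct_total_usd", ]
    cat(sprintf("  MC direct total: %s (95%% UI %s-%s) thousand USD, %d draws\n",
                format(render_thousands(tot$point), big.mark = ","),
                format(render_thousands(tot$ui_low), big.mark = ","),
                format(render_thousands(tot$ui_high), big.mark = ","),
                tot$n_draws))
  }
  invisible(x)
}
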