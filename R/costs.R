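# costs module: currency conversion, attributable direct costs, and the
# aggregation/reporting layer behind the published-style cost tables

#' Currency exchange rate
#'
#' @param crc_per_usd Costa Rican colones per US dollar; default 600 (the
#'   December 2018 rate used for nominal 2018 costs).
#' @return a `currency_rate` object.
#' @export
currency_rate <- function(crc_per_usd = 600) {
  check_number(crc_per_usd, "currency.crc_per_usd", lower = 0, strict_lower = TRUE)
  structure(list(crc_per_usd = crc_per_usd), class = "currency_rate")
}

#' Convert colones to US dollars
#'
#' @param amount_crc amount in CRC (vectorized).
#' @param rate a [currency_rate()] or a bare positive number.
#' @return amount in USD.
#' @export
crc_to_usd <- function(amount_crc, rate = currency_rate()) {
  r <- if (inherits(rate, "currency_rate")) rate$crc_per_usd else rate
  check_number(r, "currency.crc_per_usd", lower = 0, strict_lower = TRUE)
  amount_crc / r
}

#' Attributable share of a cost
#'
#' `(par / 100) * total_cost`: the fraction of an annual national cost
#' attributable to the exposure.
#'
#' @param par attributable risk in percent (vectorized).
#' @param total_cost annual national cost, >= 0 (vectorized).
#' @return attributable cost in the same currency as `total_cost`.
#' @export
attributable_cost <- function(par, total_cost) {
  if (any(total_cost < 0, na.rm = TRUE)) {
    abort_invalid("must be >= 0", "total_cost")
  }
  (par / 100) * total_cost
}

#' Apply pooled PARs to a national cost table
#'
#' Joins outcome x sex PARs onto the disease x service x sex cost table and
#' computes each cell's attributable cost. Cells flagged unavailable (e.g.
#' medication costs for stroke and rheumatic heart disease) are excluded, not
#' zero-filled, and listed in the `"excluded"` attribute of the result.
#'
#' @param pooled tibble from [pooled_par()] (`outcome`, `sex`, `par_pct`).
#' @param cost_table tibble with columns `disease`, `service`, `sex`,
#'   `annual_cost_usd` (or `annual_cost_crc`), `available`.
#' @param rate a [currency_rate()], used only when costs are given in CRC.
#' @return tibble of cells with `par_pct` and `attributable_usd` columns.
#' @export
attributable_costs <- function(pooled, cost_table, rate = currency_rate()) {
  check_columns(cost_table, c("disease", "service", "sex", "available"),
                "cost_table")
  if (!"annual_cost_usd" %in% names(cost_table)) {
    check_columns(cost_table, "annual_cost_crc", "cost_table")
    cost_table$annual_cost_usd <- crc_to_usd(cost_table$annual_cost_crc, rate)
  }
  if (anyDuplicated(cost_table[, c("disease", "service", "sex")])) {
    abort_invalid("duplicate disease x service x sex cell", "cost_table")
  }
  excluded <- cost_table[!cost_table$available,
                         c("disease", "service", "sex")]
  cells <- cost_table |>
    filter(.data$available) |>
    left_join(pooled, by = c(disease = "outcome", sex = "sex"))
  if (anyNA(cells$par_pct)) {
    abort_invalid("cost table contains disease x sex cells with no pooled PAR",
                  "attributable_costs")
  }
  cells <- cells |>
    mutate(attributable_usd = attributable_cost(.data$par_pct,
                                                .data$annual_cost_usd)) |>
    select("disease", "service", "sex", "annual_cost_usd",
           "par_pct", "attributable_usd")
  attr(cells, "excluded") <- excluded
  cells
}

#' Aggregate attributable-cost cells into report tables
#'
#' Computes, at full floating precision, the grand total and the marginal
#' totals over every key column present (`disease`, `service`, `sex`),
#' together with integer-percent shares (round half away from zero). Rounding
#' happens only here, at the rendering margin — never inside the model — so
#' the one-unit discrepancies that per-cell rounding would introduce cannot
#' propagate.
#'
#' @param cells tibble with a `value` column (or the column named by
#'   `value_col`) and any of `disease`, `service`, `sex` as keys. Unavailable
#'   cells must be absent rather than zero.
#' @param value_col name of the value column (default `"value"`).
#' @return a `cost_report` list: `grand_total`, and for each key present a
#'   tibble `by_<key>` with `total` and `share_pct` columns; the input cells
#'   are kept as `cells`.
#' @export
#' @examples
#' cells <- tibble::tibble(
#'   service = c("hospitalization", "consultation", "medication"),
#'   value = c(8019, 4905, 2198))
#' rep <- cost_report(cells)
#' rep$grand_total          # 15122
#' rep$by_service$share_pct # 53 32 15
cost_report <- function(cells, value_col = "value") {
  check_columns(cells, value_col, "cost_report")
  keys <- intersect(c("disease", "service", "sex"), names(cells))
  if (length(keys) > 0 && anyDuplicated(cells[, keys])) {
    abort_invalid("duplicate cell for the same key", "cost_report")
  }
  value <- cells[[value_col]]
  if (any(is.na(value))) {
    abort_invalid("missing values: drop unavailable cells instead", "cost_report")
  }
  out <- list(cells = cells, grand_total = sum(value))
  for (k in keys) {
    tab <- cells |>
      group_by(.data[[k]]) |>
      summarise(total = sum(.data[[value_col]]), .groups = "drop")
    tab$share_pct <- integer_share(tab$total, out$grand_total)
    out[[paste0("by_", k)]] <- tab
  }
  if (all(c("disease", "service") %in% keys)) {
    wide <- cells |>
      group_by(.data$disease, .data$service) |>
      summarise(total = sum(.data[[value_col]]), .groups = "drop")
    out$by_disease_service <- wide
  }
  structure(out, class = "cost_report")
}

#' @export
print.cost_report <- function(x, ...) {
  cat("Attributable-cost report\n")
  cat(sprintf("  grand total: %s thousand USD\n",
              format(render_thousands(x$grand_total), big.mark = ",")))
  for (k in c("by_service", "by_disease", "by_sex")) {
    if (!is.null(x[[k]])) {
      cat(sprintf("  %s:\n", sub("by_", "shares by ", k)))
      tab <- x[[k]]
      for (i in seq_len(nrow(tab))) {
        cat(sprintf("    %-18s %10s (%d%%)\n", tab[[1]][i],
                    format(render_thousands(tab$total[i]), big.mark = ","),
                    tab$share_pct[i]))
      }
    }
  }
  invisible(x)
}
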