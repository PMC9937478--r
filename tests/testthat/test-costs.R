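test_that("attributable cost is the PAR share of the total cost", {
  expect_equal(attributable_cost(0, 1000), 0)
  expect_equal(attributable_cost(10, 1000), 100)
  expect_equal(attributable_cost(100, 1000), 1000)
  set.seed(3)
  par <- runif(50, 0, 100); cost <- runif(50, 0, 1e8)
  expect_true(all(attributable_cost(par, cost) <= cost))
  expect_error(attributable_cost(10, -5), "total_cost")
})

test_that("colones convert to dollars at the fixed rate", {
  expect_equal(crc_to_usd(600, currency_rate(600)), 1)
  expect_equal(crc_to_usd(0), 0)
  expect_equal(crc_to_usd(9073200000, 600), 15122000)
})

test_that("display rounding is half-away-from-zero", {
  expect_equal(round_half_away(c(2.5, -2.5, 14.53, 0.5)), c(3, -3, 15, 1))
  expect_equal(round_half_away(1.25, 1), 1.3)
})

test_that("report aggregation reproduces totals and integer shares", {
  cells <- tibble::tibble(
    service = c("hospitalization", "consultation", "medication"),
    value = c(8019, 4905, 2198))
  rep <- cost_report(cells)
  expect_equal(rep$grand_total, 15122)
  shares <- setNames(rep$by_service$share_pct, rep$by_service$service)
  expect_equal(shares[["hospitalization"]], 53)
  expect_equal(shares[["consultation"]], 32)
  expect_equal(shares[["medication"]], 15)
  # single cell: total equals the cell, share 100%
  one <- cost_report(tibble::tibble(service = "hospitalization", value = 42))
  expect_equal(one$grand_total, 42)
  expect_equal(one$by_service$share_pct, 100)
})

test_that("aggregation is permutation-invariant and conserves sex totals", {
  set.seed(9)
  cells <- tibble::tibble(
    disease = rep(c("CHD", "stroke"), each = 4),
    service = rep(rep(c("hospitalization", "consultation"), each = 2), 2),
    sex = rep(c("male", "female"), 4),
    value = runif(8, 1e5, 1e7))
  rep1 <- cost_report(cells)
  rep2 <- cost_report(cells[sample(nrow(cells)), ])
  expect_equal(rep1$grand_total, rep2$grand_total)
  expect_equal(dplyr::arrange(rep1$by_disease, disease),
               dplyr::arrange(rep2$by_disease, disease))
  # sex-stratified totals sum to the grand total at full precision
  expect_equal(sum(rep1$by_sex$total), rep1$grand_total, tolerance = 1e-12)
})

test_that("duplicate cells and missing values are rejected", {
  cells <- tibble::tibble(disease = c("CHD", "CHD"),
                          service = "hospitalization",
                          sex = "male", value = c(1, 2))
  expect_error(cost_report(cells), "duplicate")
  expect_error(cost_report(tibble::tibble(disease = "CHD", value = NA_real_)),
               "missing")
})

test_that("pooled PARs apply to cost cells with unavailable cells excluded", {
  b <- tiny_bundle()
  b$cost_table$available[1] <- FALSE
  b$cost_table$annual_cost_usd[1] <- NA
  pooled <- tibble::tibble(
    outcome = rep(c("CHD", "stroke"), each = 2),
    sex = rep(c("male", "female"), 2),
    par_pct = c(10, 12, 8, 9), par_baseline_pct = c(12, 14, 10, 11))
  cells <- attributable_costs(pooled, b$cost_table)
  expect_equal(nrow(cells), 7)
  expect_equal(nrow(attr(cells, "excluded")), 1)
  expect_equal(cells$attributable_usd,
               cells$par_pct / 100 * cells$annual_cost_usd)
})
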