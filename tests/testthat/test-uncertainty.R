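test_that("log-normal moments invert in closed form and by simulation", {
  p0 <- lognormal_params(7, 0)
  expect_equal(p0$mu, log(7))
  expect_equal(p0$sigma, 0)
  p <- lognormal_params(10, 5.4)
  expect_equal(p$sigma, sqrt(log(1 + (5.4 / 10)^2)))
  expect_equal(p$sigma, 0.5055, tolerance = 1e-3)
  expect_equal(p$mu, log(10) - p$sigma^2 / 2)
  set.seed(21)
  x <- rlnorm(1e6, p$mu, p$sigma)
  expect_equal(mean(x), 10, tolerance = 0.01)
  expect_equal(sd(x), 5.4, tolerance = 0.01)
  expect_error(lognormal_params(-2, 1), "mean")
})

test_that("percentile intervals follow the interpolated order statistics", {
  expect_equal(percentile_interval(rep(3.7, 50)),
               c(low = 3.7, high = 3.7))
  expect_equal(percentile_interval(1:1000),
               c(low = 25.975, high = 975.025))
  near_full <- percentile_interval(1:1000, level = 1 - 1e-9)
  expect_equal(unname(near_full), c(1, 1000), tolerance = 1e-4)
  expect_error(percentile_interval(numeric(0)), "non-empty")
})

test_that("degenerate sampling collapses the simulation onto the point run", {
  b <- tiny_bundle()
  det <- run_pipeline(b)
  cfg <- mc_config(draws = 50, seed = 5, intake_mean_cv = 0, cost_cv = 0,
                   rr_log_se_frac = 0, deaths_cv = 0)
  mc <- run_monte_carlo(b, cfg)
  pts <- setNames(mc$point, mc$quantity)
  expect_equal(pts[names(det$outputs)], det$outputs)
  expect_equal(mc$ui_low, mc$point)
  expect_equal(mc$ui_high, mc$point)
})

test_that("a fixed seed reproduces the simulation bit for bit", {
  b <- tiny_bundle()
  m1 <- run_monte_carlo(b, mc_config(draws = 300, seed = 11))
  m2 <- run_monte_carlo(b, mc_config(draws = 300, seed = 11))
  expect_identical(m1, m2)
  m3 <- run_monte_carlo(b, mc_config(draws = 300, seed = 12))
  expect_false(identical(m1$point, m3$point))
})

test_that("interval width shrinks as input spreads shrink", {
  b <- tiny_bundle()
  width <- sapply(c(1, 0.5, 0.1), function(k) {
    cfg <- mc_config(draws = 1000, seed = 31, intake_mean_cv = 0.05 * k,
                     cost_cv = 0.05 * k, rr_log_se_frac = 0.1 * k,
                     deaths_cv = 0.05 * k)
    mc <- run_monte_carlo(b, cfg)
    with(mc[mc$quantity == "direct_total_usd", ], ui_high - ui_low)
  })
  expect_true(all(diff(width) < 0))
})

test_that("doubling cost-cell means doubles the cost point estimates", {
  b <- tiny_bundle()
  b2 <- b
  b2$cost_table$annual_cost_usd <- 2 * b2$cost_table$annual_cost_usd
  cfg <- mc_config(draws = 2000, seed = 77)
  m1 <- run_monte_carlo(b, cfg)
  m2 <- run_monte_carlo(b2, cfg)
  for (q in c("direct_total_usd", "direct_CHD_usd", "direct_male_usd")) {
    expect_equal(m2$point[m2$quantity == q], 2 * m1$point[m1$quantity == q],
                 tolerance = 1e-9)
  }
  # productivity does not depend on the cost table
  expect_equal(m2$point[m2$quantity == "productivity_total_usd"],
               m1$point[m1$quantity == "productivity_total_usd"])
})

test_that("per-cell substreams are stable when unrelated inputs change", {
  b <- tiny_bundle()
  cfg <- mc_config(draws = 200, seed = 13)
  m1 <- run_monte_carlo(b, cfg, keep_draws = TRUE)
  b2 <- b
  b2$mortality$n_deaths <- b2$mortality$n_deaths * 3  # unrelated to costs
  m2 <- run_monte_carlo(b2, cfg, keep_draws = TRUE)
  d1 <- attr(m1, "draws"); d2 <- attr(m2, "draws")
  expect_identical(d1[, "direct_total_usd"], d2[, "direct_total_usd"])
})

test_that("draw counts below one are rejected", {
  expect_error(mc_config(draws = 0), "draws")
})
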