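test_that("years of life lost multiply deaths by residual life expectancy", {
  expect_equal(yll(0, 30), 0)
  expect_equal(yll(10, 30), 300)
  expect_equal(yll(1, 82.6), 82.6)
  expect_error(yll(-1, 30), "n_deaths")
})

test_that("working years lost truncate to the sex-specific pension window", {
  expect_equal(working_years_lost(70, "male"), 0)
  expect_equal(working_years_lost(50, "male"), 15)
  expect_equal(working_years_lost(58, "female"), 2)
  # deaths below working age count the full working span
  expect_equal(working_years_lost(10, "male"), 50)
  expect_equal(working_years_lost(10, "female"), 45)
  expect_equal(working_years_lost(65, "male"), 0)
})

test_that("human-capital monetization is linear in YPLL and participation", {
  expect_equal(productivity_loss(0), 0)
  expect_equal(productivity_loss(100), 569160)  # 100 x 765 x 12 x 0.62
  expect_equal(productivity_loss(1, labor_params(participation_rate = 1)),
               9180)
  lab <- labor_params()
  set.seed(4)
  y <- runif(10, 0, 50)
  expect_equal(productivity_loss(2 * y, lab), 2 * productivity_loss(y, lab))
  expect_equal(productivity_loss(y, labor_params(participation_rate = 0)),
               rep(0, 10))
})

test_that("a positive discount rate shrinks but never zeroes losses", {
  lab0 <- labor_params()
  lab3 <- labor_params(discount_rate = 0.03)
  expect_lt(productivity_loss(20, lab3), productivity_loss(20, lab0))
  expect_gt(productivity_loss(20, lab3), 0)
  expect_equal(productivity_loss(0, lab3), 0)
})

test_that("YPLL never exceeds YLL when life expectancy spans working years", {
  b <- tiny_bundle()
  tab <- productivity_table(b$mortality, b$labor)
  wyl <- working_years_lost(b$mortality$age_at_death, b$mortality$sex, b$labor)
  spans <- b$mortality$residual_life_expectancy >= wyl
  expect_true(all(spans))  # tiny fixture satisfies the premise
  expect_true(all(tab$ypll[spans] <= tab$yll[spans] + 1e-12))
  expect_true(all(tab$yll >= 0 & tab$ypll >= 0 & tab$loss_usd >= 0))
})

test_that("productivity report reproduces published-style aggregation", {
  cells <- tibble::tibble(
    outcome = rep(c("CHD", "stroke"), each = 2),
    sex = rep(c("male", "female"), 2),
    age_group = "45-49",
    loss_usd = c(1932, 2141, 1408, 1349) * 1000,
    yll = 1, ypll = 0.5)
  rep <- productivity_report(cells)
  expect_equal(rep$grand_total, 6830000)
  expect_equal(rep$by_disease$share_pct[rep$by_disease$disease == "CHD"], 60)
  expect_equal(rep$by_sex$share_pct[rep$by_sex$sex == "female"], 51)
  # empty input: empty table, zero totals
  empty <- productivity_report(tibble::tibble(outcome = character(),
                                              sex = character(),
                                              loss_usd = numeric()))
  expect_equal(empty$grand_total, 0)
  expect_equal(nrow(empty$cells), 0)
})
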