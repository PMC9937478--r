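test_that("the default fixture is pure and carries the published key inputs", {
  b1 <- default_fixture()
  b2 <- default_fixture()
  expect_identical(b1, b2)
  expect_equal(b1$baseline$mean, 10.0)
  expect_equal(b1$baseline$sd, 5.4)
  expect_equal(b1$baseline$kcal, 2171)
  expect_equal(b1$counterfactual$mean, 5.0)
  expect_equal(b1$counterfactual$sd, 2.65)
  expect_equal(b1$labor$participation_rate, 0.62)
  expect_equal(b1$labor$monthly_wage, 765)
  expect_equal(b1$labor$pension_age_female, 60)
  expect_equal(b1$labor$pension_age_male, 65)
  expect_equal(b1$currency$crc_per_usd, 600)
  ct <- b1$cost_table
  expect_equal(sum(ct$annual_cost_usd[ct$service == "hospitalization"]),
               1584985326.39)
  expect_equal(sum(ct$annual_cost_usd[ct$service == "consultation"]),
               853309618.14)
  expect_equal(sum(ct$annual_cost_usd[ct$service == "medication"],
                   na.rm = TRUE), 642090.81)
  # medication unavailable for stroke and RHD, and only there
  unavailable <- ct[!ct$available, ]
  expect_setequal(unique(unavailable$disease), c("stroke", "RHD"))
  expect_setequal(unique(unavailable$service), "medication")
  expect_true(all(is.na(unavailable$annual_cost_usd)))
  expect_silent(validate_bundle(b1))
})

test_that("random bundles are seed-deterministic and seed-sensitive", {
  a1 <- generate_random_bundle(seed = 1)
  a2 <- generate_random_bundle(seed = 1)
  expect_identical(a1, a2)
  b <- generate_random_bundle(seed = 2)
  expect_false(isTRUE(all.equal(a1$cost_table$annual_cost_usd,
                                b$cost_table$annual_cost_usd)))
})

test_that("generated bundles satisfy every structural invariant", {
  for (s in c(7, 19, 103)) {
    b <- generate_random_bundle(seed = s)
    expect_silent(validate_bundle(b))
    expect_true(all(b$rr_table$rr_per_mmHg >= 1))
    # RRs weakly decreasing across age bands within outcome x sex
    dec <- b$rr_table |>
      dplyr::group_by(outcome, sex) |>
      dplyr::summarise(ok = all(diff(rr_per_mmHg) <= 1e-12),
                       .groups = "drop")
    expect_true(all(dec$ok))
    costs <- b$cost_table$annual_cost_usd[b$cost_table$available]
    expect_true(all(costs > 0))
    expect_true(all(b$mortality$n_deaths >= 0))
  }
})

test_that("bundle validation names the violated field", {
  b <- default_fixture()
  b$rr_table$rr_per_mmHg[3] <- -1
  expect_error(validate_bundle(b), "rr_per_mmHg")
  b2 <- default_fixture()
  b2$strata$population[1] <- 0
  expect_error(validate_bundle(b2), "population")
  b3 <- default_fixture()
  b3$mortality$n_deaths[1] <- -2
  expect_error(validate_bundle(b3), "n_deaths")
})

test_that("a zero-SD intake degenerates cleanly through the pipeline", {
  b <- tiny_bundle(intake_mean = 10, intake_sd = 0)
  res <- run_pipeline(b)
  expect_equal(unique(res$paf$P), 1)  # everyone in the bin containing 10 g
  expect_true(all(is.finite(res$outputs)))
})
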