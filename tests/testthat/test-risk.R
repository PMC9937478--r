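test_that("per-bin relative risks rescale log-linearly in the SBP shift", {
  expect_equal(rr_at_bin(1, 8, 5), 1)
  expect_equal(rr_at_bin(1.27, 5, 5), 1)  # zero shift at the reference
  expect_equal(rr_at_bin(1.02, 11, 5), 1.02^5.8)
  expect_equal(rr_at_bin(1.02, 11, 5), 1.1217, tolerance = 1e-4)
  expect_error(rr_at_bin(-0.5, 11, 5), "rr_per_mmHg")
})

test_that("combined RR is the prevalence-weighted mean over exposed bins", {
  prev <- exposure_prevalence(c(0.5, 0.25, 0.25), c(5, 6.5, 8.5),
                              c(FALSE, TRUE, TRUE), reference = 5)
  out <- combined_rr(prev, c(1, 1.2, 1.4))
  expect_equal(out$P, 0.5)
  expect_equal(out$RR, 1.3)
  # unexposed population
  ref_only <- exposure_prevalence(c(1, 0, 0), c(5, 6.5, 8.5),
                                  c(FALSE, TRUE, TRUE), reference = 5)
  expect_equal(combined_rr(ref_only, c(1, 1.2, 1.4)), list(P = 0, RR = 1))
  # constant RR across exposed bins aggregates to itself
  set.seed(2)
  for (i in 1:10) {
    w <- runif(3); w <- w / sum(w)
    prev_i <- exposure_prevalence(w, c(5, 6.5, 8.5), c(FALSE, TRUE, TRUE),
                                  reference = 5)
    expect_equal(combined_rr(prev_i, c(1, 1.7, 1.7))$RR, 1.7)
  }
  expect_error(combined_rr(prev, c(1, 1.2)), "length")
})

test_that("the PAR formula evaluates exactly and flags protective exposure", {
  expect_equal(par_percent(0.3, 1), 0)
  expect_equal(par_percent(1, 2), 50)
  expect_equal(par_percent(0.5, 3), 50)
  expect_warning(out <- par_percent(0.5, 0.8), "protective")
  expect_lt(out, 0)
  expect_error(par_percent(1.2, 2), "P")
  expect_error(par_percent(0.5, 0), "RR")
})

test_that("PAR is strictly increasing in RR and in P", {
  rr <- seq(1.05, 3, length.out = 20)
  expect_true(all(diff(par_percent(rep(0.4, 20), rr)) > 0))
  p <- seq(0.05, 1, length.out = 20)
  expect_true(all(diff(par_percent(p, rep(1.8, 20))) > 0))
})

test_that("binary PAR with combined RR equals the multi-category PAF", {
  # identity: with RR = sum(w_i RR_i)/P over exposed bins,
  # P(RR-1) = sum(p_i (RR_i - 1)), so both forms agree to machine precision
  set.seed(7)
  for (i in 1:50) {
    w <- runif(3); w <- w / sum(w)
    rrs <- runif(2, 0.9, 3)
    prev <- exposure_prevalence(w, c(5, 6.5, 8.5), c(FALSE, TRUE, TRUE),
                                reference = 5)
    comb <- combined_rr(prev, c(1, rrs))
    got <- suppressWarnings(par_percent(comb$P, comb$RR))
    want <- oracle_paf_multicat(w[2:3], rrs)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("raising the baseline intake mean never decreases any stratum PAR", {
  b <- tiny_bundle()
  pars <- sapply(c(7, 8.5, 10, 12, 14), function(m) {
    prev <- discretize(intake_distribution(m, 4), b$bins)
    stratum_paf(b$rr_table, prev, spec = b$dose_response,
                mode = "threshold")$par_baseline
  })
  expect_true(all(apply(pars, 1, function(x) all(diff(x) >= -1e-12))))
})

test_that("stratum PARs pool to outcome x sex with population weights", {
  paf <- tibble::tibble(outcome = "CHD", sex = "male",
                        age_group = c("15-19", "45-49"),
                        rr_per_mmHg = 1.02, P = 0.5, RR = 1.2,
                        par_baseline = c(10, 20),
                        par_counterfactual = 0, par_net = c(10, 20))
  strata <- tibble::tibble(sex = "male", age_group = c("15-19", "45-49"),
                           population = c(1000, 3000))
  pooled <- pooled_par(paf, strata)
  expect_equal(pooled$par_pct, 17.5)
  expect_error(
    pooled_par(dplyr::mutate(paf, age_group = c("15-19", "80+")), strata),
    "strata")
})

test_that("duplicate outcome x stratum RR records are rejected", {
  b <- tiny_bundle()
  rr2 <- rbind(b$rr_table, b$rr_table[1, ])
  prev <- discretize(b$baseline, b$bins)
  expect_error(stratum_paf(rr2, prev), "duplicate")
})
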