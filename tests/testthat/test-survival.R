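test_that("exposure binning follows the month conventions", {
  # a full year-2 span contributes ~365.25 days to the first class
  one <- tibble::tibble(animal_id = "a", sex = "m", entry_age_months = 13,
                        exit_age_months = 24, fate = "censored")
  ex <- bin_exposure(one, c(13, 25, 37, 49, 61))
  expect_equal(ex$d_exp, c(365.25, 0, 0, 0))

  # empty ledger: all-zero classes
  ex0 <- bin_exposure(one[0, ], c(13, 25, 37, 49, 61))
  expect_equal(ex0$d_exp, rep(0, 4))
  expect_equal(ex0$n_events, rep(0L, 4))

  expect_error(bin_exposure(one, c(13, 13)), "increasing")
  expect_error(
    bin_exposure(tibble::tibble(animal_id = "b", sex = "m",
                                entry_age_months = 20, exit_age_months = 10,
                                fate = "died")),
    "exit before entry")
})

test_that("the study ledger reconstruction reproduces the published aggregates", {
  ex <- bin_exposure(egoa_exposure_ledger())
  expect_equal(ex$d_exp, c(5757, 7763, 5979, 4573), tolerance = 1e-9)
  expect_equal(ex$n_events, c(7L, 4L, 0L, 1L))
  expect_equal(ex$n_animals, c(35L, 25L, 18L, 15L))
  expect_equal(sum(ex$d_exp), 24072)
})

test_that("Mayfield annual survival matches the published class estimates", {
  expect_equal(round(annual_survival(7, 5757)$period_survival, 3), 0.641)
  expect_equal(annual_survival(0, 5979)$period_survival, 1)
  expect_equal(round(annual_survival(1, 4573)$period_survival, 3), 0.923)
  # published 0.829 is exact under a 365-day annualisation and within
  # 0.001 under the default 365.25
  expect_equal(round(annual_survival(4, 7763, period_days = 365)$period_survival, 3),
               0.829)
  expect_lt(abs(annual_survival(4, 7763)$period_survival - 0.829), 0.001)
  expect_error(annual_survival(3, 0), "positive")
})

test_that("period survival is monotone in events and exposure", {
  s <- function(e, d) annual_survival(e, d)$period_survival
  expect_true(s(8, 5757) < s(7, 5757))
  expect_true(s(7, 6500) > s(7, 5757))
})

test_that("Johnson intervals have delta-method behaviour", {
  ci <- johnson_ci(7, 5757)
  pt <- annual_survival(7, 5757)$period_survival
  expect_true(ci$lo < pt && pt < ci$hi)
  # doubling exposure at fixed daily rate shrinks the interval by ~sqrt(2)
  ci2 <- johnson_ci(14, 2 * 5757)
  expect_lt(ci2$hi - ci2$lo, ci$hi - ci$lo)
  expect_equal((ci$hi - ci$lo) / (ci2$hi - ci2$lo), sqrt(2), tolerance = 0.01)
  # zero events: upper limit 1, one-sided lower below 1
  ci0 <- johnson_ci(0, 5979)
  expect_equal(ci0$hi, 1)
  expect_lt(ci0$lo, 1)
})

test_that("the failure-adjusted lower limit only lowers the bound", {
  base <- johnson_ci(7, 5757)$lo
  adj <- pfail_adjusted_lower_cl(7, 8, 5757)
  expect_lt(adj, base)
  expect_equal(pfail_adjusted_lower_cl(7, 7, 5757), base)
  expect_error(pfail_adjusted_lower_cl(7, 6, 5757), ">=")
})

test_that("cumulative survival multiplies through the age classes", {
  est <- purrr::map_dfr(list(c(7, 5757), c(4, 7763)), function(x) {
    dplyr::bind_cols(annual_survival(x[1], x[2]), johnson_ci(x[1], x[2]))
  })
  cum <- cumulative_survival(est)
  expect_equal(round(cum$period_survival, 3), 0.531)

  est4 <- purrr::map_dfr(list(c(7, 5757), c(4, 7763), c(0, 5979), c(1, 4573)),
                         function(x) annual_survival(x[1], x[2]))
  cum4 <- cumulative_survival(est4)
  # published 13-60-month value 0.491, reproduced within 0.001 under the
  # 365.25-day annualisation
  expect_lt(abs(cum4$period_survival - 0.491), 0.001)

  all1 <- tibble::tibble(period_survival = rep(1, 4))
  expect_equal(cumulative_survival(all1)$period_survival, 1)
})

test_that("survival_table assembles annual and cumulative rows", {
  est <- estimate_pfail(egoa_return_counts())
  tab <- survival_table(egoa_age_class_exposure(),
                        f_correction = est$f_correction, e_corr_upper = 13)
  annual <- tab[!tab$cumulative, ]
  expect_true(all(abs(annual$period_survival -
                        c(0.641, 0.829, 1.000, 0.923)) < 0.001))
  # the extra upper-limit event goes to the most-exposed event-bearing class
  expect_lt(annual$lo_adjusted[2], johnson_ci(4, 7763)$lo)
  expect_equal(annual$lo_adjusted[1], tab$lo[1], tolerance = 1e-9)
  cum <- tab[tab$cumulative, ]
  expect_equal(cum$age_hi, c(36, 48, 60))
  expect_equal(cum$period_survival[c(1, 3)], c(0.531, 0.491), tolerance = 0.002)
  expect_true(all(cum$lo_adjusted <= cum$lo + 1e-12))
})

test_that("Mayfield recovers the generating annual survival over many cohorts", {
  # pooled exposure over 200 simulated cohorts under a constant year-2 hazard
  s_true <- 0.75
  events <- 0; days <- 0
  for (k in 1:200) {
    sim <- simulate_cohort(
      cohort_spec(n_animals = 40, release_age_months = 13, horizon_months = 24,
                  annual_survival_by_ageclass = c(0.9, s_true),
                  p_fail_true = 0, rng_seed = k),
      profile_events = FALSE
    )
    ex <- bin_exposure(sim$ledger, c(13, 25))
    events <- events + ex$n_events
    days <- days + ex$d_exp
  }
  est <- annual_survival(events, days)$period_survival
  # binomial-scale SE at the pooled animal count
  se <- sqrt(s_true * (1 - s_true) / (200 * 40))
  expect_lt(abs(est - s_true), 3 * se)
})

test_that("estimation over merged classes matches the partition product", {
  # constant hazard across two adjacent year classes: estimating each year
  # and multiplying equals estimating the merged interval directly
  sim <- simulate_cohort(
    cohort_spec(n_animals = 5000, release_age_months = 13, horizon_months = 36,
                annual_survival_by_ageclass = c(0.9, 0.7, 0.7),
                p_fail_true = 0, rng_seed = 31),
    profile_events = FALSE
  )
  by_year <- bin_exposure(sim$ledger, c(13, 25, 37))
  merged <- bin_exposure(sim$ledger, c(13, 37))
  prod_est <- prod(purrr::map_dbl(1:2, function(k) {
    annual_survival(by_year$n_events[k], by_year$d_exp[k])$period_survival
  }))
  direct <- annual_survival(merged$n_events, merged$d_exp,
                            period_days = 2 * 365.25)$period_survival
  expect_equal(prod_est, direct, tolerance = 0.01)
})
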