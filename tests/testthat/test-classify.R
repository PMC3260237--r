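test_that("feature extraction summarises the sensor signature", {
  f <- extract_features(step_event(drop_h = 0.2))
  expect_true(f$usable)
  expect_lte(f$time_to_ambient_h, 0.25)
  expect_equal(f$transmission_delay_h, 0)

  # exponential with half-life 6 h: the +/-1 degree ambient band is reached
  # at t = ln(29)/k ~ 29 h, well beyond 12 h
  f2 <- extract_features(exp_event(k = log(2) / 6))
  expect_gt(f2$time_to_ambient_h, 12)

  # degenerate single-sample record
  ev <- step_event()
  ev$temp_series <- ev$temp_series[1, ]
  expect_false(extract_features(ev)$usable)
})

test_that("cooling-mass fits recover known masses", {
  params <- cooling_params(noise_sd_c = 0)
  # noise-free self-fit is exact to optimizer tolerance
  prof <- generate_temperature_profile("non_traumatic", 100, 8,
                                       params = params, mass_fraction = 0.6,
                                       rng_seed = 1)
  expect_equal(fit_cooling_mass(prof$temp_series, 8, 100, params), 0.6,
               tolerance = 1e-4)

  # with default sensor noise
  noisy <- generate_temperature_profile("non_traumatic", 100, 8,
                                        mass_fraction = 1, rng_seed = 2)
  expect_equal(fit_cooling_mass(noisy$temp_series, 8, 100), 1, tolerance = 0.05)
  noisy14 <- generate_temperature_profile("non_traumatic", 100, 8,
                                          mass_fraction = 0.14, rng_seed = 3)
  expect_equal(fit_cooling_mass(noisy14$temp_series, 8, 100), 0.14,
               tolerance = 0.03)
})

test_that("events are classified by signature and cooling mass", {
  # ten precipitous-drop events with immediate transmissions -> predation
  steps <- lapply(1:10, function(i) step_event(id = paste0("s", i)))
  res <- classify_events(steps)
  expect_equal(res$cause, rep("predation", 10))

  # gradual cooling at 14% of predicted mass -> predation (dismemberment)
  dism <- generate_temperature_profile("non_traumatic", 100, 8,
                                       mass_fraction = 0.14, rng_seed = 4)
  dism$event_id <- "d"
  res_d <- classify_events(list(dism))
  expect_equal(res_d$cause, "predation")
  expect_match(res_d$rationale, "dismemberment")

  # intact gradual cooling -> non-traumatic; no payload -> undetermined
  intact <- generate_temperature_profile("non_traumatic", 100, 8, rng_seed = 5)
  intact$event_id <- "i"
  res2 <- classify_events(list(intact, empty_event()))
  expect_equal(res2$cause, c("non_traumatic", "undetermined"))
})

test_that("classifier separates the archetypes at default noise", {
  # >= 99% of simulated predation and intact non-traumatic events must be
  # recovered correctly
  n_each <- 120
  events <- c(
    lapply(seq_len(n_each), function(i) {
      p <- generate_temperature_profile("predation", 100, 8, rng_seed = i)
      p$event_id <- paste0("p", i); p
    }),
    lapply(seq_len(n_each), function(i) {
      p <- generate_temperature_profile("non_traumatic", 100, 8,
                                        rng_seed = 10000 + i)
      p$event_id <- paste0("n", i); p
    })
  )
  res <- classify_events(events)
  truth <- rep(c("predation", "non_traumatic"), each = n_each)
  acc_p <- mean(res$cause[truth == "predation"] == "predation")
  acc_n <- mean(res$cause[truth == "non_traumatic"] == "non_traumatic")
  expect_gte(acc_p, 0.99)
  expect_gte(acc_n, 0.99)
})

test_that("the predation proportion uses the conservative denominator", {
  pp <- estimate_pp(egoa_cause_summary(), iterations = 2000, rng_seed = 1)
  expect_equal(round(pp$pp_point, 3), 0.917)   # 11 of 12 detected
  expect_equal(pp$pp_ceiling, 1)               # 11 of 11 classifiable
  expect_equal(pp$n_classified, 11)

  # order invariance
  shuffled <- egoa_cause_summary()[c(12, 3, 1, 5, 7, 2, 4, 6, 8, 9, 11, 10), ,
                                   drop = FALSE]
  pp2 <- estimate_pp(shuffled, iterations = 2000, rng_seed = 1)
  expect_equal(pp2$pp_point, pp$pp_point)

  expect_equal(estimate_pp(tibble::tibble(cause = rep("non_traumatic", 5)),
                           iterations = 500, rng_seed = 1)$pp_point, 0)
  expect_error(estimate_pp(tibble::tibble(cause = rep("undetermined", 3))),
               "no classifiable")
})

test_that("the Monte Carlo lower limit matches the exact binomial bound", {
  # 11 predation in 12 detected: exact bound 0.05^(1/12) = 0.779
  lower <- mc_pp_lower_cl(11, 12, iterations = 10000, rng_seed = 1)
  exact <- lhxdemog:::exact_pp_lower_cl(11, 12)
  expect_equal(exact, 0.05^(1 / 12), tolerance = 1e-6)
  expect_lt(abs(lower - exact), 0.015)  # grid resolution + MC noise

  # working value is the centre of [lower, 1]
  pp <- estimate_pp(egoa_cause_summary(), iterations = 10000, rng_seed = 1)
  expect_lt(abs(pp$pp_working - 0.89), 0.01)

  # the coarse published grid is available
  lower_coarse <- mc_pp_lower_cl(11, 12, iterations = 5000, grid_step = 0.1,
                                 rng_seed = 1)
  expect_equal(lower_coarse, 0.8, tolerance = 0.1 + 1e-9)
})

test_that("the lower limit is monotone and approaches 1 for clean sweeps", {
  lows <- vapply(6:12, function(k) {
    lhxdemog:::exact_pp_lower_cl(k, 12)
  }, numeric(1))
  # non-decreasing; strictly increasing until the all-predation ceiling,
  # where the (n, n) fallback coincides with the n-1 bound
  expect_true(all(diff(lows) >= 0))
  expect_true(all(diff(lows[1:6]) > 0))

  # (n, n): the limit increases toward 1 with n
  l5 <- mc_pp_lower_cl(5, 5, iterations = 4000, rng_seed = 2)
  l20 <- mc_pp_lower_cl(20, 20, iterations = 4000, rng_seed = 2)
  l60 <- mc_pp_lower_cl(60, 60, iterations = 4000, rng_seed = 2)
  expect_true(l5 < l20 && l20 < l60)
  expect_gt(l60, 0.9)
})
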