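# anchors and models are deterministic; build once for the file
lhx_f <- build_lhx_egoa()
lhx_m <- derive_male_schedule(lhx_f)
anchors <- response_anchors(lhx_f, lhx_m)
mod_sig <- response_model("sigmoid", anchors)
mod_flat <- response_model("flat", anchors)
mod_lin <- response_model("linear", anchors)
grid <- seq(0.2, 1, by = 0.04)
sweep_sig <- response_sweep(mod_sig, grid)

test_that("anchors reproduce the pre-decline survivorship at peak abundance", {
  # with fixed non-predation mortality, consumption at 100% rebuilds the
  # pre-decline schedule: cumulative months 13-60 survival 0.64
  m <- metrics_at(mod_sig, 1)
  pre <- hfys_pre_schedule()
  expect_equal(prod(pre$s[2:5]), 0.64, tolerance = 1e-9)
  sol <- lhxdemog:::solve_response(mod_sig, 1)
  s_f <- sol$state$F$n[3:6] / sol$state$F$n[2:5]
  expect_equal(prod(s_f), 0.64, tolerance = 1e-3)
  # female recruitment at peak is 51%
  expect_equal(m$female_recruitment, 0.51, tolerance = 0.005)
})

test_that("the predation age structure shifts between the anchors", {
  # shares of predation events using the 13-60-month juvenile definition
  share <- function(a) {
    cons <- consumption_at(mod_sig, a) %>%
      dplyr::group_by(.data$age_year) %>%
      dplyr::summarise(consumed = sum(.data$consumed), .groups = "drop")
    c(pup = cons$consumed[1],
      juv = sum(cons$consumed[2:5]),
      adult = sum(cons$consumed[6:31])) / sum(cons$consumed)
  }
  s20 <- share(0.2)
  # published contemporary split: pups 23%, juveniles 72%, adults 5%
  # (absolute tolerances; the base schedules are reconstructions)
  expect_lt(abs(s20[["pup"]] - 0.23), 0.05)
  expect_lt(abs(s20[["juv"]] - 0.72), 0.05)
  expect_lt(abs(s20[["adult"]] - 0.05), 0.03)
  # at peak abundance adults carry a far larger share of predation
  s100 <- share(1)
  expect_gt(s100["adult"], 0.25)
  expect_lt(s100["pup"], 0.12)
})

test_that("infeasible peak-abundance consumption names the age class", {
  high <- vital_schedule(c(0.99, rep(0.95, 30)), pp = 0)
  expect_error(
    response_anchors(lhx_f, lhx_m, pre_female = high,
                     pre_male = derive_male_schedule(high, decay_ratio = 0.98)),
    "age class 1")
})

test_that("flat and linear consumption interpolate the anchors", {
  c_flat_20 <- consumption_at(mod_flat, 0.2)
  c_flat_100 <- consumption_at(mod_flat, 1)
  expect_equal(c_flat_20$consumed, c_flat_100$consumed, tolerance = 1e-9)

  c_lin <- consumption_at(mod_lin, 0.6)
  mid <- (anchors$C20 + anchors$C100) / 2
  expect_equal(c_lin$consumed[c_lin$sex == "female"], unname(mid[, "F"]),
               tolerance = 1e-6)
})

test_that("sigmoid consumption holds total consumed mass flat at high abundance", {
  masses <- vapply(c(0.6, 0.8, 1.0),
                   function(a) metrics_at(mod_sig, a)$mass_consumed_t,
                   numeric(1))
  expect_lt(diff(range(masses)) / max(masses), 0.01)
})

test_that("contemporary-abundance metrics match the published consumption", {
  m02 <- metrics_at(mod_sig, 0.2)
  expect_equal(m02$total_consumed, 2676, tolerance = 0.10)
  # juveniles by the 13-60-month definition
  cons <- consumption_at(mod_sig, 0.2)
  juv <- sum(cons$consumed[cons$age_year %in% 2:5])
  expect_equal(juv, 1938, tolerance = 0.10)
  # the contemporary state is self-consistent: no pup deficit at birth rate 0.69
  expect_lt(abs(m02$pup_difference) / m02$seed, 1e-3)
})

test_that("zero consumption leaves the non-predation-only schedule", {
  no_pred_f <- build_lhx_egoa(pp_juvenile = 0)
  no_pred_m <- derive_male_schedule(no_pred_f)
  an0 <- response_anchors(no_pred_f, no_pred_m,
                          pre_female = no_pred_f, pre_male = no_pred_m)
  mod0 <- response_model("flat", an0)
  sol <- lhxdemog:::solve_response(mod0, 0.5)
  s_obs <- sol$state$F$n[2:31] / sol$state$F$n[1:30]
  expect_equal(s_obs, 1 - no_pred_f$m_np[1:30], tolerance = 1e-9)
})

test_that("sweeps conserve the seed and keep non-predation density-independent", {
  for (a in c(0.25, 0.5, 0.75, 1)) {
    sol <- lhxdemog:::solve_response(mod_sig, a)
    for (sx in c("F", "M")) {
      st <- sol$state[[sx]]
      expect_equal(sum(st$p + st$d) + st$n_end, sol$seed / 2,
                   tolerance = 1e-9 * sol$seed)
      # per-capita non-predation mortality never varies with abundance
      expect_equal(st$d / st$n, unname(anchors$m_np[, sx]), tolerance = 1e-12)
    }
  }
})

test_that("the sigmoid sweep exhibits the published landmarks", {
  sw <- sweep_sig
  # juvenile predation proportion peaks near 0.92 at intermediate abundance
  i_pp <- which.max(sw$pp_juvenile)
  expect_equal(sw$pp_juvenile[i_pp], 0.92, tolerance = 0.033)
  expect_true(sw$abundance_frac[i_pp] >= 0.35 &&
                sw$abundance_frac[i_pp] <= 0.55)
  # juvenile consumption peaks near 8,240 animals at mid abundance
  i_juv <- which.max(sw$consumed_juveniles)
  expect_equal(sw$consumed_juveniles[i_juv], 8240, tolerance = 0.20)
  expect_true(sw$abundance_frac[i_juv] >= 0.40 &&
                sw$abundance_frac[i_juv] <= 0.60)
  # the juvenile fraction J/T has an interior maximum between 40 and 50%
  i_jt <- which.max(sw$j_over_t)
  expect_true(sw$abundance_frac[i_jt] >= 0.40 &&
                sw$abundance_frac[i_jt] <= 0.50)
  expect_gt(sw$j_over_t[i_jt], sw$j_over_t[1])
  expect_gt(sw$j_over_t[i_jt], sw$j_over_t[nrow(sw)])
  # the most vulnerable class's annual survival bottoms out near 49%
  expect_equal(min(sw$survival_year2), 0.49, tolerance = 0.05)
})

test_that("female recruitment halves between peak and the trough", {
  sw <- sweep_sig
  expect_equal(sw$female_recruitment[sw$abundance_frac == 1], 0.51,
               tolerance = 0.03 / 0.51)
  trough <- sw$abundance_frac[which.max(sw$pup_difference)]
  expect_true(trough >= 0.40 && trough <= 0.55)
  expect_equal(min(sw$female_recruitment), 0.23, tolerance = 0.03 / 0.23)
})

test_that("the adult-female consumed fraction barely moves with abundance", {
  sw <- sweep_sig
  at1 <- sw$adult_female_consumed_frac[sw$abundance_frac == 1]
  at_trough <- sw$adult_female_consumed_frac[which.max(sw$pup_difference)]
  expect_equal(at1, 0.036, tolerance = 0.003 / 0.036)
  expect_lt(abs(at1 - at_trough), 0.003)
})

test_that("flat and linear sweeps have their qualitative shapes", {
  sw_f <- response_sweep(mod_flat, grid)
  expect_lt(diff(range(sw_f$total_consumed)), 1e-6 * max(sw_f$total_consumed))
  sw_l <- response_sweep(mod_lin, grid)
  expect_true(all(diff(sw_l$pup_difference) < 0))
  # neither admits a stable equilibrium above the contemporary state
  eq_f <- find_equilibria(sw_f)
  expect_true(nrow(eq_f[eq_f$stable & eq_f$abundance_frac > 0.21, ]) == 0)
})

test_that("equilibria sit at the contemporary state and shift with natality", {
  eq <- find_equilibria(sweep_sig)
  stable <- eq[eq$stable, ]
  expect_gte(nrow(stable), 1)
  expect_equal(stable$abundance_frac[1], 0.20, tolerance = 0.02)

  # raising natality to 1.0 moves the stable equilibrium to ~32% abundance
  mod_hi <- response_model("sigmoid", anchors, birth_rate = 1.0)
  sw_hi <- response_sweep(mod_hi, grid)
  eq_hi <- find_equilibria(sw_hi)
  stable_hi <- eq_hi[eq_hi$stable, ]
  expect_gte(nrow(stable_hi), 1)
  expect_equal(stable_hi$abundance_frac[1], 0.32, tolerance = 0.03)
})
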