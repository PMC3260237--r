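# shared builders for small synthetic fixtures

# noiseless step-drop event (acute archetype)
step_event <- function(ambient = 8, drop_h = 0.2, id = "step") {
  tm <- seq(-2, 48, by = 0.25)
  temp <- ifelse(tm < 0, 37, ambient + (37 - ambient) * pmax(0, 1 - tm / drop_h))
  structure(list(
    event_id = id,
    temp_series = tibble::tibble(time_h = tm, temp_c = temp),
    medium_series = tibble::tibble(time_h = c(-2, 0), medium = c("tissue", "air")),
    transmission_delay_h = 0, extrusion_delay_h = 0,
    ambient_c = ambient, expected_mass_kg = 100
  ), class = "lhx_event_profile")
}

# noiseless Newtonian-cooling event at a known rate constant
exp_event <- function(k, ambient = 8, id = "exp", delay = 24) {
  tm <- seq(-2, 48, by = 0.25)
  temp <- ifelse(tm < 0, 37, ambient + (37 - ambient) * exp(-k * tm))
  structure(list(
    event_id = id,
    temp_series = tibble::tibble(time_h = tm, temp_c = temp),
    medium_series = tibble::tibble(time_h = c(-2, delay), medium = c("tissue", "air")),
    transmission_delay_h = delay, extrusion_delay_h = delay,
    ambient_c = ambient, expected_mass_kg = 100
  ), class = "lhx_event_profile")
}

# event with no usable sensor payload
empty_event <- function(id = "none") {
  structure(list(
    event_id = id, temp_series = NULL, medium_series = NULL,
    transmission_delay_h = NA_real_, extrusion_delay_h = NA_real_,
    ambient_c = 8, expected_mass_kg = 100
  ), class = "lhx_event_profile")
}

# study 2x2 tables: rows are strata, columns single/dual returns
tbl_live_carcass <- matrix(c(3, 9, 1, 8), 2, byrow = TRUE)
tbl_carcass_predation <- matrix(c(1, 8, 2, 9), 2, byrow = TRUE)

# standard error of the P_fail estimator given n detected dual-deployment
# events (delta method on the conditional single-return fraction)
pfail_se <- function(p, n) {
  q <- 2 * p / (1 + p)
  2 / (2 - q)^2 * sqrt(q * (1 - q) / n)
}
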