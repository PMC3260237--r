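#' Cooling-model constants
#'
#' Single-compartment Newtonian (algor mortis) cooling: after death the
#' tag-recorded temperature relaxes from core body temperature toward
#' ambient as `T(t) = ambient + (37 - ambient) * exp(-k t)` with rate
#' `k = k0 * (mass_ref / mass)^beta`. The surface-to-volume default
#' `beta = 2/3` makes small (dismembered) cooling masses cool faster; the
#' absolute constants are stand-ins validated by self-consistency
#' (generator and fitter share this parameterisation).
#'
#' @param k0 cooling rate (1/h) at the reference mass.
#' @param beta mass-scaling exponent.
#' @param mass_ref_kg reference mass (kg).
#' @param body_temp_c ante-mortem core temperature.
#' @param noise_sd_c additive sensor noise SD (degrees C).
#' @param extrusion_meanlog,extrusion_sdlog log-normal parameters of the
#'   extrusion (and transmission onset) delay for non-traumatic deaths, h.
#' @return A list of constants.
#' @export
cooling_params <- function(k0 = 0.1, beta = 2 / 3, mass_ref_kg = 100,
                           body_temp_c = 37, noise_sd_c = 0.3,
                           extrusion_meanlog = log(24),
                           extrusion_sdlog = 0.4) {
  assert_positive(c(k0, mass_ref_kg, noise_sd_c + 1e-12), "cooling constants")
  list(k0 = k0, beta = beta, mass_ref_kg = mass_ref_kg,
       body_temp_c = body_temp_c, noise_sd_c = noise_sd_c,
       extrusion_meanlog = extrusion_meanlog,
       extrusion_sdlog = extrusion_sdlog)
}

# noiseless Newtonian cooling curve at a given cooling mass
cooling_curve <- function(time_h, mass_kg, ambient_c, params) {
  k <- params$k0 * (params$mass_ref_kg / mass_kg)^params$beta
  ifelse(time_h < 0, params$body_temp_c,
         ambient_c + (params$body_temp_c - ambient_c) * exp(-k * time_h))
}

#' Generate a post-mortem temperature profile
#'
#' Emulates the two sensor-signature archetypes a recovered implanted tag
#' records across a mortality event. Predation (acute death with
#' dismemberment): a precipitous drop from body temperature to ambient
#' within minutes, immediate sensing of water/air and immediate
#' transmissions. Non-traumatic death: Newtonian cooling of the intact (or
#' partially intact) carcass with rate set by the effective cooling mass,
#' and tag extrusion (hence light, medium change and transmissions) delayed
#' by decomposition.
#'
#' @param cause `"predation"` or `"non_traumatic"`.
#' @param mass_kg expected (ante-mortem) body mass, kg.
#' @param ambient_c ambient water temperature (must be below body
#'   temperature).
#' @param params constants from [cooling_params()].
#' @param mass_fraction effective cooling mass as a fraction of `mass_kg`
#'   (non-traumatic only; < 1 emulates partial dismemberment).
#' @param duration_h length of the recorded series after death.
#' @param step_h sampling interval.
#' @param rng_seed optional integer seed.
#'
#' @return A list of class `lhx_event_profile`: `temp_series` (tibble
#'   `time_h`, `temp_c`; time 0 is death), `medium_series`,
#'   `extrusion_delay_h`, `transmission_delay_h`, `cause`, `ambient_c`,
#'   `expected_mass_kg`, `mass_fraction`.
#' @examples
#' prof <- generate_temperature_profile("predation", 100, 8, rng_seed = 1)
#' min(prof$temp_series$temp_c) < 10
#' @export
generate_temperature_profile <- function(cause = c("predation", "non_traumatic"),
                                         mass_kg, ambient_c,
                                         params = cooling_params(),
                                         mass_fraction = 1,
                                         duration_h = 48, step_h = 0.25,
                                         rng_seed = NULL) {
  cause <- match.arg(cause)
  assert_positive(mass_kg, "mass_kg")
  if (ambient_c >= params$body_temp_c) {
    abort("`ambient_c` must be below body temperature")
  }
  if (!is.null(rng_seed)) set.seed(rng_seed)
  time_h <- seq(-6, duration_h, by = step_h)
  if (cause == "predation") {
    # step-like drop: reaches ambient within ~0.2 h of death
    temp <- ifelse(time_h < 0, params$body_temp_c,
                   ambient_c + (params$body_temp_c - ambient_c) *
                     pmax(0, 1 - time_h / 0.2))
    extrusion <- 0
    medium <- tibble(
      time_h = c(min(time_h), 0, 0.5),
      medium = c("tissue", "saltwater", "air")
    )
  } else {
    temp <- cooling_curve(time_h, mass_fraction * mass_kg, ambient_c, params)
    extrusion <- rlnorm(1, params$extrusion_meanlog, params$extrusion_sdlog)
    medium <- tibble(
      time_h = c(min(time_h), extrusion, extrusion + 0.5),
      medium = c("tissue", "saltwater", "air")
    )
  }
  temp <- temp + rnorm(length(temp), 0, params$noise_sd_c)
  structure(
    list(
      temp_series = tibble(time_h = time_h, temp_c = temp),
      medium_series = medium,
      extrusion_delay_h = extrusion,
      transmission_delay_h = extrusion,
      cause = cause,
      ambient_c = ambient_c,
      expected_mass_kg = mass_kg,
      mass_fraction = mass_fraction
    ),
    class = "lhx_event_profile"
  )
}
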