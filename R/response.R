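#' Synthetic body-mass schedule
#'
#' Sex-specific mass-at-age from a von-Bertalanffy-type growth curve,
#' `W(a) = W_inf * (1 - exp(-k (a - t0)))^3` evaluated at class midpoints.
#' This is a synthetic placeholder for the external mass-at-age table the
#' consumption-mass calculations require; consumed-mass outputs are
#' therefore indicative only (see the methods vignette).
#'
#' @param winf_f,winf_m asymptotic mass (kg) by sex.
#' @param k_f,k_m growth rate (1/yr) by sex.
#' @param t0_f,t0_m age offset (yr) by sex.
#' @return A tibble: `sex`, `age_year`, `mass_kg`.
#' @export
mass_schedule_synthetic <- function(winf_f = 265, k_f = 0.45, t0_f = -1.7,
                                    winf_m = 430, k_m = 0.38, t0_m = -1.8) {
  age <- (1:31) - 0.5
  vb <- function(winf, k, t0) winf * (1 - exp(-k * (age - t0)))^3
  bind_rows(
    tibble(sex = "female", age_year = 1:31, mass_kg = vb(winf_f, k_f, t0_f)),
    tibble(sex = "male", age_year = 1:31, mass_kg = vb(winf_m, k_m, t0_m))
  )
}

#' Consumption anchors at the contemporary and peak abundance states
#'
#' The 20%-abundance anchor is the predation vector of the contemporary
#' (telemetry-updated) schedules with the pup seed calibrated to the
#' contemporary total; the 100% anchor sets age-class-specific consumption
#' such that, holding non-predation mortality fixed (the framework's
#' density-independence assumption), the resulting survivorship equals the
#' pre-decline schedule, at a seed calibrated to the peak total. Requested
#' consumption that would be negative (pre-decline survival exceeding what
#' fixed non-predation mortality allows) raises an error naming the age
#' class.
#'
#' @param lhx_female,lhx_male contemporary schedules (predation shares
#'   attached).
#' @param pre_female,pre_male pre-decline schedules (survival only).
#' @param abundance_20,abundance_100 the two anchor totals.
#' @return A list of class `lhx_anchors`: consumption matrices `C20`,
#'   `C100` (31 x 2, columns `F`, `M`), per-capita predation rates `mp20`,
#'   `mp100`, fixed non-predation rates `m_np`, the schedules and seeds.
#' @export
response_anchors <- function(lhx_female = build_lhx_egoa(),
                             lhx_male = derive_male_schedule(lhx_female),
                             pre_female = hfys_pre_schedule(),
                             pre_male = NULL,
                             abundance_20 = 36000,
                             abundance_100 = 180000) {
  validate_schedule(lhx_female); validate_schedule(lhx_male)
  validate_schedule(pre_female)
  if (is.null(pre_male)) {
    pre_male <- derive_male_schedule(pre_female,
                                     decay_ratio = attr(lhx_male, "decay_ratio") %||% NULL)
  }
  m_np <- cbind(F = lhx_female$m_np, M = lhx_male$m_np)
  mp100 <- cbind(F = 1 - pre_female$s - m_np[, "F"],
                 M = 1 - pre_male$s - m_np[, "M"])
  if (any(mp100 < -1e-9)) {
    bad <- which(mp100 < -1e-9, arr.ind = TRUE)[1, ]
    abort(sprintf(
      "infeasible 100%%-abundance consumption at age class %d (%s): pre-decline survival exceeds 1 - m_np",
      bad[1], c("female", "male")[bad[2]]))
  }
  mp100 <- pmax(mp100, 0)
  mp20 <- cbind(F = lhx_female$m_p, M = lhx_male$m_p)
  seed20 <- calibrate_seed(lhx_female, lhx_male, abundance_20)
  seed100 <- calibrate_seed(pre_female, pre_male, abundance_100)
  l20 <- cbind(F = survivorship(lhx_female), M = survivorship(lhx_male))
  l100 <- cbind(F = survivorship(pre_female), M = survivorship(pre_male))
  structure(
    list(
      C20 = seed20 / 2 * l20 * mp20,
      C100 = seed100 / 2 * l100 * mp100,
      mp20 = mp20, mp100 = mp100, m_np = m_np,
      lhx_female = lhx_female, lhx_male = lhx_male,
      pre_female = pre_female, pre_male = pre_male,
      seed20 = seed20, seed100 = seed100,
      abundance_20 = abundance_20, abundance_100 = abundance_100
    ),
    class = "lhx_anchors"
  )
}

#' Sigmoid-response shape constants
#'
#' The sigmoid (type III) response is pinned only by the two anchors and
#' the published landmarks, so its interpolation is a package design
#' choice: adult per-capita predation ramps between the anchor rates along
#' a logistic in abundance (`mid_adult`, `scale_adult`); above `knot` the
#' pup+juvenile consumption is solved at each abundance to hold the total
#' consumed mass at its peak-abundance value, allocated across classes 1-5
#' by a logistic blend (`mid_alloc`, `scale_alloc`) of the 20%- and
#' 100%-anchor count patterns; below `knot` each class follows a cubic
#' Hermite blend to the 20% anchor whose left tangent preserves per-capita
#' rates through the anchor (so the contemporary state is an equilibrium)
#' and whose right tangent is the branch slope times `tension`. Defaults
#' were calibrated once against the published landmarks (see the methods
#' vignette) and are not data.
#'
#' @param mid_adult,scale_adult adult per-capita ramp logistic midpoint and
#'   scale (abundance fraction).
#' @param mid_alloc,scale_alloc allocation-pattern logistic midpoint and
#'   scale.
#' @param tension Hermite right-tangent multiplier.
#' @param knot abundance fraction above which consumed mass is held flat.
#' @return A list of constants.
#' @export
sigmoid_params <- function(mid_adult = 0.35, scale_adult = 0.05,
                           mid_alloc = 0.85, scale_alloc = 0.07,
                           tension = 1.0, knot = 0.6) {
  list(mid_adult = mid_adult, scale_adult = scale_adult,
       mid_alloc = mid_alloc, scale_alloc = scale_alloc,
       tension = tension, knot = knot)
}

#' Age-structured numerical-response model
#'
#' Bundles the response kind (`flat`, `linear`, `sigmoid`), the anchors,
#' the mass schedule, the birth rate used for pup production and pregnancy
#' weighting, and the age groupings used in reported metrics.
#'
#' @param kind `"flat"`, `"linear"` or `"sigmoid"`.
#' @param anchors [response_anchors()].
#' @param mass_schedule tibble `sex`, `age_year`, `mass_kg`.
#' @param birth_rate pups (both sexes) per reproductive female per year.
#' @param juvenile_classes age classes counted as juveniles in figure-style
#'   metrics (default 2:4; the 13-60-month study definition is 2:5).
#' @param repro_classes reproductive female classes (ages 5-21).
#' @param preg_mass_kg extra mass carried per pregnant female, weighted by
#'   the pregnancy fraction (= birth rate).
#' @param params [sigmoid_params()].
#' @return A list of class `lhx_response`.
#' @export
response_model <- function(kind = c("sigmoid", "flat", "linear"),
                           anchors = response_anchors(),
                           mass_schedule = mass_schedule_synthetic(),
                           birth_rate = 0.69,
                           juvenile_classes = 2:4,
                           repro_classes = 6:22,
                           preg_mass_kg = 18,
                           params = sigmoid_params()) {
  kind <- match.arg(kind)
  stopifnot(inherits(anchors, "lhx_anchors"))
  assert_fraction(birth_rate, "birth_rate", allow_zero = FALSE)
  mass <- tidyr::pivot_wider(mass_schedule, names_from = "sex",
                             values_from = "mass_kg")
  mass_mat <- cbind(F = mass$female, M = mass$male)
  # reproductive-female mass: mean of pregnant and non-pregnant, weighted
  # by the pregnancy fraction (taken equal to the birth rate)
  mass_mat[repro_classes, "F"] <- mass_mat[repro_classes, "F"] +
    birth_rate * preg_mass_kg
  structure(
    list(kind = kind, anchors = anchors, mass = mass_mat,
         birth_rate = birth_rate, juvenile_classes = juvenile_classes,
         repro_classes = repro_classes, params = params),
    class = "lhx_response"
  )
}

# forward projection: absolute juvenile/pup consumption (classes 1-5),
# per-capita adult rates (classes 6-31), fixed per-capita m_np
project_vectors <- function(seed, Cjv, mpa, m_np) {
  out <- list()
  for (sx in c("F", "M")) {
    n <- numeric(32); n[1] <- seed / 2
    p <- d <- numeric(31)
    for (i in 1:31) {
      d[i] <- n[i] * m_np[i, sx]
      p[i] <- if (i <= 5) min(Cjv[i, sx], max(0, n[i] - d[i]))
              else n[i] * mpa[i, sx]
      n[i + 1] <- n[i] - d[i] - p[i]
    }
    out[[sx]] <- list(n = n[1:31], p = p, d = d, n_end = n[32])
  }
  out
}

# absolute-consumption projection used by flat/linear kinds
project_absolute <- function(seed, C, m_np) {
  out <- list()
  for (sx in c("F", "M")) {
    n <- numeric(32); n[1] <- seed / 2
    p <- d <- numeric(31)
    for (i in 1:31) {
      d[i] <- n[i] * m_np[i, sx]
      p[i] <- min(C[i, sx], max(0, n[i] - d[i]))
      n[i + 1] <- n[i] - d[i] - p[i]
    }
    out[[sx]] <- list(n = n[1:31], p = p, d = d, n_end = n[32])
  }
  out
}

scaled_logistic <- function(x, mid, scale) {
  (plogis((x - mid) / scale) - plogis((0.2 - mid) / scale)) /
    (plogis((1 - mid) / scale) - plogis((0.2 - mid) / scale))
}

# core solver: population state at one abundance fraction
solve_response <- function(model, abundance_frac) {
  a <- abundance_frac
  stopifnot(a > 0, a <= 1)
  an <- model$anchors
  target <- a * an$abundance_100
  M100 <- sum(an$C100 * model$mass) / 1000   # consumed mass at peak, tonnes

  if (model$kind %in% c("flat", "linear")) {
    C <- if (model$kind == "flat" || a <= 0.2) an$C20
         else an$C20 + (a - 0.2) / 0.8 * (an$C100 - an$C20)
    if (a < 0.2) C <- an$C20 * (a / 0.2)
    tot <- function(seed) {
      x <- project_absolute(seed, C, an$m_np)
      sum(x$F$n) + sum(x$M$n)
    }
    seed <- uniroot(function(s) tot(s) - target, c(1e-6, 1e7))$root
    return(list(state = project_absolute(seed, C, an$m_np), seed = seed))
  }

  # sigmoid
  pr <- model$params
  jv <- 1:5; ad <- 6:31
  w_adult <- function(x) scaled_logistic(x, pr$mid_adult, pr$scale_adult)
  alloc <- function(x) {
    u <- scaled_logistic(x, pr$mid_alloc, pr$scale_alloc)
    (1 - u) * an$C20[jv, ] / sum(an$C20[jv, ]) +
      u * an$C100[jv, ] / sum(an$C100[jv, ])
  }
  mpa_at <- function(x) an$mp20 + w_adult(x) * (an$mp100 - an$mp20)
  # mass-balance branch (valid for x >= knot): juvenile+pup consumption
  # absorbs the mass budget left by the standing adult consumption
  branch <- function(x, seed) {
    mpax <- mpa_at(x)
    Cj <- an$C20[jv, ]
    for (it in 1:8) {
      st <- project_vectors(seed, Cj, mpax, an$m_np)
      ad_mass <- sum(st$F$p[ad] * model$mass[ad, "F"] +
                     st$M$p[ad] * model$mass[ad, "M"]) / 1000
      Wt <- alloc(x)
      Cj <- pmax(0, (M100 - ad_mass)) * 1000 * Wt / sum(Wt * model$mass[jv, ])
    }
    Cj
  }
  jv_at <- function(x, seed) {
    if (x <= 0.2) return(an$C20[jv, ] * (x / 0.2))
    if (x >= pr$knot) return(branch(x, seed))
    y1 <- branch(pr$knot, seed)
    m1 <- pr$tension * (branch(pr$knot + 0.005, seed) -
                        branch(pr$knot - 0.005, seed)) / 0.01
    m0 <- an$C20[jv, ] / 0.2      # per-capita continuity through the anchor
    h <- pr$knot - 0.2
    t <- (x - 0.2) / h
    out <- (2 * t^3 - 3 * t^2 + 1) * an$C20[jv, ] +
      (t^3 - 2 * t^2 + t) * h * m0 +
      (-2 * t^3 + 3 * t^2) * y1 +
      (t^3 - t^2) * h * m1
    pmax(out, 0)
  }
  mpa <- mpa_at(a)
  if (a < 0.2) mpa <- an$mp20 * (a / 0.2)
  tot <- function(seed) {
    x <- project_vectors(seed, jv_at(a, seed), mpa, an$m_np)
    sum(x$F$n) + sum(x$M$n)
  }
  seed <- uniroot(function(s) tot(s) - target, c(1e-6, 1e7))$root
  list(state = project_vectors(seed, jv_at(a, seed), mpa, an$m_np),
       seed = seed)
}

#' Consumption vectors at an abundance fraction
#'
#' Per-sex, per-age-year numbers consumed by predators under the model at
#' the given abundance. Flat: the 20%-anchor amounts at every fraction
#' above 0.2. Linear: elementwise linear interpolation between the anchors.
#' Sigmoid: see [sigmoid_params()]. Below 0.2 all kinds scale the 20%
#' anchor proportionally toward zero.
#'
#' @param model [response_model()].
#' @param abundance_frac abundance as a fraction of peak, in (0, 1].
#' @return A tibble: `sex`, `age_year`, `consumed`.
#' @export
consumption_at <- function(model, abundance_frac) {
  sol <- solve_response(model, abundance_frac)
  bind_rows(
    tibble(sex = "female", age_year = 1:31, consumed = sol$state$F$p),
    tibble(sex = "male", age_year = 1:31, consumed = sol$state$M$p)
  )
}

#' Population metrics at an abundance fraction
#'
#' Rebuilds the survivorship schedule from fixed non-predation mortality
#' plus the density-adjusted predation, and computes the comparative
#' metrics: consumed numbers (total and by age group), consumed mass,
#' overall and juvenile survival, pup difference (birth-pulse seed minus
#' actual pup production at the set birth rate; positive values indicate a
#' pup deficit and a declining potential trajectory), female recruitment
#' (fraction of the female seed surviving to the end of year 4), the
#' juvenile predation proportion (classes 2-5) and the juvenile fraction
#' J/T.
#'
#' @inheritParams consumption_at
#' @return A one-row tibble of metrics.
#' @export
metrics_at <- function(model, abundance_frac) {
  sol <- solve_response(model, abundance_frac)
  st <- sol$state
  jvc <- model$juvenile_classes
  adc <- setdiff(2:31, 1:max(jvc))
  nT <- st$F$n + st$M$n
  pT <- st$F$p + st$M$p
  dT <- st$F$d + st$M$d
  s_all <- c(nT[-1], st$F$n_end + st$M$n_end) / nT
  births <- model$birth_rate * sum(st$F$n[model$repro_classes])
  juv_study <- 2:5   # 13-60-month juvenile definition, used for PP
  tibble(
    abundance_frac = abundance_frac,
    seed = sol$seed,
    total_consumed = sum(pT),
    consumed_pups = pT[1],
    consumed_juveniles = sum(pT[jvc]),
    consumed_adults = sum(pT[adc]),
    mass_consumed_t = sum(st$F$p * model$mass[, "F"] +
                          st$M$p * model$mass[, "M"]) / 1000,
    overall_survival = sum(nT * s_all) / sum(nT),
    juvenile_survival = sum(nT[jvc] * s_all[jvc]) / sum(nT[jvc]),
    survival_year2 = s_all[2],
    pp_juvenile = sum(pT[juv_study]) / sum(pT[juv_study] + dT[juv_study]),
    pup_difference = sol$seed - births,
    female_recruitment = st$F$n[5] / st$F$n[1],
    j_over_t = sum(nT[jvc]) / sum(nT[2:31]),
    adult_female_consumed_frac = sum(st$F$p[6:31]) / sum(st$F$n[6:31])
  )
}

#' Sweep the response model across abundance
#'
#' Applies [metrics_at()] over a grid of abundance fractions, producing the
#' data behind the survival/consumption, potential-trajectory and
#' age-structure figures.
#'
#' @param model [response_model()].
#' @param grid abundance fractions in (0, 1].
#' @return A tibble of class `lhx_sweep` (one row per grid point) with a
#'   `kind` attribute.
#' @export
response_sweep <- function(model, grid = seq(0.2, 1, by = 0.02)) {
  stopifnot(all(grid > 0), all(grid <= 1))
  out <- purrr::map_dfr(sort(grid), ~metrics_at(model, .x))
  attr(out, "kind") <- model$kind
  attr(out, "birth_rate") <- model$birth_rate
  class(out) <- c("lhx_sweep", class(out))
  out
}

#' Locate potential-trajectory equilibria in a sweep
#'
#' Finds zero crossings of the pup difference (seed minus births) by sign
#' change with linear interpolation. An equilibrium is stable when the pup
#' difference increases through zero (above it the population runs a pup
#' deficit and declines back; below it a surplus and grows back). Grid
#' points lying exactly on zero are treated as crossings.
#'
#' @param sweep an `lhx_sweep` (or data frame with `abundance_frac` and
#'   `pup_difference`).
#' @param tol zero tolerance relative to the largest absolute pup
#'   difference.
#' @return A tibble: `abundance_frac`, `stable`. Zero rows when no
#'   crossing exists.
#' @export
find_equilibria <- function(sweep, tol = 1e-6) {
  stopifnot(is.data.frame(sweep), nrow(sweep) >= 3,
            all(c("abundance_frac", "pup_difference") %in% names(sweep)))
  a <- sweep$abundance_frac
  pd <- sweep$pup_difference
  eps <- tol * max(abs(pd), 1)
  sgn <- ifelse(abs(pd) <= eps, 0, sign(pd))
  out <- list()
  for (i in seq_len(length(a) - 1)) {
    if (sgn[i] == 0 && sgn[i + 1] != 0 && (i == 1 || sgn[i - 1] != sgn[i + 1])) {
      # grid point exactly at zero
      out[[length(out) + 1]] <- tibble(abundance_frac = a[i],
                                       stable = sgn[i + 1] > 0)
    } else if (sgn[i] != 0 && sgn[i + 1] != 0 && sgn[i] != sgn[i + 1]) {
      x0 <- a[i] - pd[i] * (a[i + 1] - a[i]) / (pd[i + 1] - pd[i])
      out[[length(out) + 1]] <- tibble(abundance_frac = x0,
                                       stable = sgn[i + 1] > 0)
    }
  }
  if (!length(out)) {
    return(tibble(abundance_frac = numeric(0), stable = logical(0)))
  }
  bind_rows(out)
}
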