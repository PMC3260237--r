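#' Vital-rate schedule
#'
#' A vital schedule holds, for one sex and each age-year `i = 1..31`
#' (year 1 covers months 1-12, year 2 months 13-24, and so forth):
#' the annual survival `s` (proportion of animals entering year `i` that
#' survive it), the proportion `pp` of that year's mortality attributed to
#' predation, and the resulting mortality partitions
#' `m_p = (1 - s) * pp` (consumed by predators) and
#' `m_np = (1 - s) * (1 - pp)` (all other causes), so that
#' `s + m_p + m_np = 1` in every row.
#'
#' @param s numeric length 31, annual survival in (0, 1].
#' @param pp numeric length 31 (or scalar), predation share of mortality.
#' @param sex `"female"` or `"male"`.
#'
#' @return A tibble of class `lhx_schedule` with columns
#'   `sex`, `age_year`, `s`, `pp`, `m_p`, `m_np`.
#' @examples
#' sched <- vital_schedule(rep(0.9, 31), pp = 0.5, sex = "female")
#' all.equal(sched$s + sched$m_p + sched$m_np, rep(1, 31))
#' @export
vital_schedule <- function(s, pp = 0, sex = c("female", "male")) {
  sex <- match.arg(sex)
  if (length(s) != 31L) abort("`s` must have length 31 (age-years 1..31)")
  assert_fraction(s, "s", allow_zero = FALSE)
  if (length(pp) == 1L) pp <- rep(pp, 31L)
  if (length(pp) != 31L) abort("`pp` must be scalar or length 31")
  assert_fraction(pp, "pp")
  out <- tibble(
    sex = sex,
    age_year = 1:31,
    s = as.numeric(s),
    pp = as.numeric(pp),
    m_p = (1 - s) * pp,
    m_np = (1 - s) * (1 - pp)
  )
  class(out) <- c("lhx_schedule", class(out))
  out
}

#' Validate a vital schedule
#'
#' Checks the mortality partition identity `s + m_p + m_np = 1` (tolerance
#' 1e-9), the internal consistency `m_p = (1 - s) * pp`, and value ranges.
#' Called by every schedule constructor and mutator.
#'
#' @param schedule a schedule tibble.
#' @return The schedule, invisibly; errors name the offending row.
#' @export
validate_schedule <- function(schedule) {
  stopifnot(is.data.frame(schedule))
  need <- c("sex", "age_year", "s", "pp", "m_p", "m_np")
  if (!all(need %in% names(schedule))) {
    abort(paste("schedule must have columns:", paste(need, collapse = ", ")))
  }
  bad <- which(abs(schedule$s + schedule$m_p + schedule$m_np - 1) > 1e-9)
  if (length(bad)) {
    abort(sprintf("partition identity s + m_p + m_np = 1 violated at age_year %d (sum = %.6f)",
                  schedule$age_year[bad[1]],
                  (schedule$s + schedule$m_p + schedule$m_np)[bad[1]]))
  }
  bad <- which(abs(schedule$m_p - (1 - schedule$s) * schedule$pp) > 1e-9)
  if (length(bad)) {
    abort(sprintf("m_p != (1 - s) * pp at age_year %d", schedule$age_year[bad[1]]))
  }
  assert_fraction(schedule$s, "s", allow_zero = FALSE)
  assert_fraction(schedule$pp, "pp")
  invisible(schedule)
}

#' Read / write a vital schedule as CSV
#'
#' The CSV mirrors the schedule layout: columns `sex`, `age_year`, `s`,
#' `pp`, `m_p`, `m_np`, one row per sex and age-year. Loading validates the
#' partition identity and errors naming the first offending row.
#'
#' @param file path to a schedule CSV.
#' @return `load_schedule()` returns a validated `lhx_schedule` tibble
#'   (possibly both sexes); `write_schedule()` returns `file` invisibly.
#' @examples
#' path <- system.file("extdata", "schedule_hfys06_pp_synthetic.csv",
#'                     package = "lhxdemog")
#' sched <- load_schedule(path)
#' minimum_natality(sched)$value
#' @export
load_schedule <- function(file) {
  x <- readr::read_csv(file, show_col_types = FALSE,
                       col_types = readr::cols(
                         sex = readr::col_character(),
                         .default = readr::col_double()
                       ))
  validate_schedule(x)
  class(x) <- c("lhx_schedule", class(x))
  x
}

#' @rdname load_schedule
#' @param schedule schedule tibble to write.
#' @export
write_schedule <- function(schedule, file) {
  validate_schedule(schedule)
  readr::write_csv(schedule, file)
  invisible(file)
}

# ---------------------------------------------------------------------------
# Packaged base schedules.
#
# The published schedule table for the inferential HFYS model is not
# redistributed here; these are SYNTHETIC reconstructions, calibrated once
# to the published summary anchors and then frozen:
#   * HFYS-06: cumulative survivals 0.72 / 0.67 / 0.61 for ages 13-36 /
#     13-48 / 13-60 months, minimum natality 0.6;
#   * HFYS-Pre: cumulative survivals 0.75 / 0.70 / 0.64, female recruitment
#     (survival to the end of year 4) 51%, adult-female predation fraction
#     3.6% at peak abundance when paired with the contemporary non-predation
#     schedule;
#   * the naive replacement of years 1-5 by the telemetry-based rates gives
#     minimum natality 0.92, which the published 1.13 adult rescaling brings
#     to 0.69.
# Sensitivities of derived quantities to these constants are discussed in
# the methods vignette.
# ---------------------------------------------------------------------------

# frozen calibration constants
.lhx_const <- list(
  hfys06_s1 = 0.8223557,       # first-year survival, HFYS-06 reconstruction
  hfys06_juv = c(sqrt(0.72), sqrt(0.72), 0.67 / 0.72, 0.61 / 0.67),
  adult_base = 0.8614213,      # adult (years 6+) survival embodying the 1.07 scaling
  hfys_pre_s1 = 0.7285714,     # first-year survival, pre-decline reconstruction
  hfys_pre_juv = c(sqrt(0.75), sqrt(0.75), 0.70 / 0.75, 0.64 / 0.70),
  hfys_pre_adult = 0.882,      # pre-decline adult survival
  lhx_pup = 0.667043,          # year-1 survival used in the contemporary schedule
  lhx_juv = c(0.641, 0.829, 1.0, 0.923),  # telemetry-based years 2-5
  male_decay = 0.98025         # male survival ratio r per year beyond year 5
)

#' Base survivorship schedules (synthetic reconstructions)
#'
#' `hfys06_schedule()` is the recent-period schedule of the published
#' inferential model (adult survival already carries its 1.07 scaling);
#' `hfys_pre_schedule()` is the pre-decline schedule. Both are synthetic
#' reconstructions calibrated to published cumulative survivals and
#' natality/recruitment anchors (see the methods vignette), returned with
#' `pp = 0` (no predation attribution) for the requested sex.
#'
#' @param sex `"female"` or `"male"`.
#' @return An `lhx_schedule` tibble.
#' @examples
#' minimum_natality(hfys06_schedule())  # ~0.6
#' @export
hfys06_schedule <- function(sex = "female") {
  k <- .lhx_const
  vital_schedule(c(k$hfys06_s1, k$hfys06_juv, rep(k$adult_base, 26)),
                 pp = 0, sex = sex)
}

#' @rdname hfys06_schedule
#' @export
hfys_pre_schedule <- function(sex = "female") {
  k <- .lhx_const
  vital_schedule(c(k$hfys_pre_s1, k$hfys_pre_juv, rep(k$hfys_pre_adult, 26)),
                 pp = 0, sex = sex)
}

#' Build the contemporary (telemetry-updated) schedule
#'
#' Replaces years 1-5 of a base schedule with recent, location-specific
#' estimates (year 1 from pup-resight literature, years 2-5 from the
#' implanted-transmitter survival analysis), rescales adult survival
#' (years 6+) by `adult_scale / 1.07` relative to the base's published
#' scaling (capped at 1 with a warning), and attaches the predation-share
#' schedule via [set_pp_schedule()].
#'
#' @param base base schedule (default [hfys06_schedule()]).
#' @param lhx_annual annual survival for years 2-5 (length 4).
#' @param pup_rate_year1 year-1 survival.
#' @param adult_scale adult survival scaling factor (the published update
#'   uses 1.13; the base embodies 1.07).
#' @param pp_juvenile juvenile predation proportion attached to the result
#'   (default 0.89, the working PP estimate); use `NA` to skip.
#'
#' @return An `lhx_schedule` tibble.
#' @examples
#' lhx <- build_lhx_egoa()
#' minimum_natality(lhx)  # ~0.69
#' @export
build_lhx_egoa <- function(base = hfys06_schedule(),
                           lhx_annual = .lhx_const$lhx_juv,
                           pup_rate_year1 = .lhx_const$lhx_pup,
                           adult_scale = 1.13,
                           pp_juvenile = 0.89) {
  validate_schedule(base)
  stopifnot(length(lhx_annual) == 4L)
  assert_fraction(lhx_annual, "lhx_annual", allow_zero = FALSE)
  assert_fraction(pup_rate_year1, "pup_rate_year1", allow_zero = FALSE)
  assert_positive(adult_scale, "adult_scale")
  s <- base$s
  s[1] <- pup_rate_year1
  s[2:5] <- lhx_annual
  scaled <- s[6:31] * adult_scale / 1.07
  if (any(scaled > 1)) {
    warn("scaled adult survival exceeds 1; capping at 1")
    scaled <- pmin(scaled, 1)
  }
  s[6:31] <- scaled
  out <- vital_schedule(s, pp = 0, sex = base$sex[1])
  if (!is.na(pp_juvenile)) out <- set_pp_schedule(out, pp_juvenile)
  out
}

#' Attach an age-structured predation-share schedule
#'
#' Young-of-the-year (year 1) receive 30% of the juvenile predation
#' proportion; years 2-5 receive the juvenile value; beyond year 5 the
#' share halves each year (`pp_i = pp_juvenile * 0.5^(i-5)`), reflecting
#' decreasing vulnerability with age and size. Mortality partitions are
#' recomputed.
#'
#' @param schedule an `lhx_schedule` tibble.
#' @param pp_juvenile juvenile predation proportion in `[0, 1]`.
#' @return The schedule with updated `pp`, `m_p`, `m_np`.
#' @examples
#' sched <- set_pp_schedule(hfys06_schedule(), 0.89)
#' sched$pp[c(1, 2, 6, 7)]  # 0.267, 0.89, 0.445, 0.2225
#' @export
set_pp_schedule <- function(schedule, pp_juvenile) {
  validate_schedule(schedule)
  assert_fraction(pp_juvenile, "pp_juvenile")
  i <- schedule$age_year
  pp <- ifelse(i == 1, 0.3 * pp_juvenile,
               ifelse(i <= 5, pp_juvenile, pp_juvenile * 0.5^(i - 5)))
  vital_schedule(schedule$s, pp = pp, sex = schedule$sex[1])
}

#' Derive a male schedule from a female schedule
#'
#' Male survival equals female survival through year 5; beyond that it is a
#' progressively decreasing proportion of the female rate,
#' `s_male_i = s_female_i * r^(i-5)` with a single geometric decay ratio
#' `r`. When `decay_ratio` is `NULL`, `r` is calibrated by bisection so that
#' 95% of males in the stationary age vector fall within age classes
#' 1-`male_p95_class` (default 14, the published male age concentration;
#' the corresponding female value is reported in the `p95` attribute).
#'
#' @param female female `lhx_schedule`.
#' @param decay_ratio geometric ratio `r` in (0, 1]; `NULL` to calibrate.
#' @param male_p95_class target 95th-percentile age class for males.
#' @return Male `lhx_schedule`; attributes `decay_ratio` and `p95`
#'   (achieved male and female 95th-percentile classes).
#' @examples
#' male <- derive_male_schedule(build_lhx_egoa())
#' attr(male, "decay_ratio")
#' @export
derive_male_schedule <- function(female, decay_ratio = NULL,
                                 male_p95_class = 14L) {
  validate_schedule(female)
  p95_class <- function(s) {
    l <- cumprod(c(1, s))[1:31]
    min(which(cumsum(l) / sum(l) >= 0.95))
  }
  male_s <- function(r) {
    s <- female$s
    i <- 6:31
    s[i] <- s[i] * r^(i - 5)
    s
  }
  if (is.null(decay_ratio)) {
    # bisection on the (step-valued) percentile: find the midpoint of the
    # interval of r whose male 95th percentile equals the target
    f <- function(r) p95_class(male_s(r))
    rs <- seq(0.5, 1, by = 5e-4)
    hit <- vapply(rs, f, integer(1)) == male_p95_class
    if (!any(hit)) {
      ach <- range(vapply(rs, f, integer(1)))
      abort(sprintf("male decay calibration failed: achieved 95th-percentile classes %d-%d, target %d",
                    ach[1], ach[2], male_p95_class))
    }
    decay_ratio <- mean(range(rs[hit]))
  }
  assert_fraction(decay_ratio, "decay_ratio", allow_zero = FALSE)
  out <- vital_schedule(male_s(decay_ratio), pp = female$pp, sex = "male")
  attr(out, "decay_ratio") <- decay_ratio
  attr(out, "p95") <- c(male = p95_class(out$s), female = p95_class(female$s))
  out
}

# survivorship to the start of each year (l_1 = 1)
survivorship <- function(schedule) cumprod(c(1, schedule$s))[1:31]

#' Minimum natality of a female schedule
#'
#' The birth rate that exactly balances a survivorship schedule in a
#' stationary population: the pup seed count (both sexes, 1:1 sex ratio)
#' divided by the number of females of reproductive age. Reproductive age
#' spans ages 5-21 years inclusive, i.e. age classes 6-22 (class `i` covers
#' ages `i-1` to `i`). With a unit seed this equals
#' `2 / sum(l_i, i = 6..22)` where `l_i` is survivorship to the start of
#' class `i`; the value is invariant to the seed and to the male schedule.
#'
#' @param female female `lhx_schedule`.
#' @param repro_classes age classes counted as reproductive (default 6:22).
#' @return A list with `value` and `repro_ages` (in years, 5-21).
#' @examples
#' minimum_natality(hfys06_schedule())$value  # ~0.6
#' @export
minimum_natality <- function(female, repro_classes = 6:22) {
  validate_schedule(female)
  l <- survivorship(female)
  denom <- sum(l[repro_classes])
  if (denom <= 0) abort("no surviving reproductive females: natality undefined")
  list(value = 2 / denom,
       repro_ages = range(repro_classes) - 1L)
}

#' Population, predation and non-predation vectors from a birth pulse
#'
#' Projects a pup seed (both sexes, 1:1 at birth) through the sex-specific
#' schedules: `n_i` animals enter age class `i`, `p_i = n_i * m_p_i` are
#' consumed by predators during the class and `d_i = n_i * m_np_i` die of
#' other causes. Class 31 is closed (all entrants die within it, partitioned
#' by `pp_31`), so deaths conserve the seed exactly.
#'
#' @param female,male `lhx_schedule` tibbles.
#' @param seed pup count at the birth pulse (both sexes).
#' @return A tibble with columns `sex`, `age_year`, `n`, `p`, `d`.
#' @examples
#' lhx <- build_lhx_egoa()
#' vec <- population_vectors(lhx, derive_male_schedule(lhx), seed = 1000)
#' sum(vec$p + vec$d)  # 1000: the seed is conserved
#' @export
population_vectors <- function(female, male, seed) {
  assert_positive(seed, "seed")
  one_sex <- function(sched) {
    l <- survivorship(sched)
    n <- seed / 2 * l
    p <- n * sched$m_p
    d <- n * sched$m_np
    # closed terminal class: survivors of year 31 are folded into deaths
    surv31 <- n[31] * sched$s[31]
    p[31] <- p[31] + surv31 * sched$pp[31]
    d[31] <- d[31] + surv31 * (1 - sched$pp[31])
    tibble(sex = sched$sex[1], age_year = 1:31, n = n, p = p, d = d)
  }
  bind_rows(one_sex(female), one_sex(male))
}

#' Pup seed count matching a target total abundance
#'
#' The stationary population total is linear in the seed, so the seed
#' placing the both-sex population vector sum at `target_total` is solved
#' exactly.
#'
#' @param female,male `lhx_schedule` tibbles.
#' @param target_total target both-sex population vector sum.
#' @return The seed (pups per birth pulse).
#' @examples
#' lhx <- build_lhx_egoa()
#' calibrate_seed(lhx, derive_male_schedule(lhx), 36000)
#' @export
calibrate_seed <- function(female, male, target_total) {
  if (target_total == 0) return(0)
  assert_positive(target_total, "target_total")
  per_unit <- (sum(survivorship(female)) + sum(survivorship(male))) / 2
  target_total / per_unit
}
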