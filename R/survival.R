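#' Bin an exposure ledger into age-class exposure days
#'
#' Each ledger row is one animal's exposure interval in months of age.
#' `entry_age_months` is the (1-based, integer) month of age in which
#' exposure starts; `exit_age_months` is the continuous age in months at
#' death or censoring, where an integer value means the end of that month.
#' An animal entering at month 13 and censored at exit 24 therefore
#' contributes twelve months (~365.25 days) to the 13-24-month class, and
#' a death during month 49 has an exit in (48, 49]. Months convert to days
#' at 365.25/12; mortality events are assigned to the class containing the
#' exit month.
#'
#' @param ledger data frame with columns `animal_id`, `sex`,
#'   `entry_age_months`, `exit_age_months`, `fate` (`"died"` or
#'   `"censored"`); an `event_id` column is carried through if present.
#' @param bounds increasing integer month cut points; class `k` covers
#'   months `[bounds[k], bounds[k+1] - 1]` (e.g. `c(13, 25, 37, 49, 61)`
#'   gives the four juvenile year classes 13-24, ..., 49-60).
#'
#' @return A tibble with one row per age class: `age_lo`, `age_hi` (months),
#'   `n_animals`, `d_exp` (exposure days), `n_events` (detected deaths).
#' @examples
#' ledger <- tibble::tibble(animal_id = "a", sex = "m",
#'   entry_age_months = 13, exit_age_months = 24, fate = "censored")
#' bin_exposure(ledger, c(13, 25, 37, 49, 61))
#' @export
bin_exposure <- function(ledger, bounds = c(13, 25, 37, 49, 61)) {
  stopifnot(is.data.frame(ledger))
  need <- c("animal_id", "sex", "entry_age_months", "exit_age_months", "fate")
  if (!all(need %in% names(ledger))) {
    abort(paste("ledger must have columns:", paste(need, collapse = ", ")))
  }
  if (length(bounds) < 2 || any(diff(bounds) <= 0)) {
    abort("`bounds` must be at least two increasing cut points")
  }
  if (!all(ledger$fate %in% c("died", "censored"))) {
    abort("`fate` must be 'died' or 'censored'")
  }
  bad <- ledger$exit_age_months < ledger$entry_age_months - 1
  if (any(bad)) {
    abort(sprintf("exit before entry for animal %s", ledger$animal_id[which(bad)[1]]))
  }
  n_class <- length(bounds) - 1L
  purrr::map_dfr(seq_len(n_class), function(k) {
    lo <- bounds[k]
    hi <- bounds[k + 1] - 1L
    # overlap of the age interval (entry - 1, exit] with (lo - 1, hi]
    ov <- pmax(0, pmin(ledger$exit_age_months, hi) -
                  pmax(ledger$entry_age_months - 1, lo - 1))
    died_here <- ledger$fate == "died" &
      ledger$exit_age_months > lo - 1 & ledger$exit_age_months <= hi
    tibble(
      age_lo = lo, age_hi = hi,
      n_animals = sum(ov > 0),
      d_exp = sum(ov) * DAYS_PER_MONTH,
      n_events = sum(died_here)
    )
  })
}

#' Mayfield annual (or period) survival from events and exposure days
#'
#' The daily mortality rate is the (corrected) event count divided by the
#' cumulative exposure days, `DMR = E / d_exp`; the daily survival rate is
#' `DSR = 1 - DMR`, and survival over a period is `DSR^period_days`
#' (365.25 for annual rates).
#'
#' @param e_count mortality events attributed to the class (may be a
#'   corrected, non-integer count).
#' @param d_exp cumulative exposure days (> 0).
#' @param period_days period length in days.
#' @return A one-row tibble: `dmr`, `dsr`, `period_days`, `period_survival`.
#' @examples
#' annual_survival(7, 5757)$period_survival  # 0.641
#' @export
annual_survival <- function(e_count, d_exp, period_days = 365.25) {
  if (!is.finite(d_exp) || d_exp <= 0) {
    abort("`d_exp` must be positive: daily mortality rate undefined")
  }
  stopifnot(e_count >= 0, e_count <= d_exp)
  dmr <- e_count / d_exp
  tibble(
    dmr = dmr,
    dsr = 1 - dmr,
    period_days = period_days,
    period_survival = (1 - dmr)^period_days
  )
}

#' Johnson variance confidence interval for a Mayfield survival rate
#'
#' The daily survival rate variance is
#' `var(DSR) = e (d_exp - e) / d_exp^3`; the period-scale standard error
#' follows by the delta method,
#' `SE = period_days * DSR^(period_days - 1) * se(DSR)`, and a normal
#' interval is truncated to `[0, 1]`. With zero events the point estimate
#' and upper limit are 1 and the lower limit comes from the one-sided
#' exact construction (the event count whose one-sided tail is `alpha`,
#' `-log(alpha)` expected events).
#'
#' @inheritParams annual_survival
#' @param alpha two-sided error level (0.05 for 95% limits).
#' @return A one-row tibble: `lo`, `hi`, `se_period`.
#' @examples
#' johnson_ci(7, 5757)
#' @export
johnson_ci <- function(e_count, d_exp, period_days = 365.25, alpha = 0.05) {
  if (!is.finite(d_exp) || d_exp <= 0) abort("`d_exp` must be positive")
  if (e_count == 0) {
    dmr_up <- -log(alpha) / d_exp
    return(tibble(lo = max(0, (1 - dmr_up)^period_days), hi = 1,
                  se_period = 0))
  }
  dsr <- 1 - e_count / d_exp
  var_dsr <- e_count * (d_exp - e_count) / d_exp^3
  se_p <- period_days * dsr^(period_days - 1) * sqrt(var_dsr)
  point <- dsr^period_days
  z <- qnorm(1 - alpha / 2)
  tibble(
    lo = max(0, point - z * se_p),
    hi = min(1, point + z * se_p),
    se_period = se_p
  )
}

#' Lower survival confidence limit adjusted for undetected events
#'
#' The Johnson interval ignores the uncertainty in the detection-corrected
#' event count. Following the published procedure, the lower survival limit
#' is recomputed with the event count set to the upper confidence limit of
#' `E_corr`; each added (undetected) event also removes half a period of
#' exposure (death at the interval midpoint, the standard Mayfield
#' convention). The upper survival limit is unchanged.
#'
#' @param e_detected detected events in the class.
#' @param e_upper upper-limit event count (>= `e_detected`).
#' @inheritParams johnson_ci
#' @return The adjusted lower limit (scalar).
#' @examples
#' pfail_adjusted_lower_cl(7, 8, 5757)  # < johnson_ci(7, 5757)$lo
#' @export
pfail_adjusted_lower_cl <- function(e_detected, e_upper, d_exp,
                                    period_days = 365.25, alpha = 0.05) {
  if (e_upper < e_detected) abort("`e_upper` must be >= `e_detected`")
  extra <- e_upper - e_detected
  d_adj <- d_exp - extra * period_days / 2
  if (d_adj <= e_upper) abort("adjusted exposure too small for the event count")
  johnson_ci(e_upper, d_adj, period_days, alpha)$lo
}

#' Cumulative survival across contiguous age classes
#'
#' The point estimate is the product of the class period survivals; interval
#' limits are combined by the product convention (product of class-level
#' limits).
#'
#' @param estimates data frame with columns `period_survival`, `lo`, `hi`
#'   (one row per contiguous class, in age order).
#' @return A one-row tibble: `period_survival`, `lo`, `hi`.
#' @examples
#' est <- tibble::tibble(period_survival = c(0.641, 0.829),
#'                       lo = c(0.43, 0.68), hi = c(0.85, 0.98))
#' cumulative_survival(est)
#' @export
cumulative_survival <- function(estimates) {
  stopifnot(is.data.frame(estimates), nrow(estimates) >= 1,
            "period_survival" %in% names(estimates))
  lo <- if ("lo" %in% names(estimates)) prod(estimates$lo) else NA_real_
  hi <- if ("hi" %in% names(estimates)) prod(estimates$hi) else NA_real_
  tibble(
    period_survival = prod(estimates$period_survival),
    lo = lo,
    hi = hi
  )
}

#' Full age-class survival table from binned exposure
#'
#' Runs the Mayfield estimator for every age class of a binned exposure
#' table, applies the detection correction factor to the event counts,
#' allocates the extra events implied by the upper `E_corr` limit (to the
#' class with the most exposure among classes with at least one detected
#' event, by default), and assembles annual and cumulative rows with
#' Johnson intervals and failure-adjusted lower limits.
#'
#' @param exposure tibble from [bin_exposure()].
#' @param f_correction detection correction factor `F` (default 1).
#' @param e_corr_upper upper confidence limit for the total corrected event
#'   count (default: the detected total, i.e. no adjustment).
#' @param period_days annualisation exponent in days (365.25; 365 matches
#'   some published roundings).
#' @param alpha two-sided error level.
#' @param allocate_extra `"max_exposure"` (default) or an integer vector of
#'   per-class extra events summing to `e_corr_upper - total detected`.
#' @return A tibble with one row per age class plus cumulative rows
#'   (`age_lo` to `age_hi` spanning the accumulated range), columns
#'   `d_exp`, `n_events`, `e_corr`, `period_survival`, `lo`, `hi`,
#'   `lo_adjusted`, `cumulative`.
#' @export
survival_table <- function(exposure, f_correction = 1,
                           e_corr_upper = NULL, period_days = 365.25,
                           alpha = 0.05, allocate_extra = "max_exposure") {
  stopifnot(is.data.frame(exposure),
            all(c("age_lo", "age_hi", "d_exp", "n_events") %in% names(exposure)))
  n_detected <- sum(exposure$n_events)
  e_corr_upper <- e_corr_upper %||% n_detected
  n_extra <- max(0L, as.integer(round(e_corr_upper - n_detected)))
  extra <- integer(nrow(exposure))
  if (n_extra > 0) {
    if (identical(allocate_extra, "max_exposure")) {
      eligible <- which(exposure$n_events >= 1)
      if (!length(eligible)) eligible <- seq_len(nrow(exposure))
      target <- eligible[which.max(exposure$d_exp[eligible])]
      extra[target] <- n_extra
    } else {
      stopifnot(length(allocate_extra) == nrow(exposure),
                sum(allocate_extra) == n_extra)
      extra <- as.integer(allocate_extra)
    }
  }
  rows <- purrr::map_dfr(seq_len(nrow(exposure)), function(k) {
    e_corr <- exposure$n_events[k] * f_correction
    # animals cannot die in fractions: rates use the integer portion
    e_used <- floor(e_corr)
    d <- exposure$d_exp[k]
    if (d <= 0) {
      return(tibble(age_lo = exposure$age_lo[k], age_hi = exposure$age_hi[k],
                    d_exp = d, n_events = exposure$n_events[k],
                    e_corr = e_corr, period_survival = NA_real_,
                    lo = NA_real_, hi = NA_real_, lo_adjusted = NA_real_,
                    cumulative = FALSE))
    }
    pt <- annual_survival(e_used, d, period_days)
    ci <- johnson_ci(e_used, d, period_days, alpha)
    lo_adj <- pfail_adjusted_lower_cl(e_used, e_used + extra[k],
                                      d, period_days, alpha)
    tibble(age_lo = exposure$age_lo[k], age_hi = exposure$age_hi[k],
           d_exp = d, n_events = exposure$n_events[k], e_corr = e_corr,
           period_survival = pt$period_survival,
           lo = ci$lo, hi = ci$hi, lo_adjusted = min(lo_adj, ci$lo),
           cumulative = FALSE)
  })
  cum <- purrr::map_dfr(2:nrow(rows), function(k) {
    part <- rows[1:k, ]
    tibble(age_lo = part$age_lo[1], age_hi = part$age_hi[k],
           d_exp = sum(part$d_exp), n_events = sum(part$n_events),
           e_corr = sum(part$e_corr),
           period_survival = prod(part$period_survival),
           lo = prod(part$lo), hi = prod(part$hi),
           lo_adjusted = prod(part$lo_adjusted),
           cumulative = TRUE)
  })
  bind_rows(rows, cum)
}
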