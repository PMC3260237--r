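#' Tag-return count table
#'
#' Builds the single/dual data-return tally used to estimate the per-tag
#' uplink failure probability. Each row is one stratum of dual-tag
#' deployments (e.g. live animals vs. carcass tests), with the number of
#' detected mortality events that produced a single return (one of the two
#' tags uplinked) versus a dual return (both tags uplinked).
#'
#' @param stratum character label per row (e.g. `"live"`, `"carcass"`).
#' @param n_single detected events with exactly one tag uplinking.
#' @param n_dual detected events with both tags uplinking.
#'
#' @return A tibble with columns `stratum`, `n_single`, `n_dual`.
#' @examples
#' return_counts(c("live", "carcass"), n_single = c(3, 1), n_dual = c(9, 8))
#' @export
return_counts <- function(stratum, n_single, n_dual) {
  assert_count(n_single, "n_single")
  assert_count(n_dual, "n_dual")
  tibble(stratum = as.character(stratum),
         n_single = as.integer(n_single),
         n_dual = as.integer(n_dual))
}

#' Estimate per-tag uplink failure and event detection probability
#'
#' For dual-implanted animals the per-tag uplink failure probability is
#' estimated from the ratio of single to dual data returns,
#' `P_fail = C_single / (C_single + 2 C_dual)`: each dual return contributes
#' two successful tags, each single return one success and one failure.
#' Under independent per-tag failures the probability that a mortality event
#' is detected at all is `P_detect = 1 - P_fail^2`, and detected event
#' counts are inflated by the correction factor `F = 1 / P_detect`.
#'
#' Multiple strata are pooled (summed) before estimation; use
#' [odds_ratio()] / [fisher_exact_two_tailed()] to check stratum
#' homogeneity first.
#'
#' @param counts a tibble from [return_counts()] (or any data frame with
#'   `n_single` and `n_dual` columns).
#'
#' @return An object of class `lhx_detection`: a list with elements
#'   `n_single`, `n_dual`, `p_fail`, `p_detect`, `f_correction` and a
#'   `degenerate` flag (`TRUE` when no dual returns were observed, in which
#'   case `F` is undefined).
#' @examples
#' counts <- return_counts(c("live", "carcass"), c(3, 1), c(9, 8))
#' estimate_pfail(counts)
#' @export
estimate_pfail <- function(counts) {
  stopifnot(is.data.frame(counts),
            all(c("n_single", "n_dual") %in% names(counts)))
  ns <- sum(counts$n_single)
  nd <- sum(counts$n_dual)
  if (ns + nd < 1) {
    abort("cannot estimate P_fail from all-zero return counts")
  }
  p_fail <- ns / (ns + 2 * nd)
  degenerate <- nd == 0 && ns > 0
  p_detect <- 1 - p_fail^2
  structure(
    list(
      n_single = ns,
      n_dual = nd,
      p_fail = p_fail,
      p_detect = p_detect,
      f_correction = if (degenerate) NA_real_ else 1 / p_detect,
      degenerate = degenerate
    ),
    class = "lhx_detection"
  )
}

#' @export
print.lhx_detection <- function(x, ...) {
  cat("Tag uplink failure estimate (", x$n_single, " single / ",
      x$n_dual, " dual returns)\n", sep = "")
  cat(sprintf("  P_fail   = %.4f\n", x$p_fail))
  cat(sprintf("  P_detect = %.4f\n", x$p_detect))
  if (x$degenerate) {
    cat("  F        = undefined (no dual returns; P_fail = 1)\n")
  } else {
    cat(sprintf("  F        = %.4f\n", x$f_correction))
  }
  invisible(x)
}

#' Correct a detected mortality count for undetected events
#'
#' Inflates the detected event count by the detection correction factor,
#' `E_corr = F * detected`. Because animals do not die in fractions, the
#' integer portion (floor) of `E_corr` is what downstream survival
#' estimation uses.
#'
#' @param detected_events number of detected mortality events.
#' @param est an `lhx_detection` object from [estimate_pfail()], or a
#'   numeric correction factor `F`.
#'
#' @return A list with `e_corr` (real) and `e_corr_integer` (floor).
#' @examples
#' est <- estimate_pfail(return_counts("pooled", 4, 17))
#' correct_event_count(12, est)
#' @export
correct_event_count <- function(detected_events, est) {
  assert_count(detected_events, "detected_events")
  f <- if (inherits(est, "lhx_detection")) est$f_correction else as.numeric(est)
  if (!is.finite(f) || f < 1) {
    abort("correction factor F is undefined or < 1")
  }
  e_corr <- f * detected_events
  list(e_corr = e_corr, e_corr_integer = as.integer(floor(e_corr)))
}

#' Monte Carlo confidence range for P_fail and the corrected event count
#'
#' Inverts the per-tag failure process: for each candidate failure
#' probability on a grid over (0, 1), the observed number of dual-tag
#' detected events is re-simulated (`iterations` times) and the candidate is
#' accepted when the observed single-return count falls inside the central
#' 95% of its simulated distribution. Conditional on detection, a detected
#' dual-deployment event is a single return with probability
#' `2p(1-p) / (1-p^2) = 2p / (1+p)`. The accepted range of `p` is then
#' propagated through `F = 1/(1-p^2)` to an outward-rounded integer interval
#' for the corrected event count.
#'
#' @param counts tibble of [return_counts()]; strata are pooled.
#' @param detected_events detected mortality count to which the correction
#'   is applied (defaults to the pooled detected events in `counts`).
#' @param iterations Monte Carlo iterations per candidate (>= 2500 for the
#'   headline analysis).
#' @param grid_step spacing of the candidate grid over (0, 1).
#' @param conf central coverage used for acceptance.
#' @param rng_seed integer seed.
#'
#' @return A list with `p_fail_ci95` (numeric length 2), `e_corr_ci95`
#'   (integer length 2) and `p_detect_ci95`.
#' @examples
#' counts <- return_counts(c("live", "carcass"), c(3, 1), c(9, 8))
#' mc_pfail_ci(counts, detected_events = 12, iterations = 2500, rng_seed = 1)
#' @export
mc_pfail_ci <- function(counts, detected_events = NULL, iterations = 2500,
                        grid_step = 0.0025, conf = 0.95, rng_seed = 1) {
  stopifnot(iterations >= 1)
  est <- estimate_pfail(counts)
  if (est$degenerate) {
    abort("degenerate counts (no dual returns): P_fail interval is undefined")
  }
  n_events <- est$n_single + est$n_dual
  detected_events <- detected_events %||% n_events
  set.seed(rng_seed)
  alpha <- (1 - conf) / 2
  grid <- seq(grid_step, 1 - grid_step, by = grid_step)
  accepted <- vapply(grid, function(p) {
    q <- 2 * p / (1 + p)
    singles <- rbinom(iterations, n_events, q)
    lo <- quantile(singles, alpha, names = FALSE, type = 1)
    hi <- quantile(singles, 1 - alpha, names = FALSE, type = 1)
    est$n_single >= lo && est$n_single <= hi
  }, logical(1))
  if (!any(accepted)) {
    abort("no candidate P_fail value consistent with the observed split")
  }
  p_lo <- if (accepted[1]) 0 else min(grid[accepted])
  p_hi <- max(grid[accepted])
  f_hi <- 1 / (1 - p_hi^2)
  list(
    p_fail_ci95 = c(p_lo, p_hi),
    p_detect_ci95 = c(1 - p_hi^2, 1 - p_lo^2),
    e_corr_ci95 = c(
      as.integer(floor(detected_events / (1 - p_lo^2))),
      as.integer(ceiling(f_hi * detected_events))
    )
  )
}

#' Odds ratio of a 2x2 table
#'
#' `(a/b) / (c/d)` for rows `(a, b)` and `(c, d)`. Used to compare
#' single/dual return splits between strata (live vs. carcass deployments,
#' predation vs. non-traumatic events).
#'
#' @param table 2x2 matrix or length-4 vector (row-wise).
#'
#' @return The odds ratio; `NaN` with a warning when a denominator is zero.
#' @examples
#' odds_ratio(matrix(c(3, 9, 1, 8), 2, byrow = TRUE)) # 2.67
#' @export
odds_ratio <- function(table) {
  m <- as_table_2x2(table)
  if (m[1, 2] == 0 || m[2, 2] == 0 || m[2, 1] == 0) {
    warn("odds ratio undefined: zero denominator cell")
    return(NaN)
  }
  (m[1, 1] / m[1, 2]) / (m[2, 1] / m[2, 2])
}

#' Two-tailed Fisher exact probability of a 2x2 table
#'
#' Enumerates the full hypergeometric support with the table margins fixed
#' and sums the probabilities of all tables whose point probability does not
#' exceed that of the observed table (the minimum-likelihood two-tailed
#' construction, as in [stats::fisher.test()]).
#'
#' @param table 2x2 matrix or length-4 vector (row-wise).
#'
#' @return Two-tailed p-value.
#' @examples
#' fisher_exact_two_tailed(matrix(c(3, 9, 1, 8), 2, byrow = TRUE)) # ~0.60
#' @export
fisher_exact_two_tailed <- function(table) {
  m <- as_table_2x2(table)
  row1 <- sum(m[1, ])
  col1 <- sum(m[, 1])
  total <- sum(m)
  support <- max(0, col1 - (total - row1)):min(row1, col1)
  probs <- dhyper(support, row1, total - row1, col1)
  p_obs <- dhyper(m[1, 1], row1, total - row1, col1)
  # tolerance guards against ties lost to floating point
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
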