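#' Read pipeline input files
#'
#' Small plain-text formats tie the stages together: return counts and
#' exposure ledgers travel as CSV, mortality-event records as JSON lines
#' with embedded temperature/medium arrays.
#'
#' @param file path.
#' @return `read_return_counts()`: a [return_counts()] tibble.
#'   `read_exposure_ledger()`: a ledger tibble for [bin_exposure()].
#'   `read_events_jsonl()`: a list of event profiles for
#'   [classify_events()]. `write_events_jsonl()` writes the latter format.
#' @export
read_return_counts <- function(file) {
  x <- readr::read_csv(file, show_col_types = FALSE)
  return_counts(x$stratum, x$n_single, x$n_dual)
}

#' @rdname read_return_counts
#' @export
read_exposure_ledger <- function(file) {
  x <- readr::read_csv(file, show_col_types = FALSE,
                       col_types = readr::cols(
                         animal_id = readr::col_character(),
                         sex = readr::col_character(),
                         fate = readr::col_character(),
                         event_id = readr::col_character(),
                         .default = readr::col_double()
                       ))
  if (!"event_id" %in% names(x)) x$event_id <- NA_character_
  x
}

#' @rdname read_return_counts
#' @param events list of event profiles to serialise.
#' @export
write_events_jsonl <- function(events, file) {
  lines <- vapply(events, function(ev) {
    jsonlite::toJSON(list(
      event_id = ev$event_id %||% NA_character_,
      age_at_death_months = ev$age_at_death_months %||% NA_real_,
      ambient_c = ev$ambient_c,
      expected_mass_kg = ev$expected_mass_kg,
      transmission_delay_h = ev$transmission_delay_h,
      extrusion_delay_h = ev$extrusion_delay_h,
      time_h = ev$temp_series$time_h,
      temp_c = ev$temp_series$temp_c,
      medium_time_h = ev$medium_series$time_h,
      medium = ev$medium_series$medium
    ), auto_unbox = TRUE, digits = 6, na = "null")
  }, character(1))
  writeLines(lines, file)
  invisible(file)
}

#' @rdname read_return_counts
#' @export
read_events_jsonl <- function(file) {
  purrr::map(readLines(file), function(line) {
    x <- jsonlite::fromJSON(line)
    structure(
      list(
        event_id = x$event_id,
        age_at_death_months = x$age_at_death_months,
        ambient_c = x$ambient_c,
        expected_mass_kg = x$expected_mass_kg,
        transmission_delay_h = x$transmission_delay_h,
        extrusion_delay_h = x$extrusion_delay_h,
        temp_series = tibble(time_h = x$time_h, temp_c = x$temp_c),
        medium_series = tibble(time_h = x$medium_time_h, medium = x$medium)
      ),
      class = "lhx_event_profile"
    )
  })
}

#' Run the full analysis pipeline
#'
#' Sequences the stages in analysis order: detection correction from the
#' return counts; cause-of-mortality classification (or a pre-classified
#' cause table); Mayfield survival by age class with detection-adjusted
#' limits; contemporary schedule construction and minimum natality; and
#' the numerical-response sweep. All randomness is governed by `rng_seed`.
#'
#' @param counts [return_counts()] tibble (default: the study tallies).
#' @param ledger exposure ledger (default: the study reconstruction).
#' @param events list of event profiles to classify, or `NULL` to use
#'   `causes` directly.
#' @param causes data frame with a `cause` column (used when `events` is
#'   `NULL`).
#' @param detected_events detected mortality count for the correction.
#' @param response_kinds response types to sweep.
#' @param grid abundance grid for the sweeps.
#' @param mc_iterations Monte Carlo iterations for interval estimates.
#' @param rng_seed integer seed recorded in the report.
#' @param period_days annualisation exponent (days).
#'
#' @return A list of class `lhx_report`: `detection` (estimate plus
#'   intervals), `classification`, `pp`, `survival` (Table-1-shaped),
#'   `natality`, `sweeps` (named list of `lhx_sweep`), `equilibria`,
#'   `provenance`.
#' @examples
#' \donttest{
#' rep <- run_pipeline(grid = seq(0.2, 1, 0.1))
#' rep$survival
#' }
#' @export
run_pipeline <- function(counts = egoa_return_counts(),
                         ledger = egoa_exposure_ledger(),
                         events = NULL,
                         causes = egoa_cause_summary(),
                         detected_events = NULL,
                         response_kinds = c("flat", "linear", "sigmoid"),
                         grid = seq(0.2, 1, by = 0.02),
                         mc_iterations = 10000,
                         rng_seed = 1,
                         period_days = 365.25) {
  # --- detection ---------------------------------------------------------
  est <- estimate_pfail(counts)
  exposure <- bin_exposure(ledger)
  detected_events <- detected_events %||% sum(exposure$n_events)
  corr <- correct_event_count(detected_events, est)
  ci <- mc_pfail_ci(counts, detected_events,
                    iterations = max(2500, mc_iterations %/% 4),
                    rng_seed = rng_seed)
  detection <- list(estimate = est, e_corr = corr, intervals = ci)

  # --- classification ----------------------------------------------------
  classification <- if (!is.null(events)) classify_events(events) else causes
  pp <- tryCatch(
    estimate_pp(classification, iterations = mc_iterations,
                rng_seed = rng_seed),
    error = function(e) NULL
  )
  # with no classifiable events PP is undefined; the schedule stage falls
  # back to the default working value
  pp_working <- if (is.null(pp)) 0.89 else pp$pp_working

  # --- survival ----------------------------------------------------------
  surv <- survival_table(exposure, f_correction = est$f_correction,
                         e_corr_upper = ci$e_corr_ci95[2],
                         period_days = period_days)

  # --- schedules ---------------------------------------------------------
  lhx_f <- build_lhx_egoa(pp_juvenile = pp_working)
  lhx_m <- derive_male_schedule(lhx_f)
  natality <- tibble(
    schedule = c("HFYS-06", "LHX-eGOA"),
    minimum_natality = c(minimum_natality(hfys06_schedule())$value,
                         minimum_natality(lhx_f)$value)
  )

  # --- response ----------------------------------------------------------
  anchors <- response_anchors(lhx_f, lhx_m)
  sweeps <- lapply(setNames(response_kinds, response_kinds), function(k) {
    response_sweep(response_model(k, anchors), grid = grid)
  })
  equilibria <- purrr::map_dfr(names(sweeps), function(k) {
    eq <- find_equilibria(sweeps[[k]])
    if (nrow(eq)) eq$kind <- k else eq$kind <- character(0)
    eq
  })

  structure(
    list(detection = detection, classification = classification, pp = pp,
         survival = surv, natality = natality, sweeps = sweeps,
         equilibria = equilibria,
         provenance = list(rng_seed = rng_seed,
                           pp_undefined = is.null(pp),
                           mc_iterations = mc_iterations,
                           period_days = period_days,
                           timestamp = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                           package_version = as.character(utils::packageVersion("lhxdemog")))),
    class = "lhx_report"
  )
}

#' Write a pipeline report to disk
#'
#' Emits CSV tables (survival, natality, per-kind sweeps, equilibria,
#' classification) and a plain-text summary with the detection block and
#' provenance (seed, iteration counts, package version).
#'
#' @param report `lhx_report` from [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @return The paths written, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "lhx_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(x, name) {
    p <- file.path(out_dir, name)
    readr::write_csv(x, p)
    paths <<- c(paths, p)
  }
  wr(report$survival, "survival_table.csv")
  wr(report$natality, "natality.csv")
  wr(as_tibble(report$classification), "classification.csv")
  for (k in names(report$sweeps)) {
    wr(as_tibble(report$sweeps[[k]]), paste0("sweep_", k, ".csv"))
  }
  wr(report$equilibria, "equilibria.csv")
  summary_path <- file.path(out_dir, "summary.txt")
  con <- file(summary_path, "w")
  on.exit(close(con))
  est <- report$detection$estimate
  writeLines(c(
    "Implanted-transmitter survival and predation analysis",
    sprintf("seed: %d  mc_iterations: %d  period_days: %s  version: %s",
            report$provenance$rng_seed, report$provenance$mc_iterations,
            format(report$provenance$period_days),
            report$provenance$package_version),
    "",
    sprintf("P_fail = %.4f  P_detect = %.4f  F = %.4f",
            est$p_fail, est$p_detect, est$f_correction),
    sprintf("E_corr = %.2f (integer %d; 95%% c.i. %d-%d)",
            report$detection$e_corr$e_corr,
            report$detection$e_corr$e_corr_integer,
            report$detection$intervals$e_corr_ci95[1],
            report$detection$intervals$e_corr_ci95[2]),
    if (is.null(report$pp)) "PP undefined (no classifiable events)" else
      sprintf("PP >= %.3f (lower 95%% CL %.2f, working %.2f)",
              report$pp$pp_point, report$pp$pp_lower_cl95, report$pp$pp_working)
  ), con)
  paths <- c(paths, summary_path)
  invisible(paths)
}
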