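#' Tidy a detection estimate
#'
#' @param x an `lhx_detection` object.
#' @param ... unused.
#' @return One row per quantity: `term`, `estimate`.
#' @export
tidy.lhx_detection <- function(x, ...) {
  tibble(
    term = c("p_fail", "p_detect", "f_correction"),
    estimate = c(x$p_fail, x$p_detect, x$f_correction)
  )
}

#' @rdname tidy.lhx_detection
#' @export
glance.lhx_detection <- function(x, ...) {
  tibble(n_single = x$n_single, n_dual = x$n_dual,
         degenerate = x$degenerate)
}

#' Tidy a predation-proportion estimate
#'
#' @param x an `lhx_pp` object.
#' @param ... unused.
#' @return One row per quantity: `term`, `estimate`.
#' @export
tidy.lhx_pp <- function(x, ...) {
  tibble(
    term = c("pp_point", "pp_ceiling", "pp_lower_cl95", "pp_working"),
    estimate = c(x$pp_point, x$pp_ceiling, x$pp_lower_cl95, x$pp_working)
  )
}

#' @rdname tidy.lhx_pp
#' @export
glance.lhx_pp <- function(x, ...) {
  tibble(n_detected = x$n_detected, n_classified = x$n_classified,
         n_predation = x$n_predation)
}
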