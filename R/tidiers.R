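#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @describeIn condition_erps Tidy the per-window statistics table.
#' @param x An `erp_result`.
#' @param ... Unused.
#' @export
tidy.erp_result <- function(x, ...) x$windows

#' @describeIn condition_erps One-row summary: subjects, windows, significant
#'   windows (uncorrected and Holm), largest absolute difference.
#' @export
glance.erp_result <- function(x, ...) {
  tibble::tibble(
    n_subjects = x$n_subjects,
    n_tests = nrow(x$windows),
    n_sig_uncorrected = sum(x$windows$p < 0.05, na.rm = TRUE),
    n_sig_holm = sum(x$windows$p_holm < 0.05, na.rm = TRUE),
    max_abs_diff_uV = max(abs(x$windows$diff_uV))
  )
}

#' @describeIn compare_slopes An `rm_anova` is already a tidy tibble.
#' @param x An `rm_anova` object.
#' @param ... Unused.
#' @export
tidy.rm_anova <- function(x, ...) tibble::as_tibble(unclass(x))

#' @describeIn interaction_tests Stack the real and control ANOVA tables with
#'   a `battery` column.
#' @param x A `centroid_tests` object.
#' @param ... Unused.
#' @export
tidy.centroid_tests <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$anova, battery = "trustworthiness"),
    dplyr::mutate(x$control_anova, battery = "control")
  )
}

#' @describeIn interaction_tests One-row summary of the interaction and
#'   crossover tests.
#' @export
glance.centroid_tests <- function(x, ...) {
  i <- x$anova[x$anova$effect == "electrode:condition", ]
  ic <- x$control_anova[x$control_anova$effect == "electrode:condition", ]
  tibble::tibble(
    interaction_F = i$F, interaction_p = i$p, interaction_eta_p2 = i$eta_p2,
    crossover_t = x$crossover$t, crossover_p = x$crossover$p,
    crossover_d = x$crossover$cohens_d,
    control_interaction_F = ic$F, control_interaction_p = ic$p
  )
}

#' @describeIn null_envelope Tidy to a per-timepoint tibble.
#' @param x A `null_envelope` object.
#' @param ... Unused.
#' @export
tidy.null_envelope <- function(x, ...) {
  tibble::tibble(time_ms = x$times, lo = x$lo, median = x$median, hi = x$hi)
}
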