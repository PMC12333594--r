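#' Phase-slope frequency estimate
#'
#' Ordinary least-squares slope of a phase profile (radians) against time
#' (seconds), divided by 2*pi. Because instantaneous phase is the integral of
#' instantaneous frequency, the slope of an interhemispheric phase-shift
#' profile estimates the average frequency difference between the two
#' electrodes in Hz.
#'
#' @param profile Numeric phase profile (radians), with a `times` attribute
#'   (ms) unless `times` is supplied.
#' @param times Time axis in ms.
#' @param window Regression window in ms (closed); default spans the full
#'   post-stimulus range.
#' @return A list with `slope_hz`, `intercept_rad`, `r2`, `n`.
#' @export
fit_slope <- function(profile, times = attr(profile, "times"),
                      window = c(0, 3000)) {
  keep <- times >= window[1L] & times <= window[2L]
  if (sum(keep) < 10L) {
    stop("regression window holds fewer than 10 samples", call. = FALSE)
  }
  t_sec <- times[keep] / 1000
  y <- as.numeric(profile[keep])
  tc <- t_sec - mean(t_sec)
  stt <- sum(tc^2)
  slope <- sum(tc * y) / stt
  intercept <- mean(y) - slope * mean(t_sec)
  fitted <- intercept + slope * t_sec
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(
    slope_hz = slope / (2 * pi),
    intercept_rad = intercept,
    r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
    n = sum(keep)
  )
}

# vectorized slope (Hz) over rows of a profiles matrix
fit_slopes_matrix <- function(profiles, times, window = c(0, 3000)) {
  keep <- times >= window[1L] & times <= window[2L]
  t_sec <- times[keep] / 1000
  tc <- t_sec - mean(t_sec)
  drop(profiles[, keep, drop = FALSE] %*% tc) / sum(tc^2) / (2 * pi)
}

#' Control (null-median) frequency-divergence estimate
#'
#' Fits the phase slope to each of a subject's null-resample conditioning
#' profiles and returns the median slope — the subject's expected divergence
#' under label-exchangeable resampling.
#'
#' @param np Null-profile matrix from [null_profiles()].
#' @param window Regression window in ms.
#' @return Median slope in Hz.
#' @export
control_slope <- function(np, window = c(0, 3000)) {
  stats::median(fit_slopes_matrix(np, attr(np, "times"), window))
}

#' Per-subject observed and control divergence slopes
#'
#' For each subject: the observed slope is the phase-slope fit to the
#' real-label conditioning profile; the control slope is the median slope
#' over `n_resamples` balanced-partition null profiles.
#'
#' @param ps_list List of [pair_phase_shift()] results, one per subject.
#' @param n_resamples Balanced partitions per subject.
#' @param seed Integer master seed (per-subject streams derived from it).
#' @param window Regression window in ms.
#' @return A tibble: `subject`, `observed_hz`, `control_hz`, `r2`.
#' @export
slope_table <- function(ps_list, n_resamples = 1000, seed = 1L,
                        window = c(0, 3000)) {
  seeds <- subject_seeds(seed, length(ps_list))
  purrr::map2_dfr(ps_list, seq_along(ps_list), function(ps, i) {
    obs <- fit_slope(conditioning_shift(ps), window = window)
    np <- null_profiles(ps, n_resamples, seeds[i], stat = "conditioning")
    tibble::tibble(
      subject = ps$subject,
      observed_hz = obs$slope_hz,
      control_hz = control_slope(np, window),
      r2 = obs$r2
    )
  })
}

#' Repeated-measures comparison of observed vs control slopes
#'
#' One-factor (condition: observed vs control), two-level repeated-measures
#' ANOVA across subjects, fitted with [stats::aov()] with a subject error
#' stratum. For two levels this F statistic equals the squared paired t.
#'
#' @param table A [slope_table()] tibble (or any tibble with `subject`,
#'   `observed_hz`, `control_hz`).
#' @return An object of class `rm_anova`: tibble row with `effect`, `F`,
#'   `df1`, `df2`, `p`, `eta_p2`.
#' @export
compare_slopes <- function(table) {
  if (nrow(table) < 3L) stop("need at least 3 subjects", call. = FALSE)
  if (anyNA(table$observed_hz) || anyNA(table$control_hz)) {
    stop("missing slope entries", call. = FALSE)
  }
  long <- tidyr::pivot_longer(
    table[, c("subject", "observed_hz", "control_hz")],
    cols = c("observed_hz", "control_hz"),
    names_to = "condition", values_to = "slope_hz"
  )
  rm_anova_1f(long, dv = "slope_hz", within = "condition", id = "subject")
}

# one-factor repeated-measures ANOVA via aov with an Error(subject) stratum
rm_anova_1f <- function(data, dv, within, id) {
  data[[within]] <- factor(data[[within]])
  data[[id]] <- factor(data[[id]])
  fml <- stats::as.formula(
    sprintf("%s ~ %s + Error(%s/%s)", dv, within, id, within)
  )
  fit <- stats::aov(fml, data = data)
  tab <- summary(fit)[[sprintf("Error: %s:%s", id, within)]][[1L]]
  ss_eff <- tab["Sum Sq"][[1L]][1L]
  ss_err <- tab["Sum Sq"][[1L]][2L]
  structure(
    tibble::tibble(
      effect = within,
      F = tab["F value"][[1L]][1L],
      df1 = tab["Df"][[1L]][1L],
      df2 = tab["Df"][[1L]][2L],
      p = tab["Pr(>F)"][[1L]][1L],
      eta_p2 = ss_eff / (ss_eff + ss_err)
    ),
    class = c("rm_anova", "tbl_df", "tbl", "data.frame")
  )
}

#' Per-condition interhemispheric divergence estimates
#'
#' Fits the phase slope separately to each subject's trust-mean and
#' untrust-mean interhemispheric phase-shift profile. When the two
#' conditions lateralize frequency in opposite directions, the trust and
#' untrust slopes estimate +delta_f and -delta_f, so their half-difference
#' estimates the within-condition divergence directly (while the
#' conditioning-profile slope, an absolute difference of the two means,
#' runs at about twice that).
#'
#' @param ps_list List of [pair_phase_shift()] results (or a single one).
#' @param window Regression window in ms.
#' @return A tibble: `subject`, `trust_hz`, `untrust_hz`, `divergence_hz`
#'   (half the trust-minus-untrust slope difference).
#' @export
condition_divergence <- function(ps_list, window = c(0, 3000)) {
  if (inherits(ps_list, "phase_shift")) ps_list <- list(ps_list)
  purrr::map_dfr(ps_list, function(ps) {
    prof <- function(cond) {
      structure(colMeans(ps$shift[ps$labels == cond, , drop = FALSE]),
                times = ps$times)
    }
    tr <- fit_slope(prof("trust"), window = window)$slope_hz
    un <- fit_slope(prof("untrust"), window = window)$slope_hz
    tibble::tibble(subject = ps$subject, trust_hz = tr, untrust_hz = un,
                   divergence_hz = (tr - un) / 2)
  })
}
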