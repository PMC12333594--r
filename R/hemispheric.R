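#' Component analysis windows
#'
#' The three component windows used for interhemispheric magnitude
#' statistics: P100 80-130 ms, N170 170-220 ms, P300 250-300 ms (closed
#' intervals; statistics use the mean amplitude within the window).
#'
#' @return A tibble with `component`, `start_ms`, `end_ms`.
#' @export
component_windows <- function() {
  tibble::tibble(
    component = c("P100", "N170", "P300"),
    start_ms = c(80, 170, 250),
    end_ms = c(130, 220, 300)
  )
}

#' Per-trial left-minus-right difference profiles for one pair
#'
#' Returns the per-trial difference waveform of a homologous pair over the
#' full epoch, in the same container shape as [pair_phase_shift()] so the
#' balanced-resampling machinery ([null_profiles()], [null_envelope()])
#' applies unchanged.
#'
#' @param epochs An [eeg_epochs] object.
#' @param pair Length-2 character vector `c(left, right)`.
#' @return An object of class `pair_diff` with `shift` (trials x samples,
#'   microvolts), `times`, `pair`, `labels`, `subject`.
#' @export
pair_difference_trials <- function(epochs, pair) {
  missing_ch <- setdiff(pair, epochs$channels)
  if (length(missing_ch)) {
    stop("pair ", paste(pair, collapse = "-"), ": channel(s) absent: ",
         paste(missing_ch, collapse = ", "), call. = FALSE)
  }
  structure(
    list(
      shift = channel_matrix(epochs, pair[1L]) - channel_matrix(epochs, pair[2L]),
      times = epochs$times, pair = pair, labels = epochs$labels,
      subject = epochs$subject
    ),
    class = "pair_diff"
  )
}

#' Condition-mean interhemispheric difference waveforms
#'
#' For every pair and condition, the grand difference waveform
#' `mean_subjects(mean_trials(x_L - x_R))`: trial means within subject and
#' condition first, then the mean across subjects.
#'
#' @param epochs_list A list of [eeg_epochs] (or a single one), all sharing
#'   the montage and time axis.
#' @param pairs A [pair_table()]-shaped tibble.
#' @return A tibble: `pair`, `condition`, `time_ms`, `diff_uV`.
#' @export
pair_difference <- function(epochs_list, pairs = pair_table()) {
  if (inherits(epochs_list, "eeg_epochs")) epochs_list <- list(epochs_list)
  times <- epochs_list[[1L]]$times
  purrr::pmap_dfr(pairs, function(left, right, pair) {
    per_cond <- lapply(c(trust = "trust", untrust = "untrust"), function(cond) {
      waves <- vapply(epochs_list, function(ep) {
        pd <- pair_difference_trials(ep, c(left, right))
        colMeans(pd$shift[pd$labels == cond, , drop = FALSE])
      }, numeric(length(times)))
      rowMeans(waves)
    })
    purrr::map_dfr(names(per_cond), function(cond) {
      tibble::tibble(pair = pair, condition = cond, time_ms = times,
                     diff_uV = per_cond[[cond]])
    })
  })
}

#' Component-window paired tests on hemispheric amplitudes
#'
#' For each pair and component window: every subject contributes the mean
#' amplitude (over all trials and the window samples) at the left and at the
#' right electrode; a paired t-test across subjects compares the two, so a
#' negative t means the right electrode carried the larger (signed) amplitude.
#'
#' @param epochs_list A list of [eeg_epochs], one per subject (>= 2).
#' @param pairs A [pair_table()]-shaped tibble.
#' @param windows A [component_windows()]-shaped tibble.
#' @return A tibble: `pair`, `component`, `mean_diff_uV`, `t`, `df`, `p`.
#' @export
component_stats <- function(epochs_list, pairs = pair_table(),
                            windows = component_windows()) {
  if (inherits(epochs_list, "eeg_epochs")) epochs_list <- list(epochs_list)
  if (length(epochs_list) < 2L) {
    stop("need at least 2 subjects for paired component tests", call. = FALSE)
  }
  times <- epochs_list[[1L]]$times
  purrr::pmap_dfr(pairs, function(left, right, pair) {
    amp <- function(ep, ch, cols) mean(channel_matrix(ep, ch)[, cols, drop = FALSE])
    purrr::pmap_dfr(windows, function(component, start_ms, end_ms) {
      cols <- times >= start_ms & times <= end_ms
      l_amp <- vapply(epochs_list, amp, numeric(1), ch = left, cols = cols)
      r_amp <- vapply(epochs_list, amp, numeric(1), ch = right, cols = cols)
      tt <- stats::t.test(l_amp, r_amp, paired = TRUE)
      tibble::tibble(
        pair = pair, component = component,
        mean_diff_uV = mean(l_amp - r_amp),
        t = unname(tt$statistic), df = unname(tt$parameter),
        p = tt$p.value
      )
    })
  })
}

#' Condition difference waveforms vs the resampling null
#'
#' Builds the balanced-resampling null envelope of the half-mean difference
#' waveform for one pair and reports, per condition, the fraction of
#' timepoints at which the condition-mean profile escapes the pointwise CI.
#'
#' @param epochs_list A list of [eeg_epochs] (or a single one).
#' @param pair Length-2 character vector `c(left, right)`.
#' @param n_resamples Balanced partitions per subject.
#' @param seed Integer seed.
#' @param level Confidence level.
#' @return A list with `envelope` (a [null_envelope()]), `profiles` (tibble:
#'   `condition`, `time_ms`, `diff_uV`, `outside`), and `summary` (tibble:
#'   `condition`, `frac_outside`).
#' @export
magnitude_vs_null <- function(epochs_list, pair, n_resamples = 1000,
                              seed = 1L, level = 0.95) {
  if (inherits(epochs_list, "eeg_epochs")) epochs_list <- list(epochs_list)
  pds <- lapply(epochs_list, pair_difference_trials, pair = pair)
  env <- null_envelope(pds, n_resamples, seed, level, stat = "half_mean")
  profiles <- purrr::map_dfr(c("trust", "untrust"), function(cond) {
    waves <- vapply(pds, function(pd) {
      colMeans(pd$shift[pd$labels == cond, , drop = FALSE])
    }, numeric(length(pds[[1L]]$times)))
    v <- rowMeans(waves)
    tibble::tibble(condition = cond, time_ms = pds[[1L]]$times, diff_uV = v,
                   outside = v > env$hi | v < env$lo)
  })
  summary <- dplyr::summarise(dplyr::group_by(profiles, .data$condition),
                              frac_outside = mean(.data$outside),
                              .groups = "drop")
  list(envelope = env, profiles = profiles, summary = summary)
}
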