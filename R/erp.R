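#' 100-ms analysis windows tiling the post-stimulus epoch
#'
#' @param width Window width in ms.
#' @param span Post-stimulus range in ms (half-open).
#' @return A tibble with `window_start_ms`, `window_end_ms` (30 rows for the
#'   defaults).
#' @export
erp_windows <- function(width = 100, span = c(0, 3000)) {
  starts <- seq(span[1L], span[2L] - width, by = width)
  tibble::tibble(window_start_ms = starts, window_end_ms = starts + width)
}

#' Condition-averaged ERPs and windowed condition contrasts
#'
#' Computes, for a cohort of epoched recordings, per-subject condition-mean
#' waveforms, grand means (the mean of subject means, so unbalanced trial
#' counts do not bias the average), trust-minus-untrust differences averaged
#' over non-overlapping 100-ms windows, and a per-channel, per-window
#' one-factor (trustworthiness) repeated-measures test across subjects. With
#' two condition levels the repeated-measures F equals the squared paired t,
#' which is how it is computed here; uncorrected and Holm-corrected p values
#' are both reported.
#'
#' @param epochs_list A list of [eeg_epochs], one per subject, each with both
#'   conditions present; a single [eeg_epochs] is promoted to a cohort of one
#'   (the window tests are then skipped with a warning).
#' @param width Window width in ms.
#' @return An object of class `erp_result`: list with `grand` (tibble:
#'   `channel`, `condition`, `time_ms`, `amplitude_uV`), `windows` (tibble:
#'   `channel`, `window_start_ms`, `diff_uV`, `F`, `df1`, `df2`, `p`,
#'   `p_holm`, `eta_p2`), `n_subjects`.
#' @export
condition_erps <- function(epochs_list, width = 100) {
  if (inherits(epochs_list, "eeg_epochs")) epochs_list <- list(epochs_list)
  n_sub <- length(epochs_list)
  channels <- epochs_list[[1L]]$channels
  times <- epochs_list[[1L]]$times
  n_ch <- length(channels)
  n_t <- length(times)

  subj_means <- function(ep) {
    halves <- split_by_label(ep)
    if (any(vapply(halves, n_trials, integer(1)) == 0L)) {
      stop("both conditions must be non-empty for every subject", call. = FALSE)
    }
    lapply(halves, function(h) apply(h$data, c(2L, 3L), mean))  # channels x samples
  }
  means <- lapply(epochs_list, subj_means)

  grand <- lapply(c(trust = "trust", untrust = "untrust"), function(cond) {
    Reduce(`+`, lapply(means, `[[`, cond)) / n_sub
  })
  grand_tbl <- purrr::map_dfr(names(grand), function(cond) {
    tibble::tibble(
      channel = rep(channels, times = n_t),
      condition = cond,
      time_ms = rep(times, each = n_ch),
      amplitude_uV = as.vector(grand[[cond]])
    )
  })

  win <- erp_windows(width, c(0, times[n_t] + 1000 / epochs_list[[1L]]$fs))
  n_w <- nrow(win)
  # per-subject windowed trust-untrust differences: subjects x channels x windows
  dwin <- array(NA_real_, dim = c(n_sub, n_ch, n_w))
  for (s in seq_len(n_sub)) {
    d <- means[[s]]$trust - means[[s]]$untrust
    for (w in seq_len(n_w)) {
      cols <- times >= win$window_start_ms[w] & times < win$window_end_ms[w]
      dwin[s, , w] <- rowMeans(d[, cols, drop = FALSE])
    }
  }
  mean_d <- apply(dwin, c(2L, 3L), mean)
  if (n_sub >= 2L) {
    sd_d <- apply(dwin, c(2L, 3L), stats::sd)
    t_stat <- mean_d / (sd_d / sqrt(n_sub))
    t_stat[sd_d == 0] <- 0
    f_stat <- t_stat^2
    df2 <- n_sub - 1L
    p <- stats::pf(f_stat, 1, df2, lower.tail = FALSE)
    eta <- f_stat / (f_stat + df2)
  } else {
    warning("single subject: window tests skipped", call. = FALSE)
    f_stat <- p <- eta <- array(NA_real_, dim = dim(mean_d))
    df2 <- NA_integer_
  }
  windows <- tibble::tibble(
    channel = rep(channels, times = n_w),
    window_start_ms = rep(win$window_start_ms, each = n_ch),
    diff_uV = as.vector(mean_d),
    F = as.vector(f_stat),
    df1 = 1L,
    df2 = df2,
    p = as.vector(p),
    eta_p2 = as.vector(eta)
  )
  windows$p_holm <- if (all(is.na(windows$p))) NA_real_ else
    stats::p.adjust(windows$p, method = "holm")

  structure(list(grand = grand_tbl, windows = windows, n_subjects = n_sub),
            class = "erp_result")
}

#' @export
print.erp_result <- function(x, ...) {
  cat(sprintf("<erp_result> %d subjects, %d channels, %d windows\n",
              x$n_subjects, length(unique(x$windows$channel)),
              length(unique(x$windows$window_start_ms))))
  n_sig <- sum(x$windows$p < 0.05, na.rm = TRUE)
  cat(sprintf("  windows with uncorrected p < 0.05: %d of %d\n",
              n_sig, nrow(x$windows)))
  invisible(x)
}

#' Export condition-mean waveforms or window statistics as CSV
#'
#' @param x An `erp_result`.
#' @param path Output file.
#' @param what `"windows"` (default) or `"grand"`.
#' @return `path`, invisibly.
#' @export
write_erp_csv <- function(x, path, what = c("windows", "grand")) {
  what <- match.arg(what)
  readr::write_csv(x[[what]], path)
  invisible(path)
}
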