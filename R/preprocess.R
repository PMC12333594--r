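#' Zero-phase band-pass filter
#'
#' Band-limits every trial and channel with a cascade of two zero-phase
#' (forward-backward, `signal::filtfilt`) Butterworth stages: a gentle
#' high-pass of order `order` at the low edge — kept low-order because steep
#' high-pass filtering distorts slow ERP waveforms — and a steep low-pass of
#' order `2 * order` at the high edge, which doubles as an anti-alias filter
#' ahead of decimation. Zero-phase realization matters here: any phase
#' distortion would corrupt the instantaneous-phase analysis downstream.
#' When the high edge lies within 5% of Nyquist the low-pass stage is
#' omitted (the data cannot carry energy beyond it, and a Butterworth with a
#' corner that close to Nyquist is numerically fragile). Defaults reproduce
#' the 1-49 Hz analysis band.
#'
#' @param epochs An [eeg_epochs] object.
#' @param low,high Band edges in Hz; must satisfy `0 < low < high < fs/2`.
#' @param order High-pass Butterworth order; the low-pass runs at twice this.
#' @return A filtered [eeg_epochs] object.
#' @export
bandpass <- function(epochs, low = 1, high = 49, order = 4) {
  nyq <- epochs$fs / 2
  if (low <= 0) stop("low edge must be > 0 Hz", call. = FALSE)
  if (high >= nyq) {
    stop(sprintf("high edge %g Hz must be below the Nyquist frequency %g Hz",
                 high, nyq), call. = FALSE)
  }
  if (low >= high) stop("low edge must be below high edge", call. = FALSE)
  hp <- signal::butter(order, low / nyq, type = "high")
  lp <- if (high < 0.95 * nyq) {
    signal::butter(2 * order, high / nyq, type = "low")
  }
  out <- epochs
  d <- dim(epochs$data)
  for (tr in seq_len(d[1L])) {
    for (ch in seq_len(d[2L])) {
      x <- signal::filtfilt(hp, epochs$data[tr, ch, ])
      if (!is.null(lp)) x <- signal::filtfilt(lp, x)
      out$data[tr, ch, ] <- x
    }
  }
  out
}

#' Downsample epochs by an integer factor
#'
#' Optionally applies an anti-alias zero-phase Butterworth low-pass at 45% of
#' the target Nyquist-doubling rate before keeping every k-th sample. When the
#' data are already band-limited below the target Nyquist frequency (e.g.
#' after [bandpass()] to 1-49 Hz ahead of decimation to 100 Hz), the
#' anti-alias stage can be skipped.
#'
#' @param epochs An [eeg_epochs] object.
#' @param target_fs Target sampling rate in Hz; `fs` must be an integer
#'   multiple of it.
#' @param antialias Apply the protective low-pass first (default `TRUE`).
#' @return A downsampled [eeg_epochs] object; trial and channel counts are
#'   unchanged, the time axis is recomputed.
#' @export
downsample <- function(epochs, target_fs = 100, antialias = TRUE) {
  ratio <- epochs$fs / target_fs
  if (abs(ratio - round(ratio)) > 1e-9) {
    stop(sprintf("fs (%g) must be an integer multiple of target_fs (%g)",
                 epochs$fs, target_fs), call. = FALSE)
  }
  ratio <- as.integer(round(ratio))
  if (ratio == 1L) return(epochs)
  out <- epochs
  if (antialias) {
    bf <- signal::butter(6, 0.9 * (target_fs / 2) / (epochs$fs / 2), type = "low")
    d <- dim(epochs$data)
    for (tr in seq_len(d[1L])) {
      for (ch in seq_len(d[2L])) {
        out$data[tr, ch, ] <- signal::filtfilt(bf, epochs$data[tr, ch, ])
      }
    }
  }
  keep <- seq(1L, dim(epochs$data)[3L], by = ratio)
  out$data <- out$data[, , keep, drop = FALSE]
  out$times <- epochs$times[keep]
  out$fs <- target_fs
  out
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean over the pre-stimulus baseline
#' window (default `[-500, 0)` ms).
#'
#' @param epochs An [eeg_epochs] object.
#' @param window Baseline window in ms, half-open.
#' @return A baseline-corrected [eeg_epochs] object.
#' @export
baseline_correct <- function(epochs, window = c(-500, 0)) {
  in_base <- epochs$times >= window[1L] & epochs$times < window[2L]
  if (!any(in_base)) {
    stop("baseline window contains no samples of the epoch", call. = FALSE)
  }
  means <- apply(epochs$data[, , in_base, drop = FALSE], c(1L, 2L), mean)
  out <- epochs
  out$data <- epochs$data - as.vector(means)  # recycles over samples axis
  out
}

#' Re-reference all channels to Cz
#'
#' Subtracts the Cz waveform from every channel; Cz itself becomes all-zero
#' and is retained so the channel count is stable. Left-minus-right pair
#' differences are invariant under any common re-reference.
#'
#' @param epochs An [eeg_epochs] object containing a `Cz` channel.
#' @return A re-referenced [eeg_epochs] object.
#' @export
rereference_cz <- function(epochs) {
  idx <- match("Cz", epochs$channels)
  if (is.na(idx)) stop("Cz channel absent; cannot re-reference", call. = FALSE)
  ref <- epochs$data[, idx, , drop = FALSE]
  out <- epochs
  out$data <- epochs$data - ref[, rep(1L, dim(epochs$data)[2L]), , drop = FALSE]
  out
}

#' Split epochs by condition label
#'
#' @param epochs An [eeg_epochs] object whose trials are all labeled `trust`
#'   or `untrust`.
#' @return A named list with elements `trust` and `untrust`, each an
#'   [eeg_epochs]; an empty condition yields a zero-trial object with a
#'   warning.
#' @export
split_by_label <- function(epochs) {
  unlabeled <- which(epochs$labels == "unlabeled")
  if (length(unlabeled)) {
    stop("unlabeled trials at indices: ",
         paste(utils::head(unlabeled, 10), collapse = ", "), call. = FALSE)
  }
  take <- function(keep) {
    out <- epochs
    out$data <- epochs$data[keep, , , drop = FALSE]
    out$labels <- epochs$labels[keep]
    out
  }
  res <- list(trust = take(epochs$labels == "trust"),
              untrust = take(epochs$labels == "untrust"))
  if (any(vapply(res, n_trials, integer(1)) == 0L)) {
    warning("degenerate split: one condition has no trials", call. = FALSE)
  }
  res
}

#' Standard preprocessing chain
#'
#' Band-pass 1-49 Hz, decimate to 100 Hz, baseline-correct over `[-500, 0)`
#' ms, then re-reference to Cz — the default pipeline applied before every
#' analysis. The band-pass doubles as the anti-alias filter, so decimation
#' skips its own.
#'
#' @param epochs An [eeg_epochs] object.
#' @param low,high Analysis band in Hz.
#' @param target_fs Analysis sampling rate in Hz.
#' @param baseline Baseline window in ms.
#' @param rereference Re-reference to Cz after baseline correction.
#' @return A preprocessed [eeg_epochs] object.
#' @export
preprocess <- function(epochs, low = 1, high = 49, target_fs = 100,
                       baseline = c(-500, 0), rereference = TRUE) {
  out <- epochs
  if (epochs$fs != target_fs) {
    out <- bandpass(out, low, high)
    out <- downsample(out, target_fs, antialias = FALSE)
  } else {
    out <- bandpass(out, low, high)
  }
  out <- baseline_correct(out, baseline)
  if (rereference) out <- rereference_cz(out)
  out
}
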