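#' Multi-channel EEG epoch container
#'
#' An `eeg_epochs` object stores segmented EEG as a trials x channels x
#' samples array in microvolts, together with channel labels, the sampling
#' rate, the epoch time axis and per-trial condition labels. The time axis is
#' half-open: the first sample sits at the epoch start (default -500 ms
#' relative to stimulus onset) and the last at `end - 1000/fs` ms, so an
#' epoch spanning \[-500, 3000) ms at 100 Hz holds exactly 350 samples.
#'
#' @param data Numeric array, trials x channels x samples (microvolts).
#' @param channels Character vector of unique channel labels, one per channel.
#' @param fs Sampling rate in Hz.
#' @param t_start Time of the first sample in ms relative to stimulus onset.
#' @param labels Per-trial condition labels (`"trust"`, `"untrust"`, or
#'   `"unlabeled"`); recycled if length 1.
#' @param subject Subject identifier string.
#'
#' @return An object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(data, channels, fs, t_start = -500,
                       labels = "unlabeled", subject = "s01") {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3-d array (trials x channels x samples)", call. = FALSE)
  }
  if (length(channels) != dim(data)[2L]) {
    stop("length(channels) must equal the channel dimension of `data`", call. = FALSE)
  }
  if (anyDuplicated(channels)) stop("channel labels must be unique", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a positive scalar (Hz)", call. = FALSE)
  }
  n_trials <- dim(data)[1L]
  if (length(labels) == 1L) labels <- rep(labels, n_trials)
  if (length(labels) != n_trials) {
    stop("`labels` must have one entry per trial", call. = FALSE)
  }
  bad <- setdiff(unique(labels), c("trust", "untrust", "unlabeled"))
  if (length(bad)) {
    stop("unknown trial labels: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(
    list(
      data = data,
      channels = as.character(channels),
      fs = fs,
      times = t_start + (seq_len(dim(data)[3L]) - 1L) * 1000 / fs,
      labels = as.character(labels),
      subject = as.character(subject)
    ),
    class = "eeg_epochs"
  )
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<eeg_epochs> subject %s: %d trials x %d channels x %d samples @ %g Hz\n",
    x$subject, d[1L], d[2L], d[3L], x$fs
  ))
  cat(sprintf(
    "  time %g..%g ms; labels: %s\n",
    x$times[1L], x$times[length(x$times)],
    paste(sprintf("%s=%d", names(table(x$labels)), table(x$labels)), collapse = ", ")
  ))
  invisible(x)
}

#' @export
dim.eeg_epochs <- function(x) dim(x$data)

n_trials <- function(epochs) dim(epochs$data)[1L]

#' Extract one channel as a trials x samples matrix
#'
#' @param epochs An [eeg_epochs] object.
#' @param channel Channel label.
#' @return Numeric matrix, trials in rows, samples in columns.
#' @export
channel_matrix <- function(epochs, channel) {
  idx <- match(channel, epochs$channels)
  if (is.na(idx)) stop("channel not found: ", channel, call. = FALSE)
  m <- epochs$data[, idx, , drop = FALSE]
  dim(m) <- dim(m)[c(1L, 3L)]
  m
}

#' Restrict epochs to a time window
#'
#' @param epochs An [eeg_epochs] object.
#' @param window Numeric length-2, window in ms; half-open `[from, to)`.
#' @return An [eeg_epochs] object covering only the requested samples.
#' @export
crop_epochs <- function(epochs, window) {
  keep <- epochs$times >= window[1L] & epochs$times < window[2L]
  if (!any(keep)) stop("window outside the epoch time axis", call. = FALSE)
  out <- epochs
  out$data <- epochs$data[, , keep, drop = FALSE]
  out$times <- epochs$times[keep]
  out
}

#' Convert epochs to a long tibble
#'
#' One row per trial x channel x sample; useful for plotting small objects.
#' @param x An [eeg_epochs] object.
#' @param ... Unused.
#' @return A tibble with columns `trial`, `channel`, `time_ms`, `amplitude_uV`,
#'   `label`.
#' @importFrom tibble as_tibble
#' @method as_tibble eeg_epochs
#' @export
as_tibble.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  tibble::tibble(
    trial = rep(seq_len(d[1L]), times = d[2L] * d[3L]),
    channel = rep(rep(x$channels, each = d[1L]), times = d[3L]),
    time_ms = rep(x$times, each = d[1L] * d[2L]),
    amplitude_uV = as.vector(x$data),
    label = rep(x$labels, times = d[2L] * d[3L])
  )
}

#' Standard 30-channel montage
#'
#' The 10-20 montage used throughout: all 24 paired electrodes plus the
#' midline and frontopolar sites. Cz is the offline reference.
#'
#' @return Character vector of 30 channel labels.
#' @export
default_montage <- function() {
  c(
    "Fp1", "Fp2", "F3", "F4", "F7", "F8", "F9", "F10", "Fz",
    "FC1", "FC2", "FC5", "FC6", "C3", "C4", "Cz",
    "CP1", "CP2", "CP5", "CP6", "P3", "P4", "P7", "P8", "Pz",
    "PO3", "PO4", "POz", "O1", "O2"
  )
}

#' The 12 homologous left/right electrode pairs
#'
#' Fixed sign convention: differences are always left minus right.
#'
#' @return A tibble with columns `left`, `right` and `pair` (e.g. `"P7-P8"`),
#'   12 rows.
#' @export
pair_table <- function() {
  left <- c("F3", "F7", "F9", "FC1", "FC5", "C3",
            "CP1", "CP5", "P3", "P7", "PO3", "O1")
  right <- c("F4", "F8", "F10", "FC2", "FC6", "C4",
             "CP2", "CP6", "P4", "P8", "PO4", "O2")
  tibble::tibble(left = left, right = right, pair = paste0(left, "-", right))
}

#' Write epochs to an array container on disk
#'
#' The container is a pair of files sharing a stem: `<stem>.json` holds the
#' metadata (channels, fs, time axis start, labels, subject, dimensions) and
#' `<stem>.dat` the array payload as little-endian float64 in trial-major
#' order. The round trip is bit-exact.
#'
#' @param epochs An [eeg_epochs] object.
#' @param stem File path stem (no extension).
#' @return `stem`, invisibly.
#' @export
write_epochs <- function(epochs, stem) {
  meta <- list(
    format = "hemiphase-epochs-v1",
    dims = dim(epochs$data),
    channels = epochs$channels,
    fs = epochs$fs,
    t_start = epochs$times[1L],
    labels = epochs$labels,
    subject = epochs$subject
  )
  jsonlite::write_json(meta, paste0(stem, ".json"),
                       auto_unbox = TRUE, digits = NA)
  con <- file(paste0(stem, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.vector(epochs$data), con, size = 8L, endian = "little")
  invisible(stem)
}

#' Read epochs written by [write_epochs()]
#'
#' @param stem File path stem (no extension).
#' @return An [eeg_epochs] object.
#' @export
read_epochs <- function(stem) {
  meta_path <- paste0(stem, ".json")
  if (!file.exists(meta_path)) stop("metadata file not found: ", meta_path, call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  required <- c("dims", "channels", "fs", "t_start", "labels", "subject")
  missing <- setdiff(required, names(meta))
  if (length(missing)) {
    stop("epoch container missing field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  dims <- as.integer(meta$dims)
  con <- file(paste0(stem, ".dat"), "rb")
  on.exit(close(con))
  vals <- readBin(con, what = "double", n = prod(dims), size = 8L,
                  endian = "little")
  if (length(vals) != prod(dims)) stop("payload size does not match dims", call. = FALSE)
  eeg_epochs(array(vals, dim = dims), channels = meta$channels, fs = meta$fs,
             t_start = meta$t_start, labels = meta$labels,
             subject = meta$subject)
}
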