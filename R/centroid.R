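#' Power spectral density on a fixed frequency grid
#'
#' One-sided periodogram evaluated on bins `f_k = 0, bin_hz, ..., f_max` by
#' zero-padding the signal to a length whose discrete-Fourier grid contains
#' exactly those frequencies. For windows shorter than `1/bin_hz` seconds the
#' grid is therefore an interpolation of the native spectral resolution
#' (e.g. a 1.2 s window at 100 Hz has 0.833 Hz native resolution but is
#' evaluated on the 0.5 Hz grid). Scaling satisfies Parseval: the PSD summed
#' times the bin width equals the signal mean square.
#'
#' @param x Numeric vector, or matrix with one signal per column.
#' @param fs Sampling rate in Hz.
#' @param f_range Frequency range `c(0, f_max)` in Hz; `f_max <= fs/2`.
#' @param bin_hz Grid spacing in Hz.
#' @param demean Subtract each signal's mean first (the DC bin otherwise
#'   dominates the centroid of broadband signals).
#' @return A matrix (bins x signals, or a vector for vector input) with
#'   attribute `freqs` (Hz).
#' @export
psd_bins <- function(x, fs, f_range = c(0, 50), bin_hz = 0.5, demean = TRUE) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1L)
  n <- nrow(x)
  if (n < 16L) stop("signal too short for spectral estimation", call. = FALSE)
  if (f_range[2L] > fs / 2 + 1e-9) {
    stop("f_range exceeds the Nyquist frequency", call. = FALSE)
  }
  n_grid <- fs / bin_hz
  if (abs(n_grid - round(n_grid)) > 1e-9) {
    stop("fs must be an integer multiple of bin_hz", call. = FALSE)
  }
  n_grid <- as.integer(round(n_grid))
  mult <- as.integer(ceiling(n / n_grid))
  n_fft <- n_grid * mult
  if (demean) x <- sweep(x, 2L, colMeans(x), "-")
  xp <- rbind(x, matrix(0, n_fft - n, ncol(x)))
  X <- stats::mvfft(xp)
  k_max <- as.integer(round(f_range[2L] / bin_hz))
  rows <- 1L + (0:k_max) * mult
  pwr <- abs(X[rows, , drop = FALSE])^2 / (fs * n)
  onesided <- rep(2, k_max + 1L)
  onesided[1L] <- 1
  if (abs(f_range[2L] - fs / 2) < 1e-9) onesided[k_max + 1L] <- 1
  pwr <- pwr * onesided
  freqs <- (0:k_max) * bin_hz
  out <- if (vec) drop(pwr) else pwr
  attr(out, "freqs") <- freqs
  out
}

#' Spectral centroid of a spectrum
#'
#' The PSD-weighted mean frequency `sum(f_k * |X(k)|) / sum(|X(k)|)` — a
#' scalar summary of where spectral mass sits.
#'
#' @param spectrum Nonnegative spectrum vector (or matrix, bins x signals).
#' @param freqs Frequencies (Hz) of the bins; taken from the `freqs`
#'   attribute if absent.
#' @return Centroid in Hz (vector of one value per signal column).
#' @export
spectral_centroid <- function(spectrum, freqs = attr(spectrum, "freqs")) {
  if (is.null(freqs)) stop("bin frequencies required", call. = FALSE)
  if (any(spectrum < 0)) stop("spectrum must be nonnegative", call. = FALSE)
  if (is.null(dim(spectrum))) spectrum <- matrix(spectrum, ncol = 1L)
  tot <- colSums(spectrum)
  if (any(tot == 0)) {
    stop("centroid undefined for an all-zero spectrum", call. = FALSE)
  }
  drop(crossprod(spectrum, freqs)) / tot
}

#' Per-subject spectral-centroid table
#'
#' For one subject: per-trial spectral centroids of the analysis window
#' (default 800-2000 ms) at each electrode, averaged within condition; the
#' two control entries come from balanced random partitions, with each
#' resample contributing its two halves' mean centroids and the values
#' averaged across resamples.
#'
#' @param epochs An [eeg_epochs] object (preprocessed).
#' @param window Analysis window in ms, half-open.
#' @param electrodes Channels analyzed.
#' @param n_resamples Balanced partitions for the control entries.
#' @param seed Integer seed.
#' @param f_range,bin_hz PSD grid; see [psd_bins()].
#' @return A tibble: `subject`, `electrode`, `condition` (trust, untrust,
#'   control1, control2), `centroid_hz`.
#' @export
centroid_analysis <- function(epochs, window = c(800, 2000),
                              electrodes = c("CP1", "CP2"),
                              n_resamples = 100, seed = 1L,
                              f_range = c(0, 50), bin_hz = 0.5) {
  if (window[1L] < epochs$times[1L] ||
      window[2L] > epochs$times[length(epochs$times)] + 1000 / epochs$fs) {
    stop("analysis window outside the epoch", call. = FALSE)
  }
  missing_ch <- setdiff(electrodes, epochs$channels)
  if (length(missing_ch)) {
    stop("electrode(s) absent: ", paste(missing_ch, collapse = ", "),
         call. = FALSE)
  }
  i_tr <- which(epochs$labels == "trust")
  i_un <- which(epochs$labels == "untrust")
  if (!length(i_tr) || !length(i_un)) {
    stop("both conditions must be non-empty", call. = FALSE)
  }
  cols <- epochs$times >= window[1L] & epochs$times < window[2L]
  parts <- balanced_partitions(epochs$labels, n_resamples, seed)
  purrr::map_dfr(electrodes, function(el) {
    sc <- spectral_centroid(
      psd_bins(t(channel_matrix(epochs, el)[, cols, drop = FALSE]),
               epochs$fs, f_range, bin_hz)
    )
    c1 <- mean(vapply(parts, function(pt) mean(sc[pt$h1]), numeric(1)))
    c2 <- mean(vapply(parts, function(pt) mean(sc[pt$h2]), numeric(1)))
    tibble::tibble(
      subject = epochs$subject,
      electrode = el,
      condition = c("trust", "untrust", "control1", "control2"),
      centroid_hz = c(mean(sc[i_tr]), mean(sc[i_un]), c1, c2)
    )
  })
}

#' Cohort spectral-centroid table
#'
#' @param epochs_list A list of [eeg_epochs], one per subject.
#' @param ... Passed to [centroid_analysis()]; per-subject seeds are derived
#'   from `seed`.
#' @param seed Integer master seed.
#' @return Row-bound [centroid_analysis()] tibbles with unique subject ids.
#' @export
cohort_centroids <- function(epochs_list, ..., seed = 1L) {
  seeds <- subject_seeds(seed, length(epochs_list))
  purrr::map2_dfr(epochs_list, seq_along(epochs_list), function(ep, i) {
    out <- centroid_analysis(ep, ..., seed = seeds[i])
    out$subject <- sprintf("s%02d", i)
    out
  })
}

# 2 x 2 repeated-measures ANOVA with interaction, partial eta squared per effect
rm_anova_2f <- function(data, dv, f1, f2, id) {
  for (v in c(f1, f2, id)) data[[v]] <- factor(data[[v]])
  fml <- stats::as.formula(
    sprintf("%s ~ %s * %s + Error(%s/(%s*%s))", dv, f1, f2, id, f1, f2)
  )
  # inline formula and data so downstream emmeans can re-evaluate the call
  fit <- do.call(stats::aov, list(fml, data = data))
  sm <- summary(fit)
  pull <- function(stratum, effect) {
    tab <- sm[[stratum]][[1L]]
    row <- trimws(rownames(tab)) == effect
    ss_eff <- tab$`Sum Sq`[row]
    ss_err <- tab$`Sum Sq`[trimws(rownames(tab)) == "Residuals"]
    tibble::tibble(
      effect = effect,
      F = tab$`F value`[row],
      df1 = tab$Df[row],
      df2 = tab$Df[trimws(rownames(tab)) == "Residuals"],
      p = tab$`Pr(>F)`[row],
      eta_p2 = ss_eff / (ss_eff + ss_err)
    )
  }
  out <- dplyr::bind_rows(
    pull(sprintf("Error: %s:%s", id, f1), f1),
    pull(sprintf("Error: %s:%s", id, f2), f2),
    pull(sprintf("Error: %s:%s:%s", id, f1, f2), sprintf("%s:%s", f1, f2))
  )
  attr(out, "fit") <- fit
  out
}

#' Electrode-by-condition interaction battery on spectral centroids
#'
#' Runs, for the real conditions (trust/untrust) and identically for the
#' resampling controls (control1/control2):
#' a 2 (electrode) x 2 (condition) repeated-measures ANOVA with interaction;
#' Tukey-HSD simple effects of condition within each electrode (via
#' `emmeans`); and a paired t-test (with Cohen's d, mean/SD of the
#' within-subject differences) comparing the condition simple effect at the
#' first electrode against the second — the crossover contrast.
#'
#' @param table A [cohort_centroids()]-shaped tibble (`subject`, `electrode`,
#'   `condition`, `centroid_hz`) with >= 3 subjects.
#' @return An object of class `centroid_tests`: list with `anova`, `tukey`,
#'   `crossover` for the real conditions, and `control_anova`,
#'   `control_tukey`, `control_crossover` for the control pair.
#' @export
interaction_tests <- function(table) {
  run_battery <- function(tab, lev) {
    tab <- tab[tab$condition %in% lev, ]
    cells <- tidyr::pivot_wider(tab, names_from = c("electrode", "condition"),
                                values_from = "centroid_hz")
    if (anyNA(cells) || nrow(cells) < 3L) {
      stop("incomplete subject x electrode x condition cells", call. = FALSE)
    }
    an <- rm_anova_2f(tab, "centroid_hz", "electrode", "condition", "subject")
    em <- emmeans::emmeans(attr(an, "fit"), ~ condition | electrode)
    tk <- tibble::as_tibble(summary(
      emmeans::contrast(em, method = "pairwise", adjust = "tukey"),
      infer = TRUE
    ))
    electrodes <- sort(unique(tab$electrode))
    wide <- tidyr::pivot_wider(tab, names_from = c("electrode", "condition"),
                               values_from = "centroid_hz")
    se1 <- wide[[paste0(electrodes[1L], "_", lev[1L])]] -
      wide[[paste0(electrodes[1L], "_", lev[2L])]]
    se2 <- wide[[paste0(electrodes[2L], "_", lev[1L])]] -
      wide[[paste0(electrodes[2L], "_", lev[2L])]]
    d <- se1 - se2
    tt <- stats::t.test(se1, se2, paired = TRUE)
    crossover <- tibble::tibble(
      contrast = sprintf("(%s-%s)@%s - (%s-%s)@%s", lev[1L], lev[2L],
                         electrodes[1L], lev[1L], lev[2L], electrodes[2L]),
      mean_diff = mean(d),
      t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
      cohens_d = mean(d) / stats::sd(d)
    )
    list(anova = an, tukey = tk, crossover = crossover)
  }
  real <- run_battery(table, c("trust", "untrust"))
  ctrl <- run_battery(table, c("control1", "control2"))
  structure(
    list(anova = real$anova, tukey = real$tukey, crossover = real$crossover,
         control_anova = ctrl$anova, control_tukey = ctrl$tukey,
         control_crossover = ctrl$crossover),
    class = "centroid_tests"
  )
}

#' @export
print.centroid_tests <- function(x, ...) {
  cat("<centroid_tests> electrode x condition repeated-measures battery\n")
  i <- x$anova[x$anova$effect == "electrode:condition", ]
  cat(sprintf("  interaction: F(%d, %d) = %.2f, p = %.4g, eta_p2 = %.3f\n",
              i$df1, i$df2, i$F, i$p, i$eta_p2))
  cat(sprintf("  crossover paired t(%d) = %.2f, p = %.4g, d = %.2f\n",
              x$crossover$df, x$crossover$t, x$crossover$p,
              x$crossover$cohens_d))
  invisible(x)
}
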