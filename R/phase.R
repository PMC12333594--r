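#' Analytic signal via the frequency-domain Hilbert transform
#'
#' Computes `x + i * H(x)` where `H` is the Hilbert transform, realized by
#' zeroing negative frequencies and doubling positive ones in the discrete
#' Fourier domain (the `-j * sgn(f)` multiplier). Operates column-wise on a
#' matrix (samples in rows).
#'
#' @param x Numeric vector or matrix (samples x series).
#' @return Complex vector or matrix of the same shape.
#' @export
analytic_signal <- function(x) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1L)
  n <- nrow(x)
  if (n < 4L) stop("signal too short for the Hilbert transform", call. = FALSE)
  if (any(!is.finite(x))) stop("signal contains non-finite values", call. = FALSE)
  h <- numeric(n)
  h[1L] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1L] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  a <- stats::mvfft(stats::mvfft(x) * h, inverse = TRUE) / n
  if (vec) a[, 1L] else a
}

#' Instantaneous phase of a signal
#'
#' The wrapped phase (radians, in (-pi, pi]) of the analytic signal,
#' `atan2(H(x), x)`. Computed over the full epoch (including the baseline) so
#' that transform edge effects sit outside the post-stimulus analysis window.
#'
#' @param x Numeric vector or matrix (samples x series).
#' @return Wrapped phase, same shape as `x`.
#' @export
instantaneous_phase <- function(x) {
  if (all(x == 0)) stop("phase undefined for an all-zero signal", call. = FALSE)
  Arg(analytic_signal(x))
}

#' Unwrap a phase series
#'
#' Removes 2*pi discontinuities so that successive differences lie in
#' (-pi, pi] and the phase becomes a continuous progression; the output is
#' congruent to the input modulo 2*pi. Column-wise on matrices.
#'
#' @param p Wrapped phase, numeric vector or matrix (samples x series).
#' @return Unwrapped phase, same shape.
#' @export
unwrap_phase <- function(p) {
  unwrap1 <- function(v) {
    dp <- diff(v)
    v[1L] + cumsum(c(0, dp - 2 * pi * round(dp / (2 * pi))))
  }
  if (is.null(dim(p))) unwrap1(p) else apply(p, 2L, unwrap1)
}

#' Per-trial interhemispheric phase-shift profiles
#'
#' For one homologous electrode pair, computes the unwrapped instantaneous
#' phase of each electrode per trial over the full epoch, takes the left
#' minus right difference, restricts it to post-stimulus samples
#' (`[0, 3000)` ms) and re-zeroes each profile at stimulus onset so the
#' slope, not the offset, carries any frequency divergence.
#'
#' @param epochs An [eeg_epochs] object.
#' @param pair Length-2 character vector `c(left, right)`.
#' @return An object of class `phase_shift` with elements `shift` (trials x
#'   post-stimulus samples matrix, radians), `times` (ms), `pair`, `labels`,
#'   `subject`.
#' @export
pair_phase_shift <- function(epochs, pair = c("CP1", "CP2")) {
  missing_ch <- setdiff(pair, epochs$channels)
  if (length(missing_ch)) {
    stop("pair channel(s) absent: ", paste(missing_ch, collapse = ", "),
         call. = FALSE)
  }
  phi_l <- unwrap_phase(instantaneous_phase(t(channel_matrix(epochs, pair[1L]))))
  phi_r <- unwrap_phase(instantaneous_phase(t(channel_matrix(epochs, pair[2L]))))
  shift <- phi_l - phi_r            # samples x trials
  post <- epochs$times >= 0 & epochs$times < 3000
  shift <- shift[post, , drop = FALSE]
  shift <- sweep(shift, 2L, shift[1L, ], "-")
  structure(
    list(shift = t(shift), times = epochs$times[post], pair = pair,
         labels = epochs$labels, subject = epochs$subject),
    class = "phase_shift"
  )
}

#' @export
print.phase_shift <- function(x, ...) {
  cat(sprintf("<phase_shift> %s-%s, %d trials x %d timepoints (%s)\n",
              x$pair[1L], x$pair[2L], nrow(x$shift), ncol(x$shift), x$subject))
  invisible(x)
}

# |mean(rows idx1) - mean(rows idx2)| per timepoint
abs_mean_diff <- function(m, idx1, idx2) {
  abs(colMeans(m[idx1, , drop = FALSE]) - colMeans(m[idx2, , drop = FALSE]))
}

#' Conditioning interhemispheric phase shift
#'
#' The core statistic: the absolute difference, per post-stimulus timepoint,
#' between the trust-trial mean and the untrust-trial mean of the
#' interhemispheric phase-shift profile, for one subject.
#'
#' @param ps A [pair_phase_shift()] result.
#' @return Numeric vector (radians) with attribute `times` (ms).
#' @export
conditioning_shift <- function(ps) {
  i1 <- which(ps$labels == "trust")
  i2 <- which(ps$labels == "untrust")
  if (!length(i1) || !length(i2)) {
    stop("both conditions must be non-empty", call. = FALSE)
  }
  structure(abs_mean_diff(ps$shift, i1, i2), times = ps$times)
}

#' Cohort-mean conditioning profile
#'
#' @param ps_list List of [pair_phase_shift()] results, one per subject.
#' @return Numeric vector (radians), mean of per-subject conditioning
#'   profiles, with attribute `times`.
#' @export
cohort_conditioning_shift <- function(ps_list) {
  profs <- vapply(ps_list, conditioning_shift, numeric(ncol(ps_list[[1L]]$shift)))
  structure(rowMeans(profs), times = ps_list[[1L]]$times)
}

#' Balanced random partitions of labeled trials
#'
#' Each partition splits the trials into two halves of (as near as possible)
#' equal size such that each half carries (as near as possible) equal numbers
#' of trust and untrust trials — the resampling scheme behind the null
#' distribution of every condition contrast.
#'
#' @param labels Character vector of per-trial labels.
#' @param n_resamples Number of partitions.
#' @param seed Integer seed.
#' @return List of `n_resamples` lists, each with integer index vectors `h1`
#'   and `h2`.
#' @export
balanced_partitions <- function(labels, n_resamples, seed = 1L) {
  by_label <- split(seq_along(labels), labels)
  if (any(lengths(by_label) < 2L)) {
    stop("need at least 2 trials per label to partition", call. = FALSE)
  }
  withr::with_seed(seed, {
    lapply(seq_len(n_resamples), function(r) {
      h1 <- integer(0)
      h2 <- integer(0)
      extra_to_h1 <- r %% 2L == 0L  # alternate which half takes odd leftovers
      for (idx in by_label) {
        perm <- sample(idx)
        k <- if (extra_to_h1) ceiling(length(perm) / 2) else floor(length(perm) / 2)
        h1 <- c(h1, perm[seq_len(k)])
        h2 <- c(h2, perm[-seq_len(k)])
        extra_to_h1 <- !extra_to_h1  # balance across labels too
      }
      list(h1 = sort(h1), h2 = sort(h2))
    })
  })
}

#' Per-subject null profiles over balanced partitions
#'
#' Recomputes the chosen statistic between the two halves of each balanced
#' random partition, exactly as [conditioning_shift()] does for the real
#' labels.
#'
#' @param ps A [pair_phase_shift()] result (or any object with a trials x
#'   timepoints `shift` matrix and `labels`).
#' @param n_resamples Number of balanced partitions.
#' @param seed Integer seed.
#' @param stat `"conditioning"` for the absolute half-mean difference (the
#'   phase-shift null), `"half_mean"` for a single half's mean profile (the
#'   magnitude-waveform null).
#' @return Matrix `n_resamples` x timepoints with attribute `times`.
#' @export
null_profiles <- function(ps, n_resamples = 1000, seed = 1L,
                          stat = c("conditioning", "half_mean")) {
  stat <- match.arg(stat)
  parts <- balanced_partitions(ps$labels, n_resamples, seed)
  m <- ps$shift
  out <- t(vapply(parts, function(pt) {
    if (stat == "conditioning") abs_mean_diff(m, pt$h1, pt$h2)
    else colMeans(m[pt$h1, , drop = FALSE])
  }, numeric(ncol(m))))
  attr(out, "times") <- ps$times
  out
}

#' Pointwise null envelope of the conditioning statistic
#'
#' Builds the null distribution of the cohort-mean conditioning statistic:
#' for each of `n_resamples` balanced partitions, every subject's statistic
#' is recomputed between random halves, the cohort mean is taken per
#' resample index, and pointwise percentile bounds are extracted.
#' Per-subject resampling streams are derived deterministically from `seed`.
#'
#' @param ps_list A [pair_phase_shift()] result or list of them (one per
#'   subject).
#' @param n_resamples Number of balanced partitions (1000 reproduces the
#'   reference analysis).
#' @param seed Integer master seed.
#' @param level Confidence level of the pointwise interval.
#' @param stat Statistic to resample; see [null_profiles()].
#' @return An object of class `null_envelope`: list with `resamples`
#'   (n_resamples x timepoints cohort-mean matrix), `lo`, `hi`, `median`,
#'   `times`, `level`, `n_resamples`.
#' @export
null_envelope <- function(ps_list, n_resamples = 1000, seed = 1L,
                          level = 0.95, stat = "conditioning") {
  if (inherits(ps_list, "phase_shift")) ps_list <- list(ps_list)
  seeds <- subject_seeds(seed, length(ps_list))
  acc <- NULL
  for (s in seq_along(ps_list)) {
    np <- null_profiles(ps_list[[s]], n_resamples, seeds[s], stat)
    acc <- if (is.null(acc)) np else acc + np
  }
  res <- acc / length(ps_list)
  a <- (1 - level) / 2
  structure(
    list(
      resamples = res,
      lo = apply(res, 2L, stats::quantile, probs = a, names = FALSE),
      hi = apply(res, 2L, stats::quantile, probs = 1 - a, names = FALSE),
      median = apply(res, 2L, stats::median),
      times = ps_list[[1L]]$times,
      level = level,
      n_resamples = n_resamples
    ),
    class = "null_envelope"
  )
}

#' @export
print.null_envelope <- function(x, ...) {
  cat(sprintf("<null_envelope> %d resamples, %d timepoints, %.0f%% pointwise CI\n",
              x$n_resamples, length(x$times), 100 * x$level))
  invisible(x)
}

#' Flag timepoints where a profile escapes the null envelope
#'
#' `sides = "above"` flags profile values above the upper bound — the
#' significance reading for the nonnegative conditioning statistic.
#' `sides = "outside"` flags values outside the two-sided interval, the
#' appropriate reading for calibration checks (an exchangeable statistic
#' falls outside a 95% interval ~5% of the time, above its upper bound only
#' ~2.5%).
#'
#' @param profile Numeric profile (e.g. from [cohort_conditioning_shift()]).
#' @param envelope A [null_envelope()] object on the same time axis.
#' @param sides `"above"` or `"outside"`.
#' @return A list with `flags` (tibble: `time_ms`, `value`, `lo`, `hi`,
#'   `exceeds`) and `intervals` (tibble of contiguous significant runs:
#'   `start_ms`, `end_ms`, `n_samples`).
#' @export
exceedance <- function(profile, envelope, sides = c("above", "outside")) {
  sides <- match.arg(sides)
  times <- attr(profile, "times")
  if (is.null(times)) times <- envelope$times
  if (length(profile) != length(envelope$times) ||
      max(abs(times - envelope$times)) > 1e-9) {
    stop("profile and envelope time axes do not match", call. = FALSE)
  }
  ex <- if (sides == "above") profile > envelope$hi
        else profile > envelope$hi | profile < envelope$lo
  flags <- tibble::tibble(time_ms = times, value = as.numeric(profile),
                          lo = envelope$lo, hi = envelope$hi, exceeds = ex)
  runs <- rle(ex)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  sig <- which(runs$values)
  intervals <- tibble::tibble(
    start_ms = times[starts[sig]],
    end_ms = times[ends[sig]],
    n_samples = runs$lengths[sig]
  )
  list(flags = flags, intervals = intervals)
}
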