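test_that("instantaneous phase matches quadrature identities", {
  fs <- 100
  t <- seq(0, 3.5 - 1 / fs, by = 1 / fs)
  # 10 Hz spans an integer number of cycles over 3.5 s, so the discrete
  # Hilbert transform is leakage-free and the identities hold exactly
  ph_cos <- instantaneous_phase(cos(2 * pi * 10 * t))
  expect_equal(ph_cos[1], 0, tolerance = 1e-6)
  ph_sin <- instantaneous_phase(sin(2 * pi * 10 * t))
  expect_equal(ph_sin[1], -pi / 2, tolerance = 1e-6)
  expect_error(instantaneous_phase(rep(0, 100)), "all-zero")
  expect_error(instantaneous_phase(c(1, NA, 3, 4)), "finite")
})

test_that("unwrapped phase slope of a pure sinusoid equals 2*pi*f", {
  fs <- 100
  t <- seq(0, 3.5 - 1 / fs, by = 1 / fs)
  for (f in c(4, 10, 17)) {
    ph <- unwrap_phase(instantaneous_phase(cos(2 * pi * f * t)))
    n <- length(t)
    keep <- seq(ceiling(0.1 * n), floor(0.9 * n))
    slope <- sum((t[keep] - mean(t[keep])) * ph[keep]) /
      sum((t[keep] - mean(t[keep]))^2)
    expect_equal(slope, 2 * pi * f, tolerance = 0.01 * 2 * pi * f)
    # FFT oracle agrees on the dominant frequency
    pg <- stats::spec.pgram(stats::ts(cos(2 * pi * f * t), frequency = fs),
                            plot = FALSE, taper = 0)
    expect_equal(pg$freq[which.max(pg$spec)], f, tolerance = fs / n)
  }
})

test_that("unwrapping removes 2*pi jumps and is a modular inverse", {
  # sawtooth wrap of a linear ramp is exactly recovered
  ramp <- seq(0, 40, length.out = 500)
  wrapped <- (ramp + pi) %% (2 * pi) - pi
  expect_equal(unwrap_phase(wrapped), ramp, tolerance = 1e-10)
  # already-continuous input unchanged
  smooth <- cumsum(runif(200, -2, 2))
  expect_equal(unwrap_phase(smooth), smooth)
  # property: unwrap(wrap(x)) - x is a constant multiple of 2*pi
  withr::with_seed(99, {
    for (i in 1:20) {
      x <- cumsum(runif(300, -2.5, 2.5)) + runif(1, -10, 10)
      w <- (x + pi) %% (2 * pi) - pi
      resid <- (unwrap_phase(w) - x) / (2 * pi)
      expect_lt(max(abs(resid - round(resid))), 1e-8)
      expect_lt(diff(range(resid)), 1e-8)
    }
  })
  # agrees with the signal package's unwrapping
  withr::with_seed(5, {
    w <- (cumsum(runif(400, -3, 3)) + pi) %% (2 * pi) - pi
    expect_equal(unwrap_phase(w), as.numeric(signal::unwrap(w)),
                 tolerance = 1e-10)
  })
})

test_that("pair phase shift recovers frequency differences and antisymmetry", {
  ep <- sine_epochs(n_trials = 3, f_l = 12, f_r = 10)
  ps <- pair_phase_shift(ep, c("CP1", "CP2"))
  expect_equal(ps$shift[, 1], rep(0, 3))  # re-zeroed at onset
  prof <- structure(colMeans(ps$shift), times = ps$times)
  expect_equal(fit_slope(prof, window = c(300, 2700))$slope_hz, 2,
               tolerance = 0.02)
  # antisymmetry under pair orientation swap
  ps_rev <- pair_phase_shift(ep, c("CP2", "CP1"))
  expect_equal(ps_rev$shift, -ps$shift, tolerance = 1e-10)
  # identical channels give the zero profile
  ep0 <- sine_epochs(f_l = 10, f_r = 10)
  expect_lt(max(abs(pair_phase_shift(ep0, c("CP1", "CP2"))$shift)), 1e-8)
  expect_error(pair_phase_shift(ep, c("CP1", "ZZ")), "absent")
})

test_that("conditioning shift is nonnegative, label-symmetric, and recovers slope", {
  ep_tr <- sine_epochs(n_trials = 3, f_l = 11, f_r = 9, onset_ms = 800)
  ep_un <- sine_epochs(n_trials = 3, f_l = 9, f_r = 11, onset_ms = 800)
  data <- array(NA_real_, dim = c(6, 3, dim(ep_tr$data)[3]))
  data[1:3, , ] <- ep_tr$data
  data[4:6, , ] <- ep_un$data
  ep <- eeg_epochs(data, ep_tr$channels, ep_tr$fs,
                   labels = rep(c("trust", "untrust"), each = 3))
  ps <- pair_phase_shift(ep, c("CP1", "CP2"))
  cs <- conditioning_shift(ps)
  expect_true(all(cs >= 0))
  # swapping the labels leaves the statistic unchanged
  ps_sw <- ps
  ps_sw$labels <- ifelse(ps$labels == "trust", "untrust", "trust")
  expect_equal(conditioning_shift(ps_sw), conditioning_shift(ps))
  # pre-onset flat, post-onset diverging at 2 * delta_f
  sl <- fit_slope(cs, window = c(1000, 2800))$slope_hz
  expect_equal(sl, 4, tolerance = 0.1)
  ps_empty <- ps
  ps_empty$labels <- rep("trust", 6)
  expect_error(conditioning_shift(ps_empty), "non-empty")
})

test_that("balanced partitions satisfy the size and balance constraints", {
  labels <- c(rep("trust", 11), rep("untrust", 10))
  parts <- balanced_partitions(labels, 50, seed = 4)
  for (pt in parts) {
    expect_equal(sort(c(pt$h1, pt$h2)), seq_along(labels))
    expect_lte(abs(length(pt$h1) - length(pt$h2)), 1)
    for (lab in c("trust", "untrust")) {
      n1 <- sum(labels[pt$h1] == lab)
      n2 <- sum(labels[pt$h2] == lab)
      expect_lte(abs(n1 - n2), 1)
    }
  }
  expect_error(balanced_partitions(c("trust", "untrust"), 5), "at least 2")
})

test_that("null envelope is seeded, ordered, and sized by the resample count", {
  ep <- noise_epochs(31, n_trials = 20)
  ps <- pair_phase_shift(ep, c("CP1", "CP2"))
  env1 <- null_envelope(ps, n_resamples = 100, seed = 9)
  env2 <- null_envelope(ps, n_resamples = 100, seed = 9)
  expect_identical(env1$resamples, env2$resamples)
  expect_true(all(env1$hi >= env1$lo))
  expect_true(all(env1$median >= env1$lo & env1$median <= env1$hi))
  expect_equal(dim(env1$resamples), c(100, length(ps$times)))
  env3 <- null_envelope(ps, n_resamples = 100, seed = 10)
  expect_false(identical(env1$resamples, env3$resamples))
})

test_that("exceedance flags, intervals, and monotonicity behave", {
  ep <- noise_epochs(13, n_trials = 16)
  ps <- pair_phase_shift(ep, c("CP1", "CP2"))
  env <- null_envelope(ps, n_resamples = 80, seed = 2)
  # the envelope median never exceeds the envelope
  med <- structure(env$median, times = env$times)
  expect_false(any(exceedance(med, env)$flags$exceeds))
  # a profile above the upper bound is flagged everywhere, as one interval
  high <- structure(env$hi + 1, times = env$times)
  exc <- exceedance(high, env)
  expect_true(all(exc$flags$exceeds))
  expect_equal(nrow(exc$intervals), 1)
  expect_equal(exc$intervals$start_ms, env$times[1])
  # monotone under uniform inflation
  prof <- conditioning_shift(ps)
  f1 <- exceedance(prof, env)$flags$exceeds
  f2 <- exceedance(structure(prof + 0.5, times = env$times), env)$flags$exceeds
  expect_true(all(f2[f1]))
  # axis mismatch is an error
  short <- structure(env$median[-1], times = env$times[-1])
  expect_error(exceedance(short, env), "match")
})

test_that("injected onset produces exceedance concentrated after the onset", {
  p <- divergence_study_params(seed = 60, n_subjects = 4)
  cohort <- simulate_cohort(p)
  ps <- lapply(cohort, function(s) pair_phase_shift(s$epochs, c("CP1", "CP2")))
  prof <- cohort_conditioning_shift(ps)
  env <- null_envelope(ps, n_resamples = 150, seed = 61)
  exc <- exceedance(prof, env)
  expect_gt(nrow(exc$intervals), 0)
  # earliest sustained significant interval begins near the 800 ms onset
  sustained <- exc$intervals[exc$intervals$n_samples >= 5, ]
  expect_gt(nrow(sustained), 0)
  expect_lt(abs(sustained$start_ms[1] - 800), 300)
  # pre-onset exceedance is sparse
  pre <- exc$flags$exceeds[exc$flags$time_ms < 600]
  expect_lt(mean(pre), 0.2)
})
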