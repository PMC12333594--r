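test_that("PSD lands on the requested grid with Parseval scaling", {
  fs <- 100
  t <- seq(0, 1.2 - 1 / fs, by = 1 / fs)
  spec <- psd_bins(cos(2 * pi * 10 * t), fs)
  freqs <- attr(spec, "freqs")
  expect_equal(freqs, seq(0, 50, by = 0.5))
  expect_equal(freqs[which.max(spec)], 10)
  # Parseval: total one-sided power times bin width equals the mean square
  withr::with_seed(2, {
    for (i in 1:5) {
      y <- rnorm(120)
      py <- psd_bins(y, fs)
      expect_equal(sum(py) * 0.5, mean((y - mean(y))^2), tolerance = 0.05)
    }
  })
  expect_error(psd_bins(rnorm(8), fs), "too short")
  expect_error(psd_bins(rnorm(120), fs, f_range = c(0, 80)), "Nyquist")
})

test_that("spectral centroid matches closed-form cases", {
  freqs <- seq(0, 50, by = 0.5)
  single <- numeric(101); single[freqs == 10] <- 3
  expect_identical(spectral_centroid(single, freqs), 10)
  flat <- rep(1, 101)
  expect_identical(spectral_centroid(flat, freqs), 25)
  two <- numeric(101); two[freqs %in% c(8, 12)] <- 1
  expect_identical(spectral_centroid(two, freqs), 10)
  expect_error(spectral_centroid(numeric(101), freqs), "all-zero")
  expect_error(spectral_centroid(c(-1, rep(1, 100)), freqs), "nonnegative")
})

test_that("centroid is translation-equivariant on the bin grid", {
  withr::with_seed(4, {
    freqs <- seq(0, 50, by = 0.5)
    spec <- runif(101)
    spec[90:101] <- 0  # leave room to shift
    c0 <- spectral_centroid(spec, freqs)
    shifted <- c(numeric(10), spec[1:91])  # +5 Hz shift
    expect_equal(spectral_centroid(shifted, freqs), c0 + 5, tolerance = 1e-10)
  })
})

test_that("per-subject centroid table reflects injected lateralization", {
  p <- interaction_study_params(seed = 13, n_subjects = 1)
  p$lateral$amp <- 4  # strong effect for a single-subject sign check
  s <- simulate_subject(p, 99)
  tbl <- centroid_analysis(baseline_correct(s$epochs), n_resamples = 40,
                           seed = 7)
  expect_setequal(tbl$condition, c("trust", "untrust", "control1", "control2"))
  get <- function(el, cond) tbl$centroid_hz[tbl$electrode == el &
                                            tbl$condition == cond]
  # trust raises CP1 frequency and lowers CP2; untrust mirrors it
  expect_gt(get("CP1", "trust"), get("CP1", "untrust"))
  expect_lt(get("CP2", "trust"), get("CP2", "untrust"))
  # random halves are exchangeable
  expect_equal(get("CP1", "control1"), get("CP1", "control2"),
               tolerance = 0.05)
  expect_true(all(tbl$centroid_hz >= 0 & tbl$centroid_hz <= 50))
})

test_that("condition-identical data give equal trust/untrust centroids", {
  ep <- noise_epochs(91, n_trials = 8)
  ep$data[ep$labels == "untrust", , ] <- ep$data[ep$labels == "trust", , ]
  tbl <- centroid_analysis(ep, n_resamples = 20, seed = 1)
  for (el in c("CP1", "CP2")) {
    expect_equal(tbl$centroid_hz[tbl$electrode == el & tbl$condition == "trust"],
                 tbl$centroid_hz[tbl$electrode == el & tbl$condition == "untrust"])
  }
  expect_error(centroid_analysis(ep, window = c(2500, 4000)), "outside")
  expect_error(centroid_analysis(ep, electrodes = c("CP1", "QQ")), "absent")
})

test_that("interaction battery: structure, equal-cell null, subject-shift invariance", {
  withr::with_seed(5, {
    base <- tidyr::expand_grid(
      subject = sprintf("s%02d", 1:10),
      electrode = c("CP1", "CP2"),
      condition = c("trust", "untrust", "control1", "control2")
    )
    base$centroid_hz <- 10 + rnorm(nrow(base), sd = 0.5)
    res <- interaction_tests(base)
    expect_setequal(res$anova$effect,
                    c("electrode", "condition", "electrode:condition"))
    expect_equal(res$anova$df1, rep(1, 3))
    expect_equal(res$anova$df2, rep(9, 3))
    expect_equal(nrow(res$tukey), 2)
    # adding a per-subject constant to all cells leaves every F unchanged
    shifted <- dplyr::mutate(base,
      centroid_hz = centroid_hz + 3 * as.integer(factor(subject)))
    res_sh <- interaction_tests(shifted)
    expect_equal(res_sh$anova$F, res$anova$F, tolerance = 1e-8)
    # per-subject contrasts that average to exactly zero: every effect's
    # group mean vanishes while residual variance stays positive -> F ~ 0
    ctr <- function(x) x - mean(x)
    a <- ctr(rnorm(10)); b <- ctr(rnorm(10)); g <- ctr(rnorm(10))
    flat <- base
    i <- as.integer(factor(flat$subject))
    he <- ifelse(flat$electrode == "CP1", 1, -1)
    hc <- ifelse(flat$condition %in% c("trust", "control1"), 1, -1)
    flat$centroid_hz <- 10 + a[i] * he + b[i] * hc + g[i] * he * hc
    res_flat <- interaction_tests(flat)
    expect_lt(max(res_flat$anova$F), 1e-10)
  })
})

test_that("crossover paired test agrees with the interaction F", {
  # for a 2x2 within design, the interaction F equals the squared paired t
  # on the per-subject simple-effect differences
  withr::with_seed(6, {
    tbl <- tidyr::expand_grid(
      subject = sprintf("s%02d", 1:12),
      electrode = c("CP1", "CP2"),
      condition = c("trust", "untrust")
    )
    tbl$centroid_hz <- 10 + rnorm(nrow(tbl)) +
      ifelse(tbl$electrode == "CP1" & tbl$condition == "trust", 0.8, 0)
    ctrl <- dplyr::mutate(tbl,
      condition = ifelse(condition == "trust", "control1", "control2"))
    res <- interaction_tests(dplyr::bind_rows(tbl, ctrl))
    f_int <- res$anova$F[res$anova$effect == "electrode:condition"]
    expect_equal(f_int, res$crossover$t^2, tolerance = 1e-6)
    expect_equal(res$crossover$cohens_d,
                 res$crossover$t / sqrt(12), tolerance = 1e-8)
  })
})
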