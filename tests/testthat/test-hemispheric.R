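test_that("pair table matches the 12-pair montage convention", {
  pt <- pair_table()
  expect_equal(nrow(pt), 12)
  expect_true(all(c(pt$left, pt$right) %in% default_montage()))
  expect_true(all(pt$pair == paste0(pt$left, "-", pt$right)))
  # left members are odd-numbered or low-numbered sites by 10-20 convention
  expect_true(all(pt$left != pt$right))
})

test_that("pair differences vanish for identical channels and flip with orientation", {
  ep <- sine_epochs(n_trials = 4, f_l = 10, f_r = 10,
                    channels = c("P7", "P8", "Cz"))
  ep$labels <- rep(c("trust", "untrust"), 2)
  pd <- pair_difference_trials(ep, c("P7", "P8"))
  expect_lt(max(abs(pd$shift)), 1e-12)
  ep2 <- noise_epochs(3, channels = c("P7", "P8", "Cz"), n_trials = 6)
  d1 <- pair_difference_trials(ep2, c("P7", "P8"))
  d2 <- pair_difference_trials(ep2, c("P8", "P7"))
  expect_equal(d2$shift, -d1$shift)
  expect_error(pair_difference_trials(ep2, c("P7", "O9")), "absent")
})

test_that("condition waveforms average trials then subjects", {
  eps <- lapply(c(51, 52), noise_epochs, n_trials = 10,
                channels = c("P7", "P8", "Cz"))
  pt <- tibble::tibble(left = "P7", right = "P8", pair = "P7-P8")
  wf <- pair_difference(eps, pt)
  expect_setequal(unique(wf$condition), c("trust", "untrust"))
  one <- vapply(eps, function(ep) {
    keep <- ep$labels == "trust"
    mean(ep$data[keep, 1, 1] - ep$data[keep, 2, 1])
  }, numeric(1))
  got <- wf$diff_uV[wf$condition == "trust" & wf$time_ms == eps[[1]]$times[1]]
  expect_equal(got, mean(one), tolerance = 1e-12)
})

test_that("right-lateralized generator yields the expected component signs", {
  p <- sim_params(n_subjects = 6, n_sessions = 1, trials_per_session = 12,
                  fs_raw = 100, noise_sd = 1,
                  montage = c("P7", "P8", "O1", "O2", "CP1", "CP2", "Cz"),
                  background = list(exponent = 1, amp = 1, alpha_amp = 1,
                                    alpha_freq = 10),
                  components = list(
                    list(name = "P100", center = 100, sd = 15, amp = 3,
                         channels = c("O1", "O2", "P7", "P8")),
                    list(name = "N170", center = 195, sd = 18, amp = -4,
                         channels = c("P7", "P8", "O1", "O2")),
                    list(name = "P300", center = 275, sd = 25, amp = 3,
                         channels = c("CP1", "CP2"))
                  ),
                  lateral_gain = c(P8 = 1.3, O2 = 1.3), seed = 77)
  cohort <- simulate_cohort(p)
  eps <- lapply(cohort, function(s) baseline_correct(s$epochs))
  pt <- tibble::tibble(left = c("P7", "O1"), right = c("P8", "O2"),
                       pair = c("P7-P8", "O1-O2"))
  st <- component_stats(eps, pt)
  # positive P100 with right gain > 1 -> left minus right negative
  p100 <- st[st$pair == "P7-P8" & st$component == "P100", ]
  expect_lt(p100$mean_diff_uV, 0)
  expect_lt(p100$t, 0)
  # negative N170 with right gain > 1 -> left minus right positive
  n170 <- st[st$pair == "O1-O2" & st$component == "N170", ]
  expect_gt(n170$mean_diff_uV, 0)
  expect_gt(n170$t, 0)
  # df = n_subjects - 1
  expect_true(all(st$df == 5))
})

test_that("component stats are zero when hemispheres are identical", {
  ep <- noise_epochs(61, n_trials = 8, channels = c("P7", "P8", "Cz"))
  ep$data[, 2, ] <- ep$data[, 1, ]  # right copies left
  eps <- list(ep, noise_epochs(62, n_trials = 8,
                               channels = c("P7", "P8", "Cz")))
  eps[[2]]$data[, 2, ] <- eps[[2]]$data[, 1, ]
  pt <- tibble::tibble(left = "P7", right = "P8", pair = "P7-P8")
  st <- component_stats(eps, pt)
  expect_true(all(abs(st$mean_diff_uV) < 1e-12))
  expect_error(component_stats(list(ep), pt), "at least 2")
})

test_that("magnitude null comparison is calibrated under exchangeable labels", {
  eps <- lapply(71:74, noise_epochs, n_trials = 24,
                channels = c("P7", "P8", "Cz"))
  res <- magnitude_vs_null(eps, c("P7", "P8"), n_resamples = 200, seed = 5)
  # label-free noise: condition profiles rarely escape the envelope
  expect_lt(max(res$summary$frac_outside), 0.15)
  expect_setequal(res$summary$condition, c("trust", "untrust"))
  # profile values sit mostly inside [lo, hi]
  expect_true(all(c("envelope", "profiles", "summary") %in% names(res)))
})

test_that("pair differences are invariant under common re-referencing", {
  ep <- noise_epochs(81, n_trials = 6, channels = c("P7", "P8", "Cz"))
  reref <- rereference_cz(ep)
  d1 <- pair_difference_trials(ep, c("P7", "P8"))
  d2 <- pair_difference_trials(reref, c("P7", "P8"))
  expect_equal(d1$shift, d2$shift, tolerance = 1e-12)
})

test_that("condition-dependent magnitude asymmetry escapes the null post-onset", {
  # a trust-only offset at P7 over 1000-2500 ms: the balanced-null envelope
  # centers on the condition-mixed mean (each half holds half the trust
  # trials), so the trust profile exits by offset/2 -- make that margin
  # comfortably larger than the envelope width
  p <- sim_params(n_subjects = 4, n_sessions = 2, trials_per_session = 24,
                  fs_raw = 100, noise_sd = 1,
                  montage = c("P7", "P8", "Cz"), components = list(),
                  lateral_gain = c(),
                  lateral = list(pair = c("P7", "P8"), f0 = 10, delta_f = 0,
                                 onset_ms = 800, amp = 1),
                  cond_offset = list(channel = "P7", window = c(1000, 2500),
                                     amp = 4, condition = "trust"),
                  seed = 404)
  eps <- lapply(simulate_cohort(p), function(s) baseline_correct(s$epochs))
  res <- magnitude_vs_null(eps, c("P7", "P8"), n_resamples = 200, seed = 9)
  pr <- res$profiles[res$profiles$condition == "trust", ]
  inside_win <- pr$time_ms >= 1100 & pr$time_ms < 2400
  before_win <- pr$time_ms >= 0 & pr$time_ms < 900
  expect_gt(mean(pr$outside[inside_win]), 0.8)
  expect_lt(mean(pr$outside[before_win]), 0.2)
})
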