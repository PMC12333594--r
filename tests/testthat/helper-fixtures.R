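# Shared fixtures, built in code at test time.

# Deterministic two-channel epochs: left channel a sinusoid at f_l, right at
# f_r, switching from f0 at onset; no noise.
sine_epochs <- function(n_trials = 4, fs = 100, f_l = 10, f_r = 10,
                        f0 = 10, onset_ms = 0, channels = c("CP1", "CP2", "Cz"),
                        labels = "unlabeled") {
  times <- seq(-500, 3000 - 1000 / fs, by = 1000 / fs)
  t_sec <- times / 1000
  onset <- onset_ms / 1000
  stepped <- function(f1) {
    ph <- 2 * pi * f0 * t_sec
    post <- t_sec >= onset
    ph[post] <- 2 * pi * (f0 * onset + f1 * (t_sec[post] - onset))
    cos(ph)
  }
  n_s <- length(times)
  data <- array(0, dim = c(n_trials, length(channels), n_s))
  for (tr in seq_len(n_trials)) {
    data[tr, 1, ] <- stepped(f_l)
    data[tr, 2, ] <- stepped(f_r)
  }
  eeg_epochs(data, channels, fs, t_start = -500, labels = labels)
}

# Small noisy labeled epochs for resampling/statistics tests.
noise_epochs <- function(seed, n_trials = 40, fs = 100,
                         channels = c("CP1", "CP2", "Cz"), sd = 1) {
  withr::with_seed(seed, {
    n_s <- as.integer(3.5 * fs)
    data <- array(rnorm(n_trials * length(channels) * n_s, sd = sd),
                  dim = c(n_trials, length(channels), n_s))
    labels <- sample(rep(c("trust", "untrust"), length.out = n_trials))
    eeg_epochs(data, channels, fs, t_start = -500, labels = labels)
  })
}

# Minimal fast generator settings for unit tests; any field can be overridden.
tiny_params <- function(...) {
  defaults <- list(n_subjects = 2, n_sessions = 1, trials_per_session = 8,
                   fs_raw = 100, montage = c("CP1", "CP2", "Cz"),
                   components = list(), lateral_gain = c())
  overrides <- list(...)
  do.call(sim_params,
          c(overrides, defaults[setdiff(names(defaults), names(overrides))]))
}

# stack two trials x channels x samples arrays along the trial axis
abind_rows <- function(a, b) {
  out <- array(NA_real_, dim = c(dim(a)[1] + dim(b)[1], dim(a)[2], dim(a)[3]))
  out[seq_len(dim(a)[1]), , ] <- a
  out[dim(a)[1] + seq_len(dim(b)[1]), , ] <- b
  out
}
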