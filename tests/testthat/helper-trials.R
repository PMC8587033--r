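# Shared fixtures, generated once per test run and memoised.

fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = fixture_env)) {
    assign(key, force(expr), envir = fixture_env)
  }
  get(key, envir = fixture_env)
}

# clean gait: no variability, no artifacts, no jitter
clean_config <- function(duration = 60, seed = 3) {
  gait_sim_config(duration = duration, step_time_cv = 0, asymmetry_ratio = 1,
                  p_dropped_step = 0, p_weak_peak = 0, p_double_peak = 0,
                  sampling_jitter_sd = 0, noise_sd = 0.1, seed = seed)
}

clean_trial <- function() memo("clean_trial", generate_trial(clean_config()))

clean_prep <- function() memo("clean_prep", prepare_trial(clean_trial()))

# default-condition trial (variability, asymmetry, artifacts)
default_trial <- function() {
  memo("default_trial", generate_trial(gait_sim_config(duration = 60, seed = 11)))
}

default_prep <- function() memo("default_prep", prepare_trial(default_trial()))

# small feature matrix with injected AP-like peaks, for model toys
toy_peak_features <- function(n = 4000, n_pos = 60, seed = 1) {
  set.seed(seed)
  feats <- matrix(stats::rnorm(n * 12, 0, 0.3), n, 12)
  colnames(feats) <- c("ax", "ay", "az", "lx", "ly", "lz",
                       "gx", "gy", "gz", "ox", "oy", "oz")
  labels <- integer(n)
  pos <- seq(40L, n - 40L, length.out = n_pos)
  pos <- as.integer(round(pos))
  for (p in pos) {
    feats[p + (-2:2), 6] <- feats[p + (-2:2), 6] + c(0.5, 1.5, 2.5, 1.5, 0.5)
    labels[p] <- 1L
  }
  list(features = feats, labels = labels, pos = pos)
}
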