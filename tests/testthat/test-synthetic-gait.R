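test_that("config validation rejects out-of-range parameters", {
  expect_error(gait_sim_config(duration = -1), "duration")
  expect_error(gait_sim_config(mean_step_time = 2), "mean_step_time")
  expect_error(gait_sim_config(asymmetry_ratio = 0), "asymmetry_ratio")
  expect_error(gait_sim_config(p_double_peak = 1.4), "p_double_peak")
  expect_error(gait_sim_config(step_time_cv = -0.1), "step_time_cv")
})

test_that("sample count and event spacing follow the configured clock", {
  tr <- generate_trial(gait_sim_config(duration = 360,
                                       sampling_jitter_sd = 0, seed = 1))
  expect_length(tr$recording$timestamps, 18001L)
  expect_equal(diff(tr$recording$timestamps), rep(0.02, 18000),
               tolerance = 1e-12)

  tr2 <- generate_trial(clean_config(duration = 60, seed = 2))
  expect_equal(length(tr2$truth_events), 119L)
  expect_equal(tr2$truth_events$times[1], 1.0)   # standing lead-in
  expect_equal(unique(round(diff(tr2$truth_events$times), 9)), 0.5)
})

test_that("identical seeds give bit-identical trials", {
  a <- generate_trial(gait_sim_config(duration = 20, seed = 5))
  b <- generate_trial(gait_sim_config(duration = 20, seed = 5))
  expect_identical(a$recording, b$recording)
  expect_identical(a$truth_events, b$truth_events)
})

test_that("truth events are strictly increasing and within the trial", {
  for (seed in 1:4) {
    tr <- generate_trial(gait_sim_config(duration = 45, seed = seed))
    tt <- tr$truth_events$times
    expect_true(all(diff(tt) > 0))
    expect_true(all(tt >= 0 & tt <= 45))
  }
})

test_that("AP spectrum peaks at the step frequency for regular gait", {
  tr <- generate_trial(clean_config(duration = 60, seed = 7))
  ap <- ap_channel(tr$recording)
  sp <- Mod(stats::fft(ap - mean(ap)))
  n <- length(ap)
  freqs <- (seq_len(n) - 1) * 50 / n
  half <- freqs > 0.1 & freqs <= 25
  expect_equal(freqs[half][which.max(sp[half])], 2, tolerance = 0.05)
})

test_that("each visible step has AP and vertical local maxima at the event", {
  prep <- clean_prep()
  ap <- ap_channel(prep$recording)
  vert <- vertical_channel(prep$recording)
  lag_frames <- round(0.08 * 50)
  is_local_max_near <- function(x, f, tol = 2L) {
    win <- max(2L, f - tol):min(length(x) - 1L, f + tol)
    any(x[win] > x[win - 1L] & x[win] > x[win + 1L])
  }
  # events right at the trial boundary cannot be interior local maxima
  interior <- prep$truth$frames > 3L &
    prep$truth$frames + lag_frames + 3L <= length(ap)
  ap_ok <- vapply(prep$truth$frames[interior], is_local_max_near,
                  logical(1), x = ap)
  v_ok <- vapply(prep$truth$frames[interior] + lag_frames,
                 is_local_max_near, logical(1), x = vert)
  expect_true(all(ap_ok))
  expect_true(all(v_ok))
})

test_that("dropped steps stay in the truth but leave no AP peak", {
  cfg <- gait_sim_config(duration = 90, p_dropped_step = 0.15,
                         p_double_peak = 0, p_weak_peak = 0,
                         noise_sd = 0.02, sampling_jitter_sd = 0, seed = 13)
  tr <- generate_trial(cfg)
  expect_true(any(tr$step_flags$dropped))
  expect_equal(nrow(tr$step_flags), length(tr$truth_events))
  ap <- ap_channel(tr$recording)
  peak_height <- function(tt) {
    f <- round(tt * 50) + 1
    max(ap[max(1, f - 2):min(length(ap), f + 2)])
  }
  dropped_h <- vapply(tr$step_flags$time[tr$step_flags$dropped],
                      peak_height, numeric(1))
  visible_h <- vapply(tr$step_flags$time[!tr$step_flags$dropped],
                      peak_height, numeric(1))
  expect_lt(max(dropped_h), min(visible_h))
})

test_that("positive-label fraction equals the event/frame ratio (a few %)", {
  prep <- clean_prep()
  frac <- mean(prep$labels)
  expect_equal(frac, length(prep$truth$frames) / length(prep$labels))
  # order of magnitude for 0.4-0.7 s steps at 50 Hz: 1/(step_time * rate)
  expect_gt(frac, 0.02)
  expect_lt(frac, 0.05)
})

test_that("write_trial round-trips and is byte-stable", {
  tr <- generate_trial(gait_sim_config(duration = 10, seed = 4))
  d1 <- withr::local_tempdir()
  paths <- write_trial(tr, d1, "t")
  expect_true(all(file.exists(paths)))

  rec <- read_recording(paths["recording"])
  expect_equal(rec$timestamps, tr$recording$timestamps, tolerance = 1e-6)
  expect_equal(rec$linear_accel, tr$recording$linear_accel, tolerance = 1e-6)
  ev <- read_events(paths["events"])
  expect_equal(ev$times, tr$truth_events$times, tolerance = 1e-6)

  d2 <- withr::local_tempdir()
  paths2 <- write_trial(tr, d2, "t")
  expect_identical(readLines(paths["recording"]),
                   readLines(paths2["recording"]))
  expect_identical(readLines(paths["events"]), readLines(paths2["events"]))
})

test_that("a trial without events writes a header-only sidecar", {
  tr <- generate_trial(gait_sim_config(duration = 10, seed = 4))
  tr$truth_events <- fs_events(frames = integer(0))
  d <- withr::local_tempdir()
  paths <- write_trial(tr, d, "empty")
  expect_identical(readLines(paths["events"]), "time")
})
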