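test_that("tolerance matching follows the one-to-one contract", {
  cm <- match_events(fs_events(frames = 100L), fs_events(frames = 102L),
                     1000L, tolerance = 2)
  expect_equal(unlist(cm[c("tp", "fp", "fn")]),
               c(tp = 1, fp = 0, fn = 0))

  cm2 <- match_events(fs_events(frames = 100L), fs_events(frames = 103L),
                      1000L, tolerance = 2)
  expect_equal(unlist(cm2[c("tp", "fp", "fn")]),
               c(tp = 0, fp = 1, fn = 1))

  # two predictions cannot both claim one truth
  cm3 <- match_events(fs_events(frames = c(100L, 101L)),
                      fs_events(frames = 100L), 1000L, tolerance = 2)
  expect_equal(unlist(cm3[c("tp", "fp", "fn")]),
               c(tp = 1, fp = 1, fn = 0))

  expect_equal(cm3$tp + cm3$fp + cm3$fn + cm3$tn, 1000)
  expect_error(match_events(fs_events(frames = 2000L),
                            fs_events(frames = 10L), 1000L), "outside")
})

test_that("tolerance 0 equals frame-wise confusion of the label vectors", {
  set.seed(6)
  for (i in 1:10) {
    n <- 300L
    p <- sort(sample(n, 12))
    t <- sort(sample(n, 15))
    cm <- match_events(fs_events(frames = p), fs_events(frames = t), n,
                       tolerance = 0)
    lp <- events_to_labels(fs_events(frames = p), n)
    lt <- events_to_labels(fs_events(frames = t), n)
    expect_equal(cm$tp, sum(lp == 1 & lt == 1))
    expect_equal(cm$fp, sum(lp == 1 & lt == 0))
    expect_equal(cm$fn, sum(lp == 0 & lt == 1))
    expect_equal(cm$tn, sum(lp == 0 & lt == 0))
  }
})

test_that("swapping predicted and truth swaps fp and fn", {
  set.seed(7)
  for (i in 1:10) {
    n <- 500L
    p <- sort(sample(n, 20))
    t <- sort(sample(n, 25))
    a <- match_events(fs_events(frames = p), fs_events(frames = t), n, 2)
    b <- match_events(fs_events(frames = t), fs_events(frames = p), n, 2)
    expect_equal(a$tp, b$tp)
    expect_equal(a$fp, b$fn)
    expect_equal(a$fn, b$fp)
    expect_equal(a$tn, b$tn)
  }
})

test_that("metrics: perfect classifier and undefined denominators", {
  perfect <- compute_metrics(confusion_counts(tp = 50, fn = 0, fp = 0,
                                              tn = 950))
  expect_equal(unlist(perfect), c(sensitivity = 1, specificity = 1,
                                  accuracy = 1, precision = 1))
  none <- compute_metrics(confusion_counts(tp = 0, fn = 0, fp = 0, tn = 10))
  expect_true(is.na(none$sensitivity))
  expect_true(is.na(none$precision))
  expect_equal(none$accuracy, 1)
  expect_error(confusion_counts(-1, 0, 0, 0), "non-negative")
})

test_that("stride parameters: arithmetic on regular and asymmetric gait", {
  ev <- fs_events(times = c(0, 0.5, 1.0, 1.5))
  sp <- stride_parameters(ev)
  expect_equal(sp$step_times, rep(0.5, 3))
  expect_equal(sp$stride_times, rep(1.0, 2))
  expect_equal(sp$cadence, 120)

  asym <- stride_parameters(fs_events(times = c(0, 0.4, 1.0, 1.4)))
  expect_equal(asym$step_times, c(0.4, 0.6, 0.4))
  expect_equal(asym$stride_times, c(1.0, 1.0))

  # a spurious extra event halving one interval raises cadence
  extra <- stride_parameters(fs_events(times = c(0, 0.25, 0.5, 1.0, 1.5)))
  expect_gt(extra$cadence, sp$cadence)

  expect_error(stride_parameters(fs_events(times = c(0, 0.5))), "3 events")
  # counts: n-1 step times, n-2 stride times
  ev7 <- fs_events(times = cumsum(c(0, rep(0.5, 6))))
  sp7 <- stride_parameters(ev7)
  expect_length(sp7$step_times, 6L)
  expect_length(sp7$stride_times, 5L)
})

test_that("MDC comparison flags clinical equivalence per parameter", {
  ev <- fs_events(times = seq(0, 30, by = 0.5))
  same <- compare_to_mdc(stride_parameters(ev), stride_parameters(ev))
  expect_equal(same$difference, rep(0, 3))
  expect_true(all(same$within_mdc))

  # step-time shift of 1 ms is within the 0.042 s MDC
  shifted <- fs_events(times = seq(0, 30.1, by = 0.501))
  cmp <- compare_to_mdc(stride_parameters(shifted), stride_parameters(ev))
  expect_true(cmp$within_mdc[cmp$parameter == "step_time"])

  # halving every step doubles cadence: far outside the 8.44 steps/min MDC
  fast <- fs_events(times = seq(0, 30, by = 0.25))
  cmp2 <- compare_to_mdc(stride_parameters(fast), stride_parameters(ev))
  expect_false(cmp2$within_mdc[cmp2$parameter == "cadence"])

  expect_equal(mdc_reference(),
               list(step_time = 0.042, stride_time = 0.772, cadence = 8.44))
})

test_that("cross-validation partitions trials and conserves truth events", {
  trials <- lapply(1:10, function(s) {
    prepare_trial(generate_trial(clean_config(duration = 15, seed = 200 + s)))
  })
  # perfect oracle stub: returns the ground-truth labels
  oracle <- function(train_trials) function(trial) trial$labels
  res <- cross_validate(trials, model = "tree", trainer = oracle,
                        k = 5, seed = 3)
  expect_equal(sort(unique(res$folds)), 1:5)
  expect_equal(length(res$folds), 10L)
  # every trial tested exactly once: tp+fn equals the total truth events
  total_truth <- sum(vapply(trials, function(t) length(t$truth$frames),
                            numeric(1)))
  expect_equal(res$counts$tp + res$counts$fn, total_truth)
  expect_equal(res$metrics$accuracy, 1.0)
  expect_equal(res$metrics$sensitivity, 1.0)

  expect_error(cross_validate(trials[1:3], model = "tree", k = 5), "at least")
})

test_that("fold assignment is reproducible under a fixed seed", {
  trials <- lapply(1:6, function(s) {
    prepare_trial(generate_trial(clean_config(duration = 15, seed = 300 + s)))
  })
  oracle <- function(train_trials) function(trial) trial$labels
  r1 <- cross_validate(trials, model = "tree", trainer = oracle, k = 3,
                       seed = 11)
  r2 <- cross_validate(trials, model = "tree", trainer = oracle, k = 3,
                       seed = 11)
  expect_identical(r1$folds, r2$folds)
  expect_identical(unclass(r1$counts), unclass(r2$counts))
})
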