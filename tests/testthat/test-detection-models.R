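test_that("windows: one 31-frame window per frame, with edge rules", {
  f <- matrix(seq_len(100 * 12), 100, 12)
  ds <- make_windows(f, integer(100))
  expect_length(ds, 100L)
  # interior anchor 51: 15 before to 15 after
  expect_equal(ds$starts[51], 36L)
  # early anchor 4: the 30 frames after the anchor
  expect_equal(ds$starts[4], 4L)
  # late anchor 98: the 30 frames before the anchor
  expect_equal(ds$starts[98], 68L)
  expect_true(all(ds$starts >= 1L & ds$starts + 30L <= 100L))
  arr <- window_array(ds, c(4L, 51L, 98L))
  expect_equal(dim(arr), c(3L, 31L, 12L))
  expect_equal(arr[2, , 1], f[36:66, 1])

  expect_error(make_windows(f[1:30, ], integer(30)), "31")
  expect_error(make_windows(f, integer(5)), "per frame")
})

test_that("combined windows never cross trial boundaries", {
  f1 <- matrix(stats::rnorm(50 * 12), 50, 12)
  f2 <- matrix(stats::rnorm(40 * 12), 40, 12)
  ds <- combine_windows(list(make_windows(f1, integer(50)),
                             make_windows(f2, integer(40), trial_id = 2L)))
  expect_length(ds, 90L)
  first_block <- ds$trial_id == 1L
  expect_true(all(ds$starts[first_block] + 30L <= 50L))
  expect_true(all(ds$starts[!first_block] >= 51L))
  expect_equal(window_array(ds, 51L)[1, , ], f2[1:31, ])
})

test_that("decision tree separates a separable toy set at depth 1", {
  X <- cbind(a = c(seq(-3, -1, length.out = 40),
                   seq(1, 3, length.out = 40)),
             b = stats::rnorm(80))
  y <- rep(0:1, each = 40)
  m <- train_decision_tree(X, y, tree_hyperparams(max_depth = 1,
                                                  class_weight_ratio = 1))
  expect_equal(mean(predict_frames(m, X) == y), 1.0)

  # the selected configuration for this task is accepted
  expect_no_error(train_decision_tree(X, y, tree_hyperparams(10, 20)))
  expect_equal(tree_hyperparams()$max_depth, 10L)
  expect_equal(tree_hyperparams()$class_weight_ratio, 20)
})

test_that("tree degenerate cases: constant features, one class", {
  Xc <- matrix(1, 40, 3)
  colnames(Xc) <- c("a", "b", "c")
  yc <- rep(c(0L, 0L, 0L, 1L), 10)
  mc <- train_decision_tree(Xc, yc, tree_hyperparams(2, 1))
  expect_equal(unique(predict_frames(mc, Xc)), 0L)   # majority class
  expect_error(train_decision_tree(Xc, rep(1L, 40)), "both classes")
})

test_that("raising the class weight never lowers tree training sensitivity", {
  set.seed(2)
  X <- cbind(a = stats::rnorm(300), b = stats::rnorm(300))
  y <- as.integer(X[, "a"] + stats::rnorm(300, 0, 0.6) > 1.2)
  sens <- vapply(c(1, 2, 5, 10, 20), function(r) {
    m <- train_decision_tree(X, y, tree_hyperparams(2, r))
    p <- predict_frames(m, X)
    sum(p == 1L & y == 1L) / sum(y == 1L)
  }, numeric(1))
  expect_true(all(diff(sens) >= 0))
})

test_that("LSTM learns a separable windowed toy set", {
  toy <- toy_peak_features(n = 7000, n_pos = 100, seed = 1)
  ds <- make_windows(toy$features, toy$labels)
  set.seed(3)
  sel <- c(toy$pos, sample(which(toy$labels == 0L), 100))
  sub <- structure(list(features = ds$features, starts = ds$starts[sel],
                        anchors = ds$anchors[sel], labels = ds$labels[sel],
                        trial_id = rep(1L, length(sel))),
                   class = "fs_windows")
  hp <- lstm_hyperparams(batch_size = 32, lstm_nodes = 16, dense_nodes = 8,
                         dropout = 0.2, class_weight_ratio = 1, epochs = 20,
                         seed = 42, validation_fraction = 0)
  m <- train_lstm(sub, hp)
  expect_gte(mean(predict_frames(m, sub) == sub$labels), 0.9)

  # fixed seed: training twice gives identical predictions
  m2 <- train_lstm(sub, hp)
  expect_identical(lstm_predict_prob(m, sub), lstm_predict_prob(m2, sub))
})

test_that("default LSTM hyperparameters are the selected configuration", {
  hp <- lstm_hyperparams()
  expect_equal(hp$batch_size, 64L)
  expect_equal(hp$lstm_nodes, 100L)
  expect_equal(hp$dense_nodes, 50L)
  expect_equal(hp$dropout, 0.4)
  expect_equal(hp$class_weight_ratio, 2)
  expect_error(lstm_hyperparams(dropout = 1), "dropout")
  expect_error(train_lstm(
    structure(list(features = matrix(0, 40, 12), starts = rep(1L, 10),
                   anchors = 1:10, labels = rep(0L, 10),
                   trial_id = rep(1L, 10)), class = "fs_windows")),
    "both classes")
})

test_that("class weighting counteracts collapse on imbalanced data", {
  # 97:3 imbalance; count how often each weighting predicts any positive
  fires <- function(ratio, seed) {
    toy <- toy_peak_features(n = 1300, n_pos = 12, seed = seed)
    ds <- make_windows(toy$features, toy$labels)
    hp <- lstm_hyperparams(batch_size = 64, lstm_nodes = 8, dense_nodes = 4,
                           dropout = 0, class_weight_ratio = ratio,
                           epochs = 2, seed = seed,
                           validation_fraction = 0)
    m <- train_lstm(ds, hp)
    sum(predict_frames(m, ds))
  }
  pos_low <- vapply(1:5, function(s) fires(1, s), numeric(1))
  pos_high <- vapply(1:5, function(s) fires(20, s), numeric(1))
  # direction check over seeds: heavier positive weighting fires more,
  # unweighted training collapses toward the majority class more often
  expect_gt(mean(pos_high), mean(pos_low))
  expect_gte(sum(pos_low == 0), sum(pos_high == 0))
})

test_that("predict_frames honours the threshold contract", {
  toy <- toy_peak_features(n = 500, n_pos = 8, seed = 4)
  ds <- make_windows(toy$features, toy$labels)
  hp <- lstm_hyperparams(batch_size = 64, lstm_nodes = 4, dense_nodes = 4,
                         dropout = 0, class_weight_ratio = 1, epochs = 1,
                         seed = 1, validation_fraction = 0)
  m <- train_lstm(ds, hp)
  expect_true(all(predict_frames(m, ds, threshold = 0) == 1L))
  expect_true(all(predict_frames(m, ds, threshold = 1.0001) == 0L))
  expect_length(predict_frames(m, ds), length(ds))
  expect_error(predict_frames(m, ds$features[, 1:5]), "match")
})

test_that("grid search ranks by accuracy with deterministic ties", {
  trials <- lapply(1:4, function(s) {
    prepare_trial(generate_trial(clean_config(duration = 20, seed = 100 + s)))
  })
  grid <- list(max_depth = c(2, 10), class_weight_ratio = c(1, 20))
  res <- grid_search(trials, grid, model = "tree", k = 2, seed = 1)
  expect_equal(nrow(res), 4L)
  expect_equal(res$rank, 1:4)
  expect_true(all(diff(res$accuracy) <= 0))
  # best-of-grid at least matches every member on the ranking key
  expect_true(all(res$accuracy[1] >= res$accuracy))

  res1 <- grid_search(trials, list(max_depth = 10), model = "tree",
                      k = 2, seed = 1)
  expect_equal(nrow(res1), 1L)
  expect_error(grid_search(trials, list(), model = "tree"), "grid")
})
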