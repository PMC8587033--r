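#' Build 31-frame windows for sequence classification
#'
#' Every frame of a trial anchors one window labelled with that frame's
#' label. Interior anchors take 15 frames before through 15 frames after;
#' the first 15 frames instead take the 30 frames after the anchor, and the
#' last 15 take the 30 frames before, so every window has exactly 31 frames.
#' The window size keeps at most one foot strike per window at typical step
#' times.
#'
#' Windows are stored implicitly (feature matrix + per-anchor start index)
#' and materialised in batches during training, which keeps memory flat for
#' long trials.
#'
#' @param features Frames x 12 feature matrix from [assemble_features()].
#' @param labels Per-frame binary labels, same length as `nrow(features)`.
#' @param trial_id Integer tag carried per window (used by
#'   [combine_windows()]).
#' @return An object of class `fs_windows` with fields `features`, `starts`
#'   (window start row per anchor), `anchors`, `labels`, `trial_id`.
#' @export
make_windows <- function(features, labels, trial_id = 1L) {
  n <- nrow(features)
  if (n < 31L)
    stop("need at least 31 frames to build windows", call. = FALSE)
  if (length(labels) != n)
    stop("`labels` must have one entry per frame", call. = FALSE)
  anchors <- seq_len(n)
  starts <- ifelse(anchors <= 15L, anchors,
                   ifelse(anchors >= n - 14L, anchors - 30L, anchors - 15L))
  # trials shorter than 46 frames cannot honour the edge rules exactly;
  # clamp so every window stays inside the trial (no-op for longer trials)
  starts <- pmin(pmax(starts, 1L), n - 30L)
  structure(list(features = features, starts = as.integer(starts),
                 anchors = anchors, labels = as.integer(labels),
                 trial_id = rep(as.integer(trial_id), n)),
            class = "fs_windows")
}

#' @export
length.fs_windows <- function(x) length(x$starts)

#' Materialise selected windows as an array
#'
#' @param dataset An `fs_windows` dataset.
#' @param idx Window indices (default all).
#' @return Array `length(idx)` x 31 x 12.
#' @export
window_array <- function(dataset, idx = seq_along(dataset$starts)) {
  rows <- outer(dataset$starts[idx], 0:30, "+")
  arr <- array(0, dim = c(length(idx), 31L, ncol(dataset$features)))
  for (t in 1:31) arr[, t, ] <- dataset$features[rows[, t], , drop = FALSE]
  arr
}

#' Concatenate windowed datasets from several trials
#'
#' Row-offsets each trial's feature block so windows never cross trial
#' boundaries.
#'
#' @param datasets List of `fs_windows` objects.
#' @return A single `fs_windows` object.
#' @export
combine_windows <- function(datasets) {
  stopifnot(length(datasets) >= 1L)
  offset <- 0L
  feats <- vector("list", length(datasets))
  starts <- anchors <- labels <- tid <- vector("list", length(datasets))
  for (i in seq_along(datasets)) {
    d <- datasets[[i]]
    feats[[i]] <- d$features
    starts[[i]] <- d$starts + offset
    anchors[[i]] <- d$anchors
    labels[[i]] <- d$labels
    tid[[i]] <- rep(as.integer(i), length(d$starts))
    offset <- offset + nrow(d$features)
  }
  structure(list(features = do.call(rbind, feats),
                 starts = unlist(starts), anchors = unlist(anchors),
                 labels = unlist(labels), trial_id = unlist(tid)),
            class = "fs_windows")
}

#' Decision-tree hyperparameters
#'
#' The per-frame decision tree classifies each frame from its 12 signal
#' values alone. `class_weight_ratio` is the training weight of the rare
#' "foot strike" class relative to the background class (grid 2, 5, 10, 20).
#' Defaults are the best configuration found for this task: depth 10,
#' weighting 1:20.
#'
#' @param max_depth Maximum tree depth (>= 1).
#' @param class_weight_ratio Positive-class weight (> 0).
#' @return An object of class `tree_hyperparams`.
#' @export
tree_hyperparams <- function(max_depth = 10, class_weight_ratio = 20) {
  stopifnot(max_depth >= 1, class_weight_ratio > 0)
  structure(list(max_depth = as.integer(max_depth),
                 class_weight_ratio = class_weight_ratio),
            class = "tree_hyperparams")
}

#' Train the per-frame decision tree
#'
#' Fits a CART classifier on single-frame 12-feature vectors with the
#' positive class up-weighted by `hp$class_weight_ratio`. The tree is grown
#' to the depth limit (no complexity-based pruning) so that depth is the
#' binding capacity control, mirroring common practice for this classifier.
#'
#' @param features Frames x 12 matrix.
#' @param labels Binary per-frame labels.
#' @param hp A [tree_hyperparams()].
#' @return An object of class `fs_tree_model`.
#' @export
train_decision_tree <- function(features, labels, hp = tree_hyperparams()) {
  stopifnot(inherits(hp, "tree_hyperparams"))
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("training data must contain both classes", call. = FALSE)
  df <- as.data.frame(features)
  df$.y <- factor(labels, levels = c(0L, 1L))
  w <- ifelse(labels == 1L, hp$class_weight_ratio, 1)
  fit <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                      control = rpart::rpart.control(
                        maxdepth = hp$max_depth, cp = 0,
                        minsplit = 2, minbucket = 1, xval = 0))
  structure(list(fit = fit, hp = hp,
                 feature_names = colnames(df)[colnames(df) != ".y"]),
            class = "fs_tree_model")
}

#' Per-frame predictions from a trained model
#'
#' Thresholds the model's class-1 probability at `threshold` and returns one
#' binary label per frame. For the LSTM, window predictions are mapped back
#' to their anchor frames.
#'
#' @param model An `fs_tree_model` or `fs_lstm_model`.
#' @param newdata A feature matrix (tree or LSTM; the LSTM windows it
#'   internally) or an `fs_windows` dataset (LSTM).
#' @param threshold Decision threshold on the class-1 probability.
#' @return Integer 0/1 labels, one per frame / anchor.
#' @export
predict_frames <- function(model, newdata, threshold = 0.5) {
  UseMethod("predict_frames")
}

#' @export
predict_frames.fs_tree_model <- function(model, newdata, threshold = 0.5) {
  if (inherits(newdata, "fs_windows"))
    stop("the decision tree consumes per-frame features, not windows",
         call. = FALSE)
  df <- as.data.frame(newdata)
  if (!all(model$feature_names %in% colnames(df)))
    stop("feature columns do not match the training features", call. = FALSE)
  p <- stats::predict(model$fit, df)[, "1"]
  as.integer(p >= threshold)
}

#' @export
predict_frames.fs_lstm_model <- function(model, newdata, threshold = 0.5) {
  if (is.matrix(newdata)) {
    newdata <- make_windows(newdata, integer(nrow(newdata)))
  }
  stopifnot(inherits(newdata, "fs_windows"))
  p <- lstm_predict_prob(model, newdata)
  as.integer(p >= threshold)
}

#' Hyperparameter grid search with grouped cross-validation
#'
#' Evaluates every combination in `grid` with [cross_validate()] (the full
#' corrected pipeline: predict, band-collapse, missed-step insertion,
#' tolerance matching) and ranks configurations by pooled accuracy, breaking
#' ties by sensitivity then precision.
#'
#' @param trials List of labelled trials as accepted by [cross_validate()].
#' @param grid Named list of hyperparameter value vectors, e.g.
#'   `list(max_depth = c(5, 10), class_weight_ratio = c(2, 20))`.
#' @param model `"tree"` or `"lstm"`.
#' @param hp_base Baseline hyperparameters, overridden per combination.
#' @param k Number of folds.
#' @param seed RNG seed for fold assignment (and LSTM training).
#' @param ... Passed to [cross_validate()].
#' @return Data frame of configurations with pooled metrics, ranked best
#'   first.
#' @export
grid_search <- function(trials, grid, model = c("tree", "lstm"),
                        hp_base = NULL, k = 2, seed = 1L, ...) {
  model <- match.arg(model)
  if (!length(grid) || !all(lengths(grid) >= 1L))
    stop("`grid` must be a non-empty named list of value vectors",
         call. = FALSE)
  combos <- expand.grid(grid, stringsAsFactors = FALSE)
  if (is.null(hp_base)) {
    hp_base <- if (model == "tree") tree_hyperparams() else lstm_hyperparams()
  }
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    hp <- utils::modifyList(unclass(hp_base), as.list(combos[i, , drop = FALSE]))
    class(hp) <- class(hp_base)
    res <- cross_validate(trials, model = model, hp = hp, k = k,
                          seed = seed, ...)
    cbind(combos[i, , drop = FALSE],
          as.data.frame(res$metrics[c("accuracy", "sensitivity",
                                      "precision", "specificity")]))
  })
  out <- do.call(rbind, rows)
  ord <- order(-out$accuracy, -out$sensitivity, -out$precision)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
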