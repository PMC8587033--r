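#' Tolerance-matched event confusion counts
#'
#' Matches predicted to ground-truth foot strikes one-to-one within a
#' temporal tolerance (default +/-2 frames = +/-0.04 s at 50 Hz). Candidate
#' pairs are accepted greedily in order of increasing frame offset, ties
#' going to the earlier truth event. Matched pairs count as true positives,
#' unmatched predictions as false positives, unmatched truths as false
#' negatives, and every remaining frame as a true negative, so
#' `tp + fn + fp + tn = total_frames`.
#'
#' With `tolerance = 0` this reduces exactly to the frame-wise confusion of
#' the two binary label sequences.
#'
#' @param predicted,truth [fs_events] objects (sorted, within range).
#' @param total_frames Number of frames in the trial.
#' @param tolerance Matching tolerance in frames.
#' @return An object of class `confusion_counts`: list with `tp`, `fn`,
#'   `fp`, `tn`.
#' @export
match_events <- function(predicted, truth, total_frames, tolerance = 2) {
  stopifnot(inherits(predicted, "fs_events"), inherits(truth, "fs_events"))
  p <- predicted$frames
  t <- truth$frames
  if ((length(p) && (min(p) < 1L || max(p) > total_frames)) ||
      (length(t) && (min(t) < 1L || max(t) > total_frames)))
    stop("events outside [1, total_frames]", call. = FALSE)

  tp <- 0L
  if (length(p) && length(t)) {
    cand_p <- integer(0); cand_t <- integer(0); cand_d <- integer(0)
    for (ti in seq_along(t)) {
      near <- which(abs(p - t[ti]) <= tolerance)
      cand_p <- c(cand_p, near)
      cand_t <- c(cand_t, rep(ti, length(near)))
      cand_d <- c(cand_d, abs(p[near] - t[ti]))
    }
    if (length(cand_p)) {
      ord <- order(cand_d, cand_t, cand_p)
      used_p <- logical(length(p))
      used_t <- logical(length(t))
      for (k in ord) {
        if (!used_p[cand_p[k]] && !used_t[cand_t[k]]) {
          used_p[cand_p[k]] <- TRUE
          used_t[cand_t[k]] <- TRUE
          tp <- tp + 1L
        }
      }
    }
  }
  fp <- length(p) - tp
  fn <- length(t) - tp
  confusion_counts(tp = tp, fn = fn, fp = fp,
                   tn = total_frames - tp - fp - fn)
}

#' @rdname match_events
#' @param tp,fn,fp,tn Non-negative integer counts.
#' @export
confusion_counts <- function(tp, fn, fp, tn) {
  counts <- list(tp = as.numeric(tp), fn = as.numeric(fn),
                 fp = as.numeric(fp), tn = as.numeric(tn))
  if (any(unlist(counts) < 0))
    stop("confusion counts must be non-negative", call. = FALSE)
  structure(counts, class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, accuracy
#' `(tp+tn)/total` and precision `tp/(tp+fp)`, as fractions. A metric whose
#' denominator is zero is returned as `NA` (undefined), never as 0.
#'
#' @param counts A `confusion_counts` object.
#' @return An object of class `fs_metrics` (named list of fractions).
#' @export
compute_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  frac <- function(num, den) if (den > 0) num / den else NA_real_
  total <- counts$tp + counts$fn + counts$fp + counts$tn
  structure(list(
    sensitivity = frac(counts$tp, counts$tp + counts$fn),
    specificity = frac(counts$tn, counts$tn + counts$fp),
    accuracy = frac(counts$tp + counts$tn, total),
    precision = frac(counts$tp, counts$tp + counts$fp)
  ), class = "fs_metrics")
}

#' @export
print.fs_metrics <- function(x, ...) {
  for (nm in names(x)) {
    cat(sprintf("%-12s %s\n", nm,
                if (is.na(x[[nm]])) "undefined" else
                  sprintf("%.1f%%", 100 * x[[nm]])))
  }
  invisible(x)
}

#' Stride parameters from a foot-strike sequence
#'
#' Step time is the interval between consecutive foot strikes (opposite
#' feet), stride time between alternate foot strikes (same foot), and
#' cadence the mean instantaneous cadence `60 / step_time` in steps/min.
#' The mean-of-instantaneous definition makes cadence sensitive to spurious
#' or missed events, which is exactly what the evaluation needs to surface;
#' `60 * n_steps / duration` is available via `cadence_method = "global"`.
#'
#' @param events An [fs_events] with at least 3 events.
#' @param cadence_method `"instantaneous"` (default) or `"global"`.
#' @return An object of class `stride_parameters`: `step_times` (n-1),
#'   `stride_times` (n-2), `cadence` (scalar, steps/min).
#' @export
stride_parameters <- function(events,
                              cadence_method = c("instantaneous", "global")) {
  stopifnot(inherits(events, "fs_events"))
  cadence_method <- match.arg(cadence_method)
  tt <- events$times
  if (length(tt) < 3L)
    stop("need at least 3 events for stride parameters", call. = FALSE)
  step_times <- diff(tt)
  stride_times <- tt[-(1:2)] - tt[seq_len(length(tt) - 2L)]
  cadence <- if (cadence_method == "instantaneous") mean(60 / step_times)
             else 60 * length(step_times) / (tt[length(tt)] - tt[1])
  structure(list(step_times = step_times, stride_times = stride_times,
                 cadence = cadence),
            class = "stride_parameters")
}

#' Minimal detectable change reference values
#'
#' MDC of stride parameters for healthy older adults, used as the clinical
#' equivalence threshold: step time 0.042 s, stride time 0.772 s, cadence
#' 8.44 steps/min.
#'
#' @return Named list of MDC values.
#' @export
mdc_reference <- function() {
  list(step_time = 0.042, stride_time = 0.772, cadence = 8.44)
}

#' Compare predicted and ground-truth stride parameters against MDC
#'
#' Computes the mean difference (predicted minus truth) for step time,
#' stride time and cadence, and flags each parameter as clinically
#' equivalent when the absolute difference does not exceed its minimal
#' detectable change.
#'
#' @param pred_params,truth_params [stride_parameters()] from the same trial.
#' @param mdc MDC values, as from [mdc_reference()].
#' @return Data frame with columns `parameter`, `difference`, `mdc`,
#'   `within_mdc`.
#' @export
compare_to_mdc <- function(pred_params, truth_params, mdc = mdc_reference()) {
  stopifnot(inherits(pred_params, "stride_parameters"),
            inherits(truth_params, "stride_parameters"))
  diffs <- c(step_time = mean(pred_params$step_times) -
               mean(truth_params$step_times),
             stride_time = mean(pred_params$stride_times) -
               mean(truth_params$stride_times),
             cadence = pred_params$cadence - truth_params$cadence)
  data.frame(parameter = names(diffs),
             difference = unname(diffs),
             mdc = unname(unlist(mdc[names(diffs)])),
             within_mdc = unname(abs(diffs) <= unlist(mdc[names(diffs)])),
             row.names = NULL)
}

#' Prepare a simulated trial for training and evaluation
#'
#' Resamples to the uniform grid, low-pass filters, assembles the feature
#' matrix and converts the ground truth to per-frame labels (events beyond
#' the resampled grid, possible at the trial boundary under timestamp
#' jitter, are dropped).
#'
#' @param trial A `simulated_trial` from [generate_trial()].
#' @param rate Uniform rate, Hz.
#' @param spec A [filter_spec()].
#' @return A list with `recording` (uniform, filtered), `features`,
#'   `labels`, `truth` ([fs_events]).
#' @export
prepare_trial <- function(trial, rate = 50, spec = filter_spec(rate = rate)) {
  stopifnot(inherits(trial, "simulated_trial"))
  rec <- preprocess_recording(trial$recording, rate, spec)
  n <- length(rec$timestamps)
  keep <- trial$truth_events$frames >= 1L & trial$truth_events$frames <= n
  truth <- fs_events(frames = trial$truth_events$frames[keep], rate = rate,
                     t0 = rec$timestamps[1])
  list(recording = rec,
       features = assemble_features(rec),
       labels = events_to_labels(truth, n),
       truth = truth)
}

#' Grouped k-fold cross-validation of the detection pipeline
#'
#' Partitions trials (participants) -- never frames -- into `k` folds. For
#' each fold the model is trained on the remaining folds, applied to the
#' held-out trials, post-processed (band collapse + missed-step insertion)
#' and matched against ground truth within the tolerance. Confusion counts
#' are pooled over folds before computing metrics (micro-averaging), and
#' both corrected and uncorrected results are reported so the effect of the
#' corrections is visible.
#'
#' @param trials List of prepared trials from [prepare_trial()].
#' @param model `"tree"` or `"lstm"`.
#' @param hp Hyperparameters ([tree_hyperparams()] / [lstm_hyperparams()]);
#'   defaults to the best known configuration for the chosen model.
#' @param k Number of folds; requires at least `k` trials.
#' @param seed Seed for fold assignment and per-fold model seeds.
#' @param tolerance Matching tolerance, frames.
#' @param threshold Classifier decision threshold.
#' @param rate Frame rate, Hz.
#' @param trainer Optional override: `function(train_trials)` returning a
#'   `function(trial)` that emits per-frame labels (used for stubs and
#'   ablations).
#' @param verbose Print per-fold progress.
#' @return An object of class `fs_evaluation`: pooled `counts`, `metrics`,
#'   `counts_uncorrected`, `metrics_uncorrected`, per-trial `stride`
#'   comparison, `folds` assignment.
#' @export
cross_validate <- function(trials, model = c("tree", "lstm"), hp = NULL,
                           k = 5, seed = 1L, tolerance = 2, threshold = 0.5,
                           rate = 50, trainer = NULL, verbose = FALSE) {
  model <- match.arg(model)
  n_trials <- length(trials)
  if (n_trials < k)
    stop(sprintf("need at least k = %d trials, got %d", k, n_trials),
         call. = FALSE)
  if (is.null(hp)) {
    hp <- if (model == "tree") tree_hyperparams() else lstm_hyperparams()
  }
  set.seed(seed)
  folds <- sample(rep(seq_len(k), length.out = n_trials))

  zero <- confusion_counts(0, 0, 0, 0)
  pool <- list(corr = zero, raw = zero)
  add_counts <- function(a, b) {
    confusion_counts(a$tp + b$tp, a$fn + b$fn, a$fp + b$fp, a$tn + b$tn)
  }
  stride_rows <- list()

  for (j in seq_len(k)) {
    train_trials <- trials[folds != j]
    test_trials <- trials[folds == j]
    if (verbose) message(sprintf("fold %d/%d: training on %d trials",
                                 j, k, length(train_trials)))
    predict_one <- if (!is.null(trainer)) {
      trainer(train_trials)
    } else if (model == "tree") {
      feats <- do.call(rbind, lapply(train_trials, `[[`, "features"))
      labs <- unlist(lapply(train_trials, `[[`, "labels"))
      fit <- train_decision_tree(feats, labs, hp)
      function(trial) predict_frames(fit, trial$features, threshold)
    } else {
      ds <- combine_windows(lapply(seq_along(train_trials), function(i) {
        tr <- train_trials[[i]]
        make_windows(tr$features, tr$labels, trial_id = i)
      }))
      hp_fold <- hp
      hp_fold$seed <- hp$seed + j
      fit <- train_lstm(ds, hp_fold)
      function(trial) predict_frames(fit, make_windows(trial$features,
                                                       trial$labels),
                                     threshold)
    }
    for (trial in test_trials) {
      n <- nrow(trial$features)
      labels <- predict_one(trial)
      raw_events <- labels_to_events(labels, rate = rate,
                                     t0 = trial$recording$timestamps[1])
      corr_events <- correct_predictions(labels, trial$recording, rate = rate)
      pool$raw <- add_counts(pool$raw,
                             match_events(raw_events, trial$truth, n,
                                          tolerance))
      pool$corr <- add_counts(pool$corr,
                              match_events(corr_events, trial$truth, n,
                                           tolerance))
      if (length(corr_events$frames) >= 3L &&
          length(trial$truth$frames) >= 3L) {
        cmp <- compare_to_mdc(stride_parameters(corr_events),
                              stride_parameters(trial$truth))
        cmp$trial <- trial$recording$participant_id
        cmp$fold <- j
        stride_rows[[length(stride_rows) + 1L]] <- cmp
      }
    }
  }

  structure(list(
    counts = pool$corr,
    metrics = compute_metrics(pool$corr),
    counts_uncorrected = pool$raw,
    metrics_uncorrected = compute_metrics(pool$raw),
    stride = if (length(stride_rows)) do.call(rbind, stride_rows) else NULL,
    folds = folds,
    model = model,
    tolerance = tolerance
  ), class = "fs_evaluation")
}

#' @export
print.fs_evaluation <- function(x, ...) {
  cat(sprintf("<fs_evaluation> %s model, +/-%d-frame tolerance\n",
              x$model, x$tolerance))
  cat("corrected:\n"); print(x$metrics)
  cat("uncorrected:\n"); print(x$metrics_uncorrected)
  invisible(x)
}
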