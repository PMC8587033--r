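#' Collapse banded consecutive foot-strike predictions
#'
#' Per-frame classifiers tend to fire on several consecutive frames around a
#' single true foot strike, giving predictions a "banded" appearance. Every
#' maximal run of two or more consecutive 1-labels is replaced by a single 1
#' at the frame of maximum AP acceleration within the run (ties broken
#' toward the earlier frame, i.e. closer to initial contact). Isolated 1s
#' are preserved exactly, so the operation is idempotent and never increases
#' the number of positive labels.
#'
#' @param labels Binary per-frame labels.
#' @param ap AP linear acceleration, same length.
#' @return Corrected binary labels with no two adjacent 1s.
#' @export
collapse_bands <- function(labels, ap) {
  if (length(labels) != length(ap))
    stop("`labels` and `ap` must have equal length", call. = FALSE)
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L)))
    stop("labels must be binary (0/1)", call. = FALSE)
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- labels
  for (k in which(r$values == 1L & r$lengths >= 2L)) {
    run <- starts[k]:ends[k]
    out[run] <- 0L
    out[run[which.max(ap[run])]] <- 1L
  }
  out
}

#' Per-trial locking period from early vertical acceleration
#'
#' Estimates a refractory ("locking") period from the first 5 s of the
#' filtered vertical acceleration: intervals between successive positive
#' (upward) zero crossings of the mean-centred signal are computed, and with
#' `M` their maximum and `m` their mean the period is
#' \itemize{
#'   \item `M / 2` by default,
#'   \item `m / 2` if `M > 0.6` s (long-interval rule),
#'   \item `2 * M` if `M < 0.3` s (short-interval rule).
#' }
#' Boundary values (`M` exactly 0.3 or 0.6 s) use the default rule. The
#' locking period shrinks the search window when inserting missed steps so
#' inserted events cannot sit implausibly close to their neighbours.
#'
#' @param vertical Filtered vertical acceleration on the uniform grid.
#' @param rate Frame rate, Hz.
#' @param sample_seconds Length of the leading sample used, seconds.
#' @return An object of class `locking_period` with fields `value` (seconds)
#'   and `rule_used` (`"default"`, `"long_interval"`, `"short_interval"`),
#'   or `NULL` with a warning if fewer than 3 positive zero crossings are
#'   found (correction is then skipped).
#' @export
compute_locking_period <- function(vertical, rate = 50, sample_seconds = 5) {
  n_need <- round(sample_seconds * rate)
  if (length(vertical) < n_need)
    stop(sprintf("need at least %g s of signal", sample_seconds),
         call. = FALSE)
  v <- vertical[seq_len(n_need)]
  v <- v - mean(v)
  up <- which(v[-length(v)] < 0 & v[-1] >= 0)
  if (length(up) < 3L) {
    warning("fewer than 3 positive zero crossings in the leading sample; ",
            "missed-step correction disabled", call. = FALSE)
    return(NULL)
  }
  # sub-frame crossing times by linear interpolation
  tc <- (up - 1 + v[up] / (v[up] - v[up + 1])) / rate
  intervals <- diff(tc)
  M <- max(intervals)
  m <- mean(intervals)
  if (M > 0.6) {
    value <- m / 2; rule <- "long_interval"
  } else if (M < 0.3) {
    value <- 2 * M; rule <- "short_interval"
  } else {
    value <- M / 2; rule <- "default"
  }
  structure(list(value = value, rule_used = rule, intervals = intervals),
            class = "locking_period")
}

#' Insert missed steps into a predicted event sequence
#'
#' Scans consecutive event intervals left to right, starting at the second
#' interval (the first has no previous step to compare against). An
#' interval is a gap when its duration exceeds 1.5 times the previous
#' interval. The gap is shrunk by half the locking period at each end --
#' so an inserted step cannot sit right on an existing event -- and a new
#' event is placed at the frame of maximum AP acceleration within the
#' shrunken window.
#'
#' Gaps are identified from the original event sequence; after an
#' insertion the scan resumes over the sub-intervals it created, still
#' judged against the interval that preceded the gap, so a gap spanning
#' several missed steps is filled step by step. Intervals created by an
#' insertion never serve as the reference for later gap decisions --
#' otherwise one spurious short interval would make every following normal
#' step look like a gap and trigger a cascade of insertions. A hard cap of
#' 3x the initial event count guarantees termination. Events are never
#' removed.
#'
#' @param events Predicted [fs_events].
#' @param ap AP linear acceleration covering all event frames.
#' @param lock A `locking_period` (or `NULL` to skip correction).
#' @param rate Frame rate, Hz.
#' @param gap_factor Gap threshold as a multiple of the previous interval.
#' @return Corrected [fs_events].
#' @export
insert_missed_steps <- function(events, ap, lock, rate = 50,
                                gap_factor = 1.5) {
  stopifnot(inherits(events, "fs_events"))
  if (is.null(lock)) return(events)
  stopifnot(inherits(lock, "locking_period"))
  f0 <- events$frames
  if (length(f0) >= 2L && any(diff(f0) <= 0))
    stop("events must be sorted and strictly increasing", call. = FALSE)
  if (length(f0) && max(f0) > length(ap))
    stop("`ap` must cover all event frames", call. = FALSE)
  if (length(f0) < 3L) return(events)

  half_lock <- round(lock$value / 2 * rate)
  cap <- 3L * length(f0)
  inserted <- integer(0)
  for (j in 2L:(length(f0) - 1L)) {
    ref <- f0[j] - f0[j - 1L]
    if (!(f0[j + 1L] - f0[j] > gap_factor * ref)) next
    # fill this gap, re-scanning the sub-intervals each insertion creates
    seg <- c(f0[j], f0[j + 1L])
    i <- 1L
    while (i < length(seg) &&
           length(f0) + length(inserted) < cap) {
      lo <- seg[i] + half_lock
      hi <- seg[i + 1L] - half_lock
      if (seg[i + 1L] - seg[i] > gap_factor * ref && lo < hi) {
        win <- lo:hi
        ins <- win[which.max(ap[win])]
        if (ins > seg[i] && ins < seg[i + 1L]) {
          seg <- sort(c(seg, ins))
          inserted <- c(inserted, ins)
          next
        }
      }
      i <- i + 1L
    }
  }
  fs_events(frames = sort(unique(c(f0, inserted))),
            rate = events$rate, t0 = events$t0)
}

#' Apply both post-processing corrections
#'
#' Band collapse first, then missed-step insertion with the trial's locking
#' period -- the order the corrections were designed in. The AP channel used
#' for peak picking and the vertical channel used for the locking period are
#' taken from the (uniform, filtered) recording.
#'
#' @param labels Predicted per-frame binary labels.
#' @param recording The matching uniform, filtered [imu_recording].
#' @param rate Frame rate, Hz.
#' @param band_fix,gap_fix Toggles for the two corrections (ablation).
#' @return Corrected [fs_events].
#' @export
correct_predictions <- function(labels, recording, rate = 50,
                                band_fix = TRUE, gap_fix = TRUE) {
  stopifnot(inherits(recording, "imu_recording"))
  if (!recording$is_uniform)
    stop("recording must be uniform (resampled) before correction",
         call. = FALSE)
  ap <- ap_channel(recording)
  if (length(labels) != length(ap))
    stop("labels length must match the recording", call. = FALSE)
  if (band_fix) labels <- collapse_bands(labels, ap)
  events <- labels_to_events(labels, rate = rate,
                             t0 = recording$timestamps[1])
  if (gap_fix && length(events$frames) >= 3L) {
    lock <- tryCatch(compute_locking_period(vertical_channel(recording), rate),
                     error = function(e) NULL)
    events <- insert_missed_steps(events, ap, lock, rate = rate)
  }
  events
}
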