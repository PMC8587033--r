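#' Foot-strike event list
#'
#' An ordered set of foot-strike events for one trial, carried both as
#' 1-based frame indices on the uniform grid and as times in seconds
#' (`time = (frame - 1) / rate + t0`). Supply either frames or times.
#'
#' @param frames 1-based integer frame indices, strictly increasing.
#' @param times Event times in seconds, strictly increasing.
#' @param rate Frame rate, Hz.
#' @param t0 Time of frame 1, seconds.
#' @return An object of class `fs_events` with fields `frames`, `times`,
#'   `rate`, `t0`.
#' @export
fs_events <- function(frames = NULL, times = NULL, rate = 50, t0 = 0) {
  if (is.null(frames) && is.null(times))
    stop("supply `frames` or `times`", call. = FALSE)
  if (is.null(frames)) {
    times <- as.numeric(times)
    frames <- as.integer(round((times - t0) * rate)) + 1L
  } else {
    frames <- as.integer(frames)
    if (is.null(times)) times <- (frames - 1) / rate + t0
  }
  if (length(frames) >= 2L && any(diff(frames) <= 0))
    stop("events must be strictly increasing", call. = FALSE)
  structure(list(frames = frames, times = as.numeric(times),
                 rate = rate, t0 = t0),
            class = "fs_events")
}

#' @export
print.fs_events <- function(x, ...) {
  cat(sprintf("<fs_events> %d events", length(x$frames)))
  if (length(x$frames))
    cat(sprintf(" spanning %.2f-%.2f s", x$times[1],
                x$times[length(x$times)]))
  cat("\n")
  invisible(x)
}

#' @export
length.fs_events <- function(x) length(x$frames)

#' Convert events to per-frame binary labels
#'
#' `labels[f] = 1` exactly at event frames; every other frame is 0
#' ("no foot strike present").
#'
#' @param events An [fs_events] object.
#' @param n_frames Total number of frames in the trial.
#' @return Integer vector of 0/1 labels, length `n_frames`.
#' @export
events_to_labels <- function(events, n_frames) {
  stopifnot(inherits(events, "fs_events"))
  f <- events$frames
  if (length(f) && (min(f) < 1L || max(f) > n_frames))
    stop("event frame outside [1, n_frames]", call. = FALSE)
  labels <- integer(n_frames)
  labels[f] <- 1L
  labels
}

#' Convert per-frame binary labels to events
#'
#' @param labels Integer/numeric vector with values in `{0, 1}`.
#' @param rate Frame rate, Hz (attached to the returned events).
#' @param t0 Time of frame 1, seconds.
#' @return An [fs_events] object listing the 1-labelled frames in order.
#' @export
labels_to_events <- function(labels, rate = 50, t0 = 0) {
  if (length(labels) && !all(labels %in% c(0, 1)))
    stop("labels must be binary (0/1)", call. = FALSE)
  fs_events(frames = which(labels == 1), rate = rate, t0 = t0)
}

#' Parameters for the peak-pair labelling rule
#'
#' The rule identifies anterior-posterior (AP) acceleration peaks that are
#' immediately followed by a vertical acceleration peak -- the signature of a
#' foot strike at the pelvis. Defaults: peaks at least 0.3 s apart (below
#' the shortest plausible step with margin), a vertical peak within 0.25 s,
#' and prominence at least half the median absolute deviation of the AP
#' signal (`NULL` = derive from the signal).
#'
#' @param min_separation Minimum spacing between accepted AP peaks, seconds.
#' @param max_lag Maximum delay of the confirming vertical peak, seconds.
#' @param prominence Minimum AP peak prominence, m/s^2, or `NULL` to use
#'   `0.5 * median(|ap - median(ap)|)`.
#' @return An object of class `peak_rule_params`.
#' @export
peak_rule_params <- function(min_separation = 0.3, max_lag = 0.25,
                             prominence = NULL) {
  stopifnot(min_separation > 0, max_lag > 0)
  structure(list(min_separation = min_separation, max_lag = max_lag,
                 prominence = prominence),
            class = "peak_rule_params")
}

#' Automatic ground-truth labelling by the peak-pair rule
#'
#' Finds local maxima of the filtered AP acceleration with minimum
#' prominence and separation, and keeps a peak as a foot strike iff a local
#' maximum of the filtered vertical acceleration occurs within
#' `(0, max_lag]` seconds after it. When two candidate peaks compete within
#' `min_separation` (e.g. a gait-aid double peak), the higher peak wins.
#'
#' @param ap Filtered AP linear acceleration, uniform grid.
#' @param vertical Filtered vertical linear acceleration, same grid.
#' @param params A [peak_rule_params()].
#' @param rate Frame rate, Hz.
#' @return An [fs_events] object with the kept AP-peak frames.
#' @export
auto_label_peak_rule <- function(ap, vertical, params = peak_rule_params(),
                                 rate = 50) {
  if (length(ap) != length(vertical))
    stop("`ap` and `vertical` must have equal length", call. = FALSE)
  stopifnot(inherits(params, "peak_rule_params"))
  prom <- params$prominence
  if (is.null(prom)) prom <- 0.5 * stats::median(abs(ap - stats::median(ap)))
  min_dist <- max(1L, round(params$min_separation * rate))

  ap_pk <- find_local_maxima(ap, min_dist = min_dist, min_prom = prom)
  if (!length(ap_pk)) return(fs_events(frames = integer(0), rate = rate))
  v_pk <- find_local_maxima(vertical, min_dist = 1L, min_prom = 0)
  max_lag_frames <- round(params$max_lag * rate)
  keep <- vapply(ap_pk, function(p) {
    any(v_pk > p & v_pk <= p + max_lag_frames)
  }, logical(1))
  fs_events(frames = ap_pk[keep], rate = rate)
}

# local maxima with minimum prominence and minimum separation; when peaks
# conflict within min_dist the higher peak is kept (pracma sorts candidates
# by height before suppression)
find_local_maxima <- function(x, min_dist = 1L, min_prom = 0) {
  if (length(x) < 3L) return(integer(0))
  pk <- pracma::findpeaks(x, minpeakdistance = max(1L, min_dist),
                          minpeakheight = -Inf, nups = 1, ndowns = 1)
  if (is.null(pk)) return(integer(0))
  idx <- pk[, 2]
  if (min_prom > 0) {
    keep <- vapply(seq_along(idx), function(k) {
      peak_prominence(x, idx[k]) >= min_prom
    }, logical(1))
    idx <- idx[keep]
  }
  sort(as.integer(idx))
}

# topographic prominence of the peak at index i: height above the higher of
# the two saddles separating it from taller terrain on each side
peak_prominence <- function(x, i) {
  h <- x[i]
  n <- length(x)
  lmin <- if (i > 1L) {
    left <- x[seq_len(i - 1L)]
    taller <- which(left >= h)
    min(if (length(taller)) left[seq.int(max(taller), i - 1L)] else left)
  } else h
  rmin <- if (i < n) {
    right <- x[seq.int(i + 1L, n)]
    taller <- which(right >= h)
    min(if (length(taller)) right[seq_len(min(taller))] else right)
  } else h
  h - max(lmin, rmin)
}
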