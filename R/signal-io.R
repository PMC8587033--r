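#' IMU recording container
#'
#' A 12-channel inertial trace for one walking trial: raw acceleration,
#' linear (gravity-removed, as supplied by the smartphone API) acceleration,
#' angular velocity and orientation, each with x/y/z components, plus
#' timestamps. Axis convention throughout: x = medio-lateral, y = vertical,
#' z = anterior-posterior, body frame.
#'
#' @param timestamps Strictly increasing sample times, seconds.
#' @param raw_accel,linear_accel n x 3 matrices, m/s^2 (columns x, y, z).
#' @param angular_velocity n x 3 matrix, rad/s.
#' @param orientation n x 3 matrix, rad.
#' @param participant_id Identifier string.
#' @param is_uniform Whether the recording sits on a uniform grid
#'   (set by [resample_to_uniform()]).
#' @param is_filtered Whether channels have been low-pass filtered
#'   (set by [filter_recording()]).
#' @return An object of class `imu_recording`.
#' @export
imu_recording <- function(timestamps, raw_accel, linear_accel,
                          angular_velocity, orientation,
                          participant_id = "unknown",
                          is_uniform = FALSE, is_filtered = FALSE) {
  n <- length(timestamps)
  chans <- list(raw_accel = raw_accel, linear_accel = linear_accel,
                angular_velocity = angular_velocity, orientation = orientation)
  for (nm in names(chans)) {
    m <- as.matrix(chans[[nm]])
    if (nrow(m) != n || ncol(m) != 3L)
      stop(sprintf("`%s` must be a %d x 3 matrix", nm, n), call. = FALSE)
    colnames(m) <- c("x", "y", "z")
    chans[[nm]] <- m
  }
  if (n >= 2L && any(diff(timestamps) <= 0))
    stop("timestamps must be strictly increasing", call. = FALSE)
  structure(c(list(timestamps = as.numeric(timestamps)), chans,
              list(participant_id = participant_id,
                   is_uniform = isTRUE(is_uniform),
                   is_filtered = isTRUE(is_filtered))),
            class = "imu_recording")
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording> %s: %d samples over %.2f s%s%s\n",
              x$participant_id, length(x$timestamps),
              diff(range(x$timestamps)),
              if (x$is_uniform) ", uniform" else "",
              if (x$is_filtered) ", filtered" else ""))
  invisible(x)
}

#' Channel accessors
#'
#' Convenience accessors for the channels the detection pipeline keys on:
#' anterior-posterior (`z`) and vertical (`y`) linear acceleration.
#'
#' @param recording An [imu_recording].
#' @return Numeric vector, one value per sample.
#' @export
ap_channel <- function(recording) recording$linear_accel[, "z"]

#' @rdname ap_channel
#' @export
vertical_channel <- function(recording) recording$linear_accel[, "y"]

#' Read a trial recording from CSV
#'
#' Parses the recording CSV dialect written by [write_trial()]: an optional
#' `#` comment line, then header `time,ax,ay,az,lx,ly,lz,gx,gy,gz,ox,oy,oz`,
#' one row per sample, SI units.
#'
#' @param path Path to the CSV file.
#' @param participant_id Identifier; defaults to the file stem.
#' @return An [imu_recording] with `is_uniform = FALSE`.
#' @export
read_recording <- function(path, participant_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#")
  need <- recording_columns()
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("recording file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(df) >= 2L && any(diff(df$time) <= 0))
    stop("timestamps must be strictly increasing", call. = FALSE)
  if (is.null(participant_id))
    participant_id <- sub("_recording$", "", sub("\\.csv$", "", basename(path)))
  imu_recording(
    timestamps = df$time,
    raw_accel = as.matrix(df[c("ax", "ay", "az")]),
    linear_accel = as.matrix(df[c("lx", "ly", "lz")]),
    angular_velocity = as.matrix(df[c("gx", "gy", "gz")]),
    orientation = as.matrix(df[c("ox", "oy", "oz")]),
    participant_id = participant_id
  )
}

#' Read a ground-truth events CSV
#'
#' @param path Path to an events CSV (single `time` column, seconds).
#' @param rate Frame rate used to attach frame indices, Hz.
#' @return An [fs_events] object.
#' @export
read_events <- function(path, rate = 50) {
  df <- utils::read.csv(path)
  if (!"time" %in% names(df))
    stop("events file must have a `time` column", call. = FALSE)
  fs_events(times = df$time, rate = rate)
}

#' Resample a recording onto a uniform grid
#'
#' Linearly interpolates every channel onto the grid `t0, t0 + 1/rate, ...`
#' up to the last original timestamp. Smartphone IMU streams are sampled at a
#' variable rate; the detection models assume a fixed 50 Hz frame clock.
#'
#' @param recording An [imu_recording] with at least 2 samples.
#' @param rate Target rate, Hz.
#' @return A uniform [imu_recording] (`is_uniform = TRUE`).
#' @export
resample_to_uniform <- function(recording, rate = 50) {
  stopifnot(inherits(recording, "imu_recording"))
  ts <- recording$timestamps
  if (length(ts) < 2L)
    stop("need at least 2 samples to resample", call. = FALSE)
  t0 <- ts[1]
  grid <- seq(t0, ts[length(ts)] + 1e-9, by = 1 / rate)
  interp_mat <- function(m) {
    out <- vapply(seq_len(ncol(m)),
                  function(j) stats::approx(ts, m[, j], xout = grid,
                                            rule = 2)$y,
                  numeric(length(grid)))
    colnames(out) <- colnames(m)
    out
  }
  imu_recording(
    timestamps = grid,
    raw_accel = interp_mat(recording$raw_accel),
    linear_accel = interp_mat(recording$linear_accel),
    angular_velocity = interp_mat(recording$angular_velocity),
    orientation = interp_mat(recording$orientation),
    participant_id = recording$participant_id,
    is_uniform = TRUE,
    is_filtered = recording$is_filtered
  )
}

#' Low-pass filter specification
#'
#' Defaults match the preprocessing used throughout the package: a
#' fourth-order zero-lag Butterworth low-pass with 4 Hz cut-off applied to
#' 50 Hz signals. "Zero-lag" is realised as a forward-backward pass, which
#' squares the magnitude response (effective 8th-order attenuation) and
#' cancels phase so peak timing is preserved.
#'
#' @param order Filter order (even, >= 2) of the one-way design.
#' @param cutoff Cut-off frequency, Hz; must satisfy `0 < cutoff < rate/2`.
#' @param rate Sampling rate, Hz.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(order = 4, cutoff = 4, rate = 50) {
  if (!(order >= 2 && order %% 2 == 0))
    stop("`order` must be an even integer >= 2", call. = FALSE)
  if (!(cutoff > 0 && cutoff < rate / 2))
    stop("`cutoff` must lie in (0, rate/2)", call. = FALSE)
  structure(list(order = as.integer(order), cutoff = cutoff, rate = rate),
            class = "filter_spec")
}

# direct-form-II-transposed IIR filter with explicit initial state
iir_filter <- function(b, a, x, zi) {
  m <- length(b) - 1L
  n <- length(x)
  y <- numeric(n)
  z <- zi
  for (i in seq_len(n)) {
    xi <- x[i]
    yi <- b[1] * xi + z[1]
    if (m > 1L) {
      z[seq_len(m - 1L)] <- b[2:m] * xi + z[2:m] - a[2:m] * yi
    }
    z[m] <- b[m + 1L] * xi - a[m + 1L] * yi
    y[i] <- yi
  }
  y
}

# steady-state initial conditions for a unit step (scaled by the first
# sample before use), so constants pass through exactly
iir_zi <- function(b, a) {
  m <- length(a) - 1L
  A <- rbind(-a[2:(m + 1L)], cbind(diag(1, m - 1L), 0))
  B <- b[2:(m + 1L)] - b[1] * a[2:(m + 1L)]
  solve(diag(m) - t(A), B)
}

#' Zero-lag Butterworth low-pass filter
#'
#' Designs a Butterworth low-pass of the given order and applies it forward
#' then backward, cancelling phase delay. The signal is extended by odd
#' reflection (length 3 x order at each end) and each pass starts from
#' steady-state initial conditions, so startup transients are confined to
#' the reflected padding and DC gain is exactly 1.
#'
#' @param x Numeric signal, uniformly sampled at `spec$rate`.
#' @param spec A [filter_spec()].
#' @return Filtered signal, same length as `x`.
#' @export
zero_lag_lowpass <- function(x, spec = filter_spec()) {
  stopifnot(inherits(spec, "filter_spec"))
  n <- length(x)
  np <- 3L * spec$order
  if (n <= np)
    stop(sprintf("signal too short to filter (need > %d samples)", np),
         call. = FALSE)
  bf <- signal::butter(spec$order, spec$cutoff / (spec$rate / 2), type = "low")
  b <- bf$b; a <- bf$a
  zi <- iir_zi(b, a)
  ext <- c(2 * x[1] - x[(np + 1L):2],
           x,
           2 * x[n] - x[(n - 1L):(n - np)])
  y <- iir_filter(b, a, ext, zi * ext[1])
  y <- rev(iir_filter(b, a, rev(y), zi * y[length(y)]))
  y[(np + 1L):(np + n)]
}

#' Low-pass filter all channels of a recording
#'
#' Applies [zero_lag_lowpass()] to each of the 12 signal channels. The
#' recording must already sit on a uniform grid at `spec$rate`.
#'
#' @param recording A uniform [imu_recording].
#' @param spec A [filter_spec()].
#' @return The recording with filtered channels and `is_filtered = TRUE`.
#' @export
filter_recording <- function(recording, spec = filter_spec()) {
  stopifnot(inherits(recording, "imu_recording"))
  if (!recording$is_uniform)
    stop("recording must be resampled to a uniform grid before filtering",
         call. = FALSE)
  filt_mat <- function(m) {
    out <- vapply(seq_len(ncol(m)),
                  function(j) zero_lag_lowpass(m[, j], spec),
                  numeric(nrow(m)))
    colnames(out) <- colnames(m)
    out
  }
  recording$raw_accel <- filt_mat(recording$raw_accel)
  recording$linear_accel <- filt_mat(recording$linear_accel)
  recording$angular_velocity <- filt_mat(recording$angular_velocity)
  recording$orientation <- filt_mat(recording$orientation)
  recording$is_filtered <- TRUE
  recording
}

#' Preprocess a recording: resample then filter
#'
#' @param recording An [imu_recording].
#' @param rate Target uniform rate, Hz.
#' @param spec A [filter_spec()].
#' @return A uniform, filtered [imu_recording].
#' @export
preprocess_recording <- function(recording, rate = 50, spec = filter_spec(rate = rate)) {
  filter_recording(resample_to_uniform(recording, rate), spec)
}

#' Assemble the per-frame feature matrix
#'
#' Stacks the 12 signal channels into a frames x 12 matrix in fixed column
#' order: raw acceleration (ax, ay, az), linear acceleration (lx, ly, lz),
#' angular velocity (gx, gy, gz), orientation (ox, oy, oz).
#'
#' @param recording A uniform [imu_recording] (filtered in the standard
#'   pipeline).
#' @return Numeric matrix, one row per frame, 12 named columns.
#' @export
assemble_features <- function(recording) {
  stopifnot(inherits(recording, "imu_recording"))
  if (!recording$is_uniform)
    stop("features require a uniform recording; call resample_to_uniform()",
         call. = FALSE)
  m <- cbind(recording$raw_accel, recording$linear_accel,
             recording$angular_velocity, recording$orientation)
  colnames(m) <- recording_columns()[-1]
  m
}
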