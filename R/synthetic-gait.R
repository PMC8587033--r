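#' Simulator configuration for synthetic amputee gait
#'
#' Bundles every knob of the synthetic pelvis-IMU gait generator. Defaults
#' describe a six-minute walk at ~2 steps/s with the step-to-step variability,
#' left/right asymmetry and occasional signal artifacts (double peaks from
#' gait aids, weak peaks, steps the sensor barely registers) expected of
#' lower-limb amputee gait.
#'
#' @param duration Trial length in seconds.
#' @param nominal_rate Nominal sampling rate in Hz (smartphones sample
#'   variably around this rate; see `sampling_jitter_sd`).
#' @param mean_step_time Mean interval between consecutive foot strikes,
#'   seconds. Typical walking is 0.4--0.6 s.
#' @param step_time_cv Coefficient of variation of step time (multiplicative
#'   lognormal variability), dimensionless.
#' @param asymmetry_ratio Right step time / left step time. 1 = symmetric.
#' @param ap_vertical_lag Delay of the vertical acceleration peak after the
#'   anterior-posterior (AP) peak at each foot strike, seconds.
#' @param peak_width Gaussian width (sd) of the per-step acceleration bumps,
#'   seconds.
#' @param noise_sd White-noise sd added to all acceleration channels, m/s^2.
#' @param sampling_jitter_sd Gaussian sd of timestamp jitter, seconds.
#' @param p_double_peak Probability that a step's AP peak is split into two
#'   sub-peaks (walking-aid artifact).
#' @param p_weak_peak Probability that a step's AP peak amplitude is scaled
#'   by 0.3.
#' @param p_dropped_step Probability that a step's peaks are omitted from the
#'   signal while the event remains in the ground truth (a step the sensor
#'   barely registers).
#' @param lead_in Standing lead-in before the first foot strike, seconds.
#'   Kept as small-amplitude oscillation (not exact zero) so zero crossings
#'   stay defined for the locking-period estimator.
#' @param seed Integer RNG seed; identical seed gives identical output.
#'
#' @return An object of class `gait_sim_config` (a validated list).
#' @seealso [generate_trial()]
#' @export
gait_sim_config <- function(duration = 360,
                            nominal_rate = 50,
                            mean_step_time = 0.5,
                            step_time_cv = 0.08,
                            asymmetry_ratio = 1.1,
                            ap_vertical_lag = 0.08,
                            peak_width = 0.05,
                            noise_sd = 0.15,
                            sampling_jitter_sd = 0.002,
                            p_double_peak = 0.05,
                            p_weak_peak = 0.05,
                            p_dropped_step = 0.03,
                            lead_in = 1,
                            seed = 1L) {
  cfg <- list(duration = duration, nominal_rate = nominal_rate,
              mean_step_time = mean_step_time, step_time_cv = step_time_cv,
              asymmetry_ratio = asymmetry_ratio,
              ap_vertical_lag = ap_vertical_lag, peak_width = peak_width,
              noise_sd = noise_sd, sampling_jitter_sd = sampling_jitter_sd,
              p_double_peak = p_double_peak, p_weak_peak = p_weak_peak,
              p_dropped_step = p_dropped_step, lead_in = lead_in,
              seed = as.integer(seed))
  validate_gait_sim_config(cfg)
  class(cfg) <- "gait_sim_config"
  cfg
}

validate_gait_sim_config <- function(cfg) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  if (!num1(cfg$duration) || cfg$duration <= 0)
    stop("`duration` must be a positive number", call. = FALSE)
  if (!num1(cfg$nominal_rate) || cfg$nominal_rate <= 0)
    stop("`nominal_rate` must be a positive number", call. = FALSE)
  if (!num1(cfg$mean_step_time) ||
      cfg$mean_step_time <= 0.2 || cfg$mean_step_time >= 1.5)
    stop("`mean_step_time` must lie in (0.2, 1.5) seconds", call. = FALSE)
  if (!num1(cfg$asymmetry_ratio) || cfg$asymmetry_ratio <= 0)
    stop("`asymmetry_ratio` must be > 0", call. = FALSE)
  if (!num1(cfg$step_time_cv) || cfg$step_time_cv < 0)
    stop("`step_time_cv` must be >= 0", call. = FALSE)
  for (p in c("p_double_peak", "p_weak_peak", "p_dropped_step")) {
    if (!num1(cfg[[p]]) || cfg[[p]] < 0 || cfg[[p]] > 1)
      stop(sprintf("`%s` must be a probability in [0, 1]", p), call. = FALSE)
  }
  for (p in c("ap_vertical_lag", "peak_width", "noise_sd",
              "sampling_jitter_sd", "lead_in")) {
    if (!num1(cfg[[p]]) || cfg[[p]] < 0)
      stop(sprintf("`%s` must be >= 0", p), call. = FALSE)
  }
  invisible(cfg)
}

# Gaussian bump helper: sum of A_i * exp(-(t - c_i)^2 / (2 w^2)) evaluated on
# t, accumulated without forming an n x n_events matrix (events only affect
# +/- 5 sd of signal).
add_bumps <- function(y, t, centers, amps, width) {
  if (length(centers) == 0L) return(y)
  n <- length(t)
  dt <- if (n > 1) (t[n] - t[1]) / (n - 1) else 1
  half <- max(1L, ceiling(5 * width / dt))
  for (i in seq_along(centers)) {
    j <- round((centers[i] - t[1]) / dt) + 1
    idx <- max(1L, j - half):min(n, j + half)
    y[idx] <- y[idx] + amps[i] * exp(-(t[idx] - centers[i])^2 / (2 * width^2))
  }
  y
}

#' Generate one synthetic pelvis-IMU walking trial
#'
#' Produces a 12-channel inertial recording together with the ground-truth
#' foot-strike times that generated it. Each (non-dropped) step contributes a
#' Gaussian AP-acceleration bump centred at the foot strike, followed
#' `ap_vertical_lag` seconds later by a vertical bump -- the signature the
#' downstream peak-pair labeller and classifiers key on. Medio-lateral
#' acceleration oscillates at stride frequency (alternating sign per step),
#' angular velocities oscillate at step frequency, orientation channels drift
#' slowly, and raw acceleration is linear acceleration plus gravity.
#' Timestamps are jittered around the nominal grid to emulate the variable
#' smartphone sampling rate.
#'
#' Steps flagged as dropped are omitted from the signal but kept in the truth
#' events, creating honest false negatives for the missed-step corrector.
#'
#' @param config A [gait_sim_config()].
#' @return A list of class `simulated_trial` with elements `recording`
#'   (an [imu_recording]) and `truth_events` (an [fs_events] object on the
#'   nominal uniform grid), plus `step_flags` (per-step artifact bookkeeping).
#' @examples
#' trial <- generate_trial(gait_sim_config(duration = 30, seed = 7))
#' length(trial$truth_events$times)
#' @export
generate_trial <- function(config) {
  if (!inherits(config, "gait_sim_config")) {
    config <- do.call(gait_sim_config, as.list(config))
  }
  validate_gait_sim_config(config)
  set.seed(config$seed)

  rate <- config$nominal_rate
  n <- floor(config$duration * rate) + 1L
  t_nom <- (seq_len(n) - 1) / rate
  ts <- t_nom
  if (config$sampling_jitter_sd > 0) {
    ts <- t_nom + stats::rnorm(n, 0, config$sampling_jitter_sd)
    ts[1] <- 0
    ts <- sort(ts)
    # enforce strict monotonicity in the (rare) event of duplicated times
    bad <- which(diff(ts) <= 0)
    while (length(bad)) {
      ts[bad + 1L] <- ts[bad] + 1e-6
      bad <- which(diff(ts) <= 0)
    }
  }

  # --- ground-truth events: alternating left/right step times ---------------
  base_left <- 2 * config$mean_step_time / (1 + config$asymmetry_ratio)
  base_right <- config$asymmetry_ratio * base_left
  cv <- config$step_time_cv
  sdlog <- sqrt(log(1 + cv^2))
  mulog <- -sdlog^2 / 2    # unit-mean lognormal multiplier
  ev <- numeric(0)
  tcur <- config$lead_in
  side <- 0L
  while (tcur <= config$duration + 1e-9) {
    ev <- c(ev, tcur)
    base <- if (side == 0L) base_left else base_right
    mult <- if (cv > 0) stats::rlnorm(1, mulog, sdlog) else 1
    tcur <- tcur + base * mult
    side <- 1L - side
  }
  n_ev <- length(ev)
  dropped <- stats::runif(n_ev) < config$p_dropped_step
  weak <- !dropped & stats::runif(n_ev) < config$p_weak_peak
  double <- !dropped & stats::runif(n_ev) < config$p_double_peak

  # --- continuous-time signal model evaluated at the jittered timestamps ----
  f <- 1 / config$mean_step_time           # step frequency, Hz
  w <- config$peak_width
  visible <- ev[!dropped]
  ap_amp <- rep(1.5, length(visible))
  ap_amp[weak[!dropped]] <- 1.5 * 0.3

  # baseline oscillation: tiny during the standing lead-in, full once walking
  envelope <- function(t) 0.05 + 0.95 * (t >= config$lead_in - 0.2)

  ap <- 0.3 * envelope(ts) * sin(2 * pi * f * ts)
  is_double <- double[!dropped]
  if (any(!is_double)) {
    ap <- add_bumps(ap, ts, visible[!is_double], ap_amp[!is_double], w)
  }
  if (any(is_double)) {
    # split bump: two sub-peaks, the second slightly greater
    c2 <- visible[is_double]
    a2 <- ap_amp[is_double]
    ap <- add_bumps(ap, ts, c2 - 0.9 * w, 0.65 * a2, 0.7 * w)
    ap <- add_bumps(ap, ts, c2 + 0.9 * w, 0.75 * a2, 0.7 * w)
  }

  vert <- 0.25 * envelope(ts) * sin(2 * pi * f * ts - pi / 3)
  vert <- add_bumps(vert, ts, visible + config$ap_vertical_lag,
                    0.8 * ap_amp / 1.5 * 1.2, w)

  # medio-lateral: stride-frequency oscillation (sign alternates per step)
  ml <- 0.5 * envelope(ts) * sin(pi * f * (ts - config$lead_in))

  lx <- ml
  ly <- vert
  lz <- ap

  # raw acceleration = linear + gravity in the (slightly tilted) body frame
  ax <- lx + 0.1
  ay <- ly + 9.81
  az <- lz + 0.3

  if (config$noise_sd > 0) {
    for (nm in c("ax", "ay", "az", "lx", "ly", "lz")) {
      assign(nm, get(nm) + stats::rnorm(n, 0, config$noise_sd))
    }
  }

  gx <- 0.6 * envelope(ts) * sin(2 * pi * f * ts + 0.4)
  gy <- 0.3 * envelope(ts) * sin(pi * f * (ts - config$lead_in) + 1.1)
  gz <- 0.4 * envelope(ts) * sin(2 * pi * f * ts + 2.0)

  drift <- function(amp, period, phase) amp * sin(2 * pi * ts / period + phase)
  ox <- drift(0.05, 90, 0.3) + cumsum(stats::rnorm(n, 0, 2e-4))
  oy <- drift(0.04, 120, 1.2) + cumsum(stats::rnorm(n, 0, 2e-4))
  oz <- drift(0.06, 70, 2.1) + cumsum(stats::rnorm(n, 0, 2e-4))

  rec <- imu_recording(
    timestamps = ts,
    raw_accel = cbind(x = ax, y = ay, z = az),
    linear_accel = cbind(x = lx, y = ly, z = lz),
    angular_velocity = cbind(x = gx, y = gy, z = gz),
    orientation = cbind(x = ox, y = oy, z = oz),
    participant_id = sprintf("sim-%d", config$seed),
    is_uniform = config$sampling_jitter_sd == 0
  )

  trial <- list(
    recording = rec,
    truth_events = fs_events(times = ev, rate = rate),
    step_flags = data.frame(time = ev, dropped = dropped,
                            weak = weak, double = double),
    config = config
  )
  class(trial) <- "simulated_trial"
  trial
}

#' Write a simulated trial to CSV files
#'
#' Writes the recording as `<stem>_recording.csv` (comment line documenting
#' the axis convention, then `time,ax,ay,az,lx,ly,lz,gx,gy,gz,ox,oy,oz`) and
#' the ground-truth events as `<stem>_events.csv` (single `time` column).
#' Numeric formatting is fixed (`%.6f`) so identical trials produce
#' byte-identical files.
#'
#' @param trial A `simulated_trial` from [generate_trial()].
#' @param dir Output directory (created if missing).
#' @param stem File-name stem.
#' @return Invisibly, a named character vector with the two file paths.
#' @export
write_trial <- function(trial, dir, stem = "trial") {
  stopifnot(inherits(trial, "simulated_trial"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(dir))
      stop("cannot create directory: ", dir, call. = FALSE)
  }
  rec_path <- file.path(dir, paste0(stem, "_recording.csv"))
  ev_path <- file.path(dir, paste0(stem, "_events.csv"))
  rec <- trial$recording
  m <- cbind(time = rec$timestamps,
             rec$raw_accel, rec$linear_accel,
             rec$angular_velocity, rec$orientation)
  colnames(m) <- recording_columns()
  con <- file(rec_path, open = "wt")
  on.exit(close(con), add = TRUE)
  writeLines("# axes: x=ML, y=vertical, z=AP, body frame", con)
  writeLines(paste(colnames(m), collapse = ","), con)
  writeLines(apply_fmt_rows(m), con)
  ev_con <- file(ev_path, open = "wt")
  on.exit(close(ev_con), add = TRUE)
  writeLines("time", ev_con)
  if (length(trial$truth_events$times)) {
    writeLines(sprintf("%.6f", trial$truth_events$times), ev_con)
  }
  invisible(c(recording = rec_path, events = ev_path))
}

apply_fmt_rows <- function(m) {
  cols <- lapply(seq_len(ncol(m)), function(j) sprintf("%.6f", m[, j]))
  do.call(paste, c(cols, sep = ","))
}

recording_columns <- function() {
  c("time", "ax", "ay", "az", "lx", "ly", "lz",
    "gx", "gy", "gz", "ox", "oy", "oz")
}
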