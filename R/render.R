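# Synthetic single-cell volume trajectories with the artifacts real FXm
# movies carry: sampling noise, segmentation spikes, mitotic volume overshoot.

#' Single-cell volume trajectory container
#'
#' A light container for a sampled volume (and optional cell-cycle reporter)
#' time series. Frames dropped by [remove_spike_outliers()] are flagged, not
#' interpolated: downstream operations use retained frames only.
#'
#' @param cell_id Identifier.
#' @param t Sample times in minutes, strictly increasing on a constant grid.
#' @param volume Volumes in um^3, positive.
#' @param reporter Optional cell-cycle reporter intensities (a.u.).
#' @param cytokinesis_onsets Times (min) of cytokinesis onsets bounding the
#'   recorded cycles.
#' @param events Optional ground-truth event list (used by the synthetic
#'   renderer).
#' @return An object of class `"trajectory"`.
#' @export
trajectory <- function(cell_id, t, volume, reporter = NULL,
                       cytokinesis_onsets = numeric(), events = NULL) {
  if (length(t) != length(volume)) stop("t and volume lengths differ")
  if (length(t) < 2) stop("a trajectory needs at least 2 frames")
  dt <- diff(t)
  if (any(dt <= 0)) stop("t must be strictly increasing")
  if (max(dt) - min(dt) > 1e-6)
    stop("frame interval must be constant within a trajectory")
  if (any(!is.finite(volume)) || any(volume <= 0))
    stop("volumes must be finite and > 0")
  if (!is.null(reporter) && length(reporter) != length(t))
    stop("reporter length differs from t")
  structure(list(cell_id = cell_id, t = t, volume = volume,
                 reporter = reporter, frame_interval = dt[1],
                 cytokinesis_onsets = sort(cytokinesis_onsets),
                 retained = rep(TRUE, length(t)),
                 n_removed = 0L, events = events),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory '%s': %d frames every %g min (%d retained)%s\n",
              as.character(x$cell_id), length(x$t), x$frame_interval,
              sum(x$retained),
              if (is.null(x$reporter)) "" else ", with reporter channel"))
  invisible(x)
}

#' Render a sampled volume trajectory from a simulated cell cycle
#'
#' Turns one completed cycle (a row of [simulate_lineages()] output) into a
#' sampled trajectory spanning cytokinesis to cytokinesis. The previous
#' cytokinesis onset sits at t = 0 min; birth is sampled 40 min after it and
#' mitotic entry 60 min before the next onset, matching the measurement
#' windows used on real movies. Volume grows exponentially, with optional
#' multiplicative lognormal sampling noise, isolated segmentation spikes
#' (local value times a factor in \[2, 10\]), and a reversible mitotic volume
#' overshoot confined to 20 min around each cytokinesis onset. The reporter
#' channel is flat background noise before the G1/S transition and a linear
#' ramp after it (only when the record carries phase durations).
#'
#' @param record One-row data.frame (or list) with at least `V_birth`,
#'   `alpha`, `tau`; `tau_G1` enables the reporter ramp.
#' @param frame_interval Sampling interval in minutes, in \[1, 60\].
#' @param noise_cv Multiplicative CV of the volume read-out.
#' @param spike_rate Per-frame probability of a segmentation spike.
#' @param overshoot_amplitude Fractional amplitude of the mitotic overshoot.
#' @param seed Optional integer seed.
#' @return A [trajectory()] whose `events` field stores the ground truth:
#'   event times (min), true volumes, and spike frame indices.
#' @export
render_trajectory <- function(record, frame_interval = 10, noise_cv = 0,
                              spike_rate = 0, overshoot_amplitude = 0,
                              seed = NULL) {
  if (frame_interval < 1 || frame_interval > 60)
    stop("frame_interval must be in [1, 60] minutes")
  if (noise_cv < 0 || spike_rate < 0 || spike_rate > 1 ||
      overshoot_amplitude < 0)
    stop("noise_cv, overshoot_amplitude must be >= 0; spike_rate in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  V_birth <- record$V_birth; alpha <- record$alpha; tau <- record$tau
  if (!is.finite(V_birth) || !is.finite(alpha) || !is.finite(tau) ||
      V_birth <= 0 || tau <= 0)
    stop("record must carry finite positive V_birth and tau")

  t_birth <- 40
  t_mitosis <- t_birth + tau * 60
  onset2 <- t_mitosis + 60
  t <- seq(0, onset2 + 20, by = frame_interval)
  n <- length(t)

  v <- V_birth * exp(alpha * (t - t_birth) / 60)
  after <- t > onset2 # daughter cell after division
  v[after] <- 0.5 * V_birth * exp(alpha * (onset2 - t_birth) / 60) *
    exp(alpha * (t[after] - onset2) / 60)

  if (overshoot_amplitude > 0) {
    for (on in c(0, onset2)) {
      w <- pmax(0, 1 - abs(t - on) / 20)
      v <- v * (1 + overshoot_amplitude * w)
    }
  }
  v_true <- v

  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    v <- v * exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
  }
  spike_frames <- integer()
  if (spike_rate > 0) {
    spike_frames <- which(stats::runif(n) < spike_rate)
    if (length(spike_frames))
      v[spike_frames] <- v[spike_frames] *
        stats::runif(length(spike_frames), 2, 10)
  }

  t_G1S <- if (!is.null(record$tau_G1) && is.finite(record$tau_G1))
    t_birth + record$tau_G1 * 60 else NA_real_
  bg_mean <- 100; bg_sd <- 5
  reporter <- stats::rnorm(n, bg_mean, bg_sd)
  if (is.finite(t_G1S))
    reporter <- reporter + pmax(0, 2 * (t - t_G1S))

  events <- list(
    t_birth = t_birth, t_G1S = t_G1S, t_mitosis = t_mitosis,
    cytokinesis_onsets = c(0, onset2),
    V_birth = V_birth,
    V_G1S = if (is.finite(t_G1S)) V_birth * exp(alpha * record$tau_G1)
            else NA_real_,
    V_mitosis = V_birth * exp(alpha * tau),
    spike_frames = spike_frames, volume_true = v_true)

  trajectory(cell_id = if (is.null(record$cell_id)) NA else record$cell_id,
             t = t, volume = v, reporter = reporter,
             cytokinesis_onsets = c(0, onset2), events = events)
}
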