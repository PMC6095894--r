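# Trajectory processing: despike -> smooth -> growth speed / events,
# mirroring how real FXm growth curves are cleaned before analysis.

#' Remove isolated segmentation spikes from a trajectory
#'
#' A single pass over the retained frames drops frame i when its volume lies
#' further than `k * 1.4826 * MAD` from the median of a centred window
#' (the 1.4826 factor makes the MAD a consistent s.d. estimate). Windows
#' shrink at the trajectory edges. When the window MAD is zero (locally
#' constant signal) only frames beyond a small absolute tolerance of the
#' median are dropped, so exact duplicates survive. Dropped frames are
#' flagged, never interpolated.
#'
#' @param traj A [trajectory()].
#' @param window Window length in frames, odd, >= 3. Default 11.
#' @param k Threshold multiplier. Default 3.
#' @return The trajectory with updated `retained` flags; `n_removed` holds
#'   the number of frames removed by this pass.
#' @export
remove_spike_outliers <- function(traj, window = 11, k = 3) {
  stopifnot(inherits(traj, "trajectory"))
  if (window < 3 || window %% 2 == 0) stop("window must be odd and >= 3")
  idx <- which(traj$retained)
  v <- traj$volume[idx]
  n <- length(v)
  h <- (window - 1) %/% 2
  drop <- logical(n)
  for (i in seq_len(n)) {
    w <- v[max(1, i - h):min(n, i + h)]
    med <- stats::median(w)
    madv <- stats::median(abs(w - med))
    thr <- if (madv > 0) k * 1.4826 * madv
           else sqrt(.Machine$double.eps) * max(1, abs(med))
    drop[i] <- abs(v[i] - med) > thr
  }
  traj$retained[idx[drop]] <- FALSE
  traj$n_removed <- sum(drop)
  traj
}

#' Smooth a trajectory with a centred sliding average
#'
#' Centred moving mean over the retained frames; at the edges the window
#' shrinks to the frames available, so the series keeps its full length.
#'
#' @inheritParams remove_spike_outliers
#' @param window Window length in frames, odd. Default 7 (70 min at 10-min
#'   sampling).
#' @return The trajectory with smoothed volumes at the retained frames.
#' @export
smooth_trajectory <- function(traj, window = 7) {
  stopifnot(inherits(traj, "trajectory"))
  if (window < 1 || window %% 2 == 0) stop("window must be odd")
  idx <- which(traj$retained)
  v <- traj$volume[idx]
  n <- length(v)
  h <- (window - 1) %/% 2
  sm <- vapply(seq_len(n), function(i)
    mean(v[max(1, i - h):min(n, i + h)]), numeric(1))
  traj$volume[idx] <- sm
  traj
}

# median of pairwise slopes (Theil-Sen); deterministic, resists
# floor((w - 1) / 2) outliers in a window of w points
theil_sen_slope <- function(t, v) {
  n <- length(t)
  ij <- utils::combn(n, 2)
  stats::median((v[ij[2, ]] - v[ij[1, ]]) / (t[ij[2, ]] - t[ij[1, ]]))
}

#' Instantaneous growth speed by windowed Theil-Sen regression
#'
#' The growth speed dV/dt at each retained frame is the Theil-Sen slope
#' (median of pairwise slopes) over a centred window of `window` retained
#' frames, converted to um^3/h. Frames whose centred window is incomplete
#' (trajectory edges) are marked invalid rather than extrapolated.
#'
#' @param traj A despiked, smoothed [trajectory()].
#' @param window Window length in frames, odd, >= 5. Default 9 (90 min at
#'   10-min sampling).
#' @return A `data.frame` with columns `frame`, `t_min`, `volume_um3`,
#'   `dvdt_um3_per_h`, `valid`, one row per retained frame.
#' @export
instantaneous_growth_speed <- function(traj, window = 9) {
  stopifnot(inherits(traj, "trajectory"))
  if (window < 5 || window %% 2 == 0) stop("window must be odd and >= 5")
  idx <- which(traj$retained)
  t <- traj$t[idx]; v <- traj$volume[idx]
  n <- length(t)
  h <- (window - 1) %/% 2
  dvdt <- rep(NA_real_, n)
  valid <- rep(FALSE, n)
  if (n >= window) {
    for (i in (h + 1):(n - h)) {
      sel <- (i - h):(i + h)
      dvdt[i] <- theil_sen_slope(t[sel], v[sel]) * 60
      valid[i] <- TRUE
    }
  }
  data.frame(frame = idx, t_min = t, volume_um3 = v,
             dvdt_um3_per_h = dvdt, valid = valid)
}

# nearest retained frame to a target time; ties round down (earlier frame)
snap_to_frame <- function(t, target) {
  d <- abs(t - target)
  which(d == min(d))[1]
}

#' Read cell-cycle event volumes from a trajectory
#'
#' For each pair of consecutive cytokinesis onsets, birth is sampled 40 min
#' after the first onset and mitotic entry 60 min before the second, snapped
#' to the nearest retained frame (ties round down). These windows skip the
#' transient mitotic volume overshoot around cytokinesis. Volumes are read
#' from the trajectory as given, so pass the despiked, smoothed series.
#' Events whose target time falls outside the recorded range are reported
#' missing, never extrapolated.
#'
#' @inheritParams remove_spike_outliers
#' @param birth_offset Minutes after cytokinesis onset at which birth volume
#'   is read. Default 40.
#' @param mitosis_offset Minutes before the next onset at which mitotic-entry
#'   volume is read. Default 60.
#' @param g1s If `TRUE` and a reporter channel is present, locate the G1/S
#'   transition with [detect_g1s()].
#' @return A `data.frame` with one row per recorded cycle: `cell_id`,
#'   `t_birth`, `V_birth`, `t_G1S`, `V_G1S`, `t_mitosis`, `V_mitosis`
#'   (times min, volumes um^3).
#' @export
annotate_events <- function(traj, birth_offset = 40, mitosis_offset = 60,
                            g1s = !is.null(traj$reporter)) {
  stopifnot(inherits(traj, "trajectory"))
  on <- traj$cytokinesis_onsets
  if (length(on) < 2)
    stop("annotate_events needs at least two cytokinesis onsets")
  idx <- which(traj$retained)
  t <- traj$t[idx]; v <- traj$volume[idx]
  rng <- range(t)

  t_g1s_global <- NA_real_
  if (isTRUE(g1s) && !is.null(traj$reporter))
    t_g1s_global <- tryCatch(detect_g1s(traj), error = function(e) NA_real_)

  rows <- lapply(seq_len(length(on) - 1L), function(i) {
    tb_target <- on[i] + birth_offset
    tm_target <- on[i + 1] - mitosis_offset
    read_at <- function(target) {
      if (target < rng[1] || target > rng[2]) return(c(NA_real_, NA_real_))
      j <- snap_to_frame(t, target)
      c(t[j], v[j])
    }
    b <- read_at(tb_target)
    m <- read_at(tm_target)
    tg <- if (is.finite(t_g1s_global) && t_g1s_global >= on[i] &&
              t_g1s_global < on[i + 1]) t_g1s_global else NA_real_
    g <- if (is.finite(tg)) read_at(tg) else c(NA_real_, NA_real_)
    data.frame(cell_id = if (is.null(traj$cell_id)) NA else traj$cell_id,
               t_birth = b[1], V_birth = b[2],
               t_G1S = g[1], V_G1S = g[2],
               t_mitosis = m[1], V_mitosis = m[2])
  })
  do.call(rbind, rows)
}

#' Detect the G1/S transition from a cycle-reporter channel
#'
#' The reporter background (mean and s.d.) is estimated from the first 10
#' retained frames at or after birth; the transition is the first time the
#' reporter exceeds `background mean + k * sd` for `m` consecutive frames.
#' A degron-based S-phase reporter (e.g. geminin fusions) accumulates from
#' S-phase onset, so this crossing marks G1/S.
#'
#' @inheritParams remove_spike_outliers
#' @param k Threshold multiplier on the background s.d. Default 3.
#' @param m Number of consecutive supra-threshold frames required. Default 3.
#' @return The transition time in minutes, or `NA` if the reporter never
#'   crosses. A crossing at the first examined frame is flagged with
#'   attribute `unreliable = TRUE` (background likely contaminated).
#' @export
detect_g1s <- function(traj, k = 3, m = 3) {
  stopifnot(inherits(traj, "trajectory"))
  if (is.null(traj$reporter)) stop("trajectory has no reporter channel")
  idx <- which(traj$retained)
  t <- traj$t[idx]; r <- traj$reporter[idx]
  start <- if (length(traj$cytokinesis_onsets))
    traj$cytokinesis_onsets[1] + 40 else t[1]
  sel <- which(t >= start)
  if (length(sel) < 10 + m)
    stop("need at least 10 background frames plus ", m, " signal frames")
  bg <- r[sel[1:10]]
  thr <- mean(bg) + k * stats::sd(bg)
  above <- r[sel] > thr
  run <- 0L
  hit <- NA_integer_
  for (i in seq_along(above)) {
    run <- if (above[i]) run + 1L else 0L
    if (run == m) { hit <- i - m + 1L; break }
  }
  if (is.na(hit)) return(NA_real_)
  out <- t[sel[hit]]
  if (hit == 1L) attr(out, "unreliable") <- TRUE
  out
}

#' Pooled growth-speed versus volume regression
#'
#' Pools per-frame (volume, growth speed) points across cells, averages them
#' in equal-width volume bins, drops bins fed by fewer than
#' `min_distinct_cells` distinct cells (low-sampling guard), and fits a
#' count-weighted line. Under exponential growth the slope of speed against
#' volume is the growth rate (1/h); linear growers give slope 0 with the
#' speed as intercept.
#'
#' @param data A `data.frame` with columns `cell_id`, `volume`, `dvdt`
#'   (um^3 and um^3/h), e.g. stacked [instantaneous_growth_speed()] outputs.
#' @param n_bins Number of equal-width volume bins. Default 10.
#' @param min_distinct_cells Minimum distinct cells per retained bin.
#'   Default 5.
#' @return A list with `fit` (a [weighted_binned_fit()] result), `bins`, and
#'   `growth_rate` (the slope, 1/h).
#' @export
growth_speed_vs_volume_bins <- function(data, n_bins = 10,
                                        min_distinct_cells = 5) {
  stopifnot(all(c("cell_id", "volume", "dvdt") %in% names(data)))
  data <- data[is.finite(data$volume) & is.finite(data$dvdt), , drop = FALSE]
  if (length(unique(data$cell_id)) < min_distinct_cells)
    stop("need at least ", min_distinct_cells, " distinct cells")
  rng <- range(data$volume)
  if (rng[1] == rng[2]) stop("all volumes identical, cannot bin")
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin <- findInterval(data$volume, edges, rightmost.closed = TRUE)
  parts <- split(data, bin)
  bins <- do.call(rbind, lapply(parts, function(d) {
    data.frame(x_stat = mean(d$volume), y_stat = mean(d$dvdt),
               count = nrow(d), y_sd = stats::sd(d$dvdt),
               n_cells_bin = length(unique(d$cell_id)))
  }))
  bins <- bins[bins$n_cells_bin >= min_distinct_cells, , drop = FALSE]
  if (nrow(bins) < 2)
    stop("fewer than 2 bins retained after the distinct-cell filter")
  rownames(bins) <- NULL
  class(bins) <- c("size_bins", "data.frame")
  fit <- weighted_binned_fit(bins)
  list(fit = fit, bins = bins, growth_rate = fit$slope)
}

#' Split cells into three groups by percentiles of a column
#'
#' Labels observations `low` (at or below the lower percentile cut), `mid`,
#' and `high` (above the upper cut). Values tied with a cut are assigned to
#' the group below the cut, deterministically. With the default cuts
#' `(20, 80)` the groups hold the 20% smallest, intermediate, and 20% largest
#' values.
#'
#' @param x Numeric vector (>= 10 values).
#' @param cuts Percentile pair. Default `c(20, 80)`.
#' @return A factor with levels `low`, `mid`, `high` and an attribute
#'   `cuts` holding the percentile values.
#' @export
percentile_groups <- function(x, cuts = c(20, 80)) {
  if (length(x) < 10) stop("need at least 10 observations")
  if (length(cuts) != 2 || cuts[1] >= cuts[2] || cuts[1] <= 0 || cuts[2] >= 100)
    stop("cuts must be an increasing pair inside (0, 100)")
  q <- stats::quantile(x, cuts / 100, names = FALSE)
  if (q[1] == q[2]) {
    warning("degenerate percentile cuts (identical values); all in 'mid'")
    g <- rep("mid", length(x))
  } else {
    g <- ifelse(x <= q[1], "low", ifelse(x > q[2], "high", "mid"))
  }
  out <- factor(g, levels = c("low", "mid", "high"))
  attr(out, "cuts") <- q
  out
}
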