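#' Per-phase locomotor metrics
#'
#' Total distance (mm) and mean velocity (mm/s) computed independently for
#' each light phase of the schedule, using half-open `[start, end)` windows;
#' each step belongs to the phase containing its starting sample.
#'
#' @param traj A [trajectory()].
#' @param schedule A [phase_schedule()] covering the recording.
#' @return Data frame with columns `phase`, `total_distance`,
#'   `mean_velocity`, plus subject labels.
#' @export
phase_metrics <- function(traj, schedule) {
  stopifnot(inherits(traj, "trajectory"), inherits(schedule, "phase_schedule"))
  rec_end <- traj$time[nrow(traj)]
  if (max(schedule$end) < rec_end - 1e-9) {
    stop("phase schedule does not cover the recording")
  }
  speeds <- step_speeds(traj)
  sr <- attr(traj, "sample_rate")
  step_start <- traj$time[-nrow(traj)]
  ph <- phase_at(schedule, step_start)
  rows <- lapply(seq_len(nrow(schedule)), function(i) {
    sel <- ph == schedule$name[i]
    d <- sum(speeds[sel]) / sr
    dur <- sum(sel) / sr
    data.frame(subject_id = attr(traj, "subject_id"),
               genotype = attr(traj, "genotype"),
               treatment = attr(traj, "treatment"),
               phase = schedule$name[i],
               total_distance = d,
               mean_velocity = if (dur > 0) d / dur else NA_real_)
  })
  do.call(rbind, rows)
}

#' Detect seizure-like episodes
#'
#' The recording is partitioned into consecutive non-overlapping (tumbling)
#' windows of `window` seconds anchored at t = 0; every window whose
#' traveled distance strictly exceeds `distance_threshold` is one episode,
#' and the episode amplitude is that window's distance.  Defaults implement
#' the > 200 mm per 1 min criterion; episodes are counted over the entire
#' recording.
#'
#' @param traj A [trajectory()].
#' @param window Window length in s (default 60).
#' @param distance_threshold Distance threshold in mm (default 200).
#' @return Data frame of class `seizure_episodes` with columns
#'   `window_start` (s) and `window_distance` (mm), one row per episode;
#'   attribute `n_windows` gives the number of windows examined.
#' @export
detect_seizure_episodes <- function(traj, window = 60,
                                    distance_threshold = 200) {
  stopifnot(inherits(traj, "trajectory"), window > 0)
  rec_len <- traj$time[nrow(traj)] - traj$time[1]
  if (rec_len < window - 1e-9) {
    stop("recording shorter than one detection window")
  }
  sr <- attr(traj, "sample_rate")
  step_len <- sqrt(diff(traj$x)^2 + diff(traj$y)^2)
  step_start <- traj$time[-nrow(traj)]
  n_win <- floor(rec_len / window + 1e-9)
  win_idx <- floor((step_start - traj$time[1]) / window) + 1L
  keep <- win_idx >= 1L & win_idx <= n_win
  dist <- vapply(seq_len(n_win), function(w)
    sum(step_len[keep & win_idx == w]), numeric(1))
  hit <- dist > distance_threshold
  out <- data.frame(window_start = (which(hit) - 1L) * window + traj$time[1],
                    window_distance = dist[hit])
  attr(out, "n_windows") <- n_win
  attr(out, "window_distances") <- dist
  class(out) <- c("seizure_episodes", "data.frame")
  out
}

#' Circling score per window
#'
#' Quantifies whirlpool-like circular swimming as net revolutions per
#' window: the absolute cumulative signed heading change across consecutive
#' moving steps, divided by 2 pi.  Straight swimming scores ~0; a full loop
#' per window scores ~1.
#'
#' @param traj A [trajectory()].
#' @param window Window length in s (default 60).
#' @param move_threshold Steps slower than this (mm/s) are ignored, so
#'   heading noise while stationary does not contribute.
#' @return Data frame with `window_start` (s) and `revolutions` per window.
#' @export
circling_score <- function(traj, window = 60, move_threshold = 2) {
  stopifnot(inherits(traj, "trajectory"))
  speeds <- step_speeds(traj)
  heading <- atan2(diff(traj$y), diff(traj$x))
  step_start <- traj$time[-nrow(traj)]
  rec_len <- traj$time[nrow(traj)] - traj$time[1]
  n_win <- max(1L, floor(rec_len / window + 1e-9))
  win_idx <- pmin(floor((step_start - traj$time[1]) / window) + 1L, n_win)
  moving <- classify_movement(speeds, move_threshold)
  revs <- vapply(seq_len(n_win), function(w) {
    h <- heading[moving & win_idx == w]
    if (length(h) < 2L) return(0)
    abs(sum(wrap_angle(diff(h)))) / (2 * pi)
  }, numeric(1))
  data.frame(window_start = (seq_len(n_win) - 1L) * window + traj$time[1],
             revolutions = revs)
}

#' Startle response after light transitions
#'
#' Distance traveled in the `startle_window` seconds immediately after each
#' light transition of the schedule.
#'
#' @param traj A [trajectory()].
#' @param schedule A [phase_schedule()].
#' @param startle_window Window after each transition, in s (default 5).
#' @return Data frame with `transition_time` (s) and `distance` (mm); zero
#'   rows when the schedule has no light change.
#' @export
startle_response <- function(traj, schedule, startle_window = 5) {
  stopifnot(inherits(traj, "trajectory"), inherits(schedule, "phase_schedule"))
  trans <- schedule_transitions(schedule)
  if (!length(trans)) {
    return(data.frame(transition_time = numeric(0), distance = numeric(0)))
  }
  step_len <- sqrt(diff(traj$x)^2 + diff(traj$y)^2)
  step_start <- traj$time[-nrow(traj)]
  data.frame(
    transition_time = trans,
    distance = vapply(trans, function(tr)
      sum(step_len[step_start >= tr & step_start < tr + startle_window]),
      numeric(1))
  )
}
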