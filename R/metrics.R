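#' Per-step speeds of a trajectory
#'
#' @param traj A [trajectory()] with at least 2 samples.
#' @return Numeric vector of length `n - 1`: Euclidean step length times the
#'   sample rate (mm/s), one value per inter-sample interval.
#' @export
step_speeds <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  if (nrow(traj) < 2L) stop("need at least 2 samples to compute speeds")
  sqrt(diff(traj$x)^2 + diff(traj$y)^2) * attr(traj, "sample_rate")
}

#' Total distance traveled (mm)
#'
#' @param traj A [trajectory()].
#' @return Total path length in mm (0 for a single-sample track).
#' @export
total_distance <- function(traj) {
  if (nrow(traj) < 2L) return(0)
  sum(sqrt(diff(traj$x)^2 + diff(traj$y)^2))
}

#' Movement/no-movement dichotomy
#'
#' A step counts as movement iff its speed is at least `move_threshold`.
#'
#' @param speeds Per-step speeds (mm/s), as from [step_speeds()].
#' @param move_threshold Threshold in mm/s (default 2).
#' @return Logical vector, `TRUE` where moving.
#' @export
classify_movement <- function(speeds, move_threshold = 2) {
  stopifnot(move_threshold >= 0)
  speeds >= move_threshold
}

#' Count fast-movement events
#'
#' Fast movements are steps with speed strictly above `fast_threshold`
#' (default 20 mm/s); an event is one maximal run of consecutive
#' supra-threshold steps, so the count is sample-rate independent.
#'
#' @param speeds Per-step speeds (mm/s).
#' @param fast_threshold Threshold in mm/s (> 0).
#' @return Integer event count.
#' @export
count_fast_movements <- function(speeds, fast_threshold = 20) {
  stopifnot(fast_threshold > 0)
  fast <- speeds > fast_threshold
  if (!length(fast)) return(0L)
  sum(fast & !c(FALSE, fast[-length(fast)]))
}

#' Zone occupancy with the movement split
#'
#' Assigns each inter-sample interval to the zone of its starting point
#' (left-closed rule) and to moving/not-moving, accumulating durations in
#' seconds.
#'
#' @param traj A [trajectory()].
#' @param arena An [arena()].
#' @param moving Logical per-step vector, as from [classify_movement()];
#'   computed with the default threshold when `NULL`.
#' @param partition `"border_center"` or `"light_dark"`.
#' @param move_threshold Used when `moving` is `NULL`.
#' @return A data frame of class `zone_occupancy` with columns `zone`,
#'   `duration_moving`, `duration_not_moving` (s).
#' @export
zone_occupancy <- function(traj, arena, moving = NULL,
                           partition = c("border_center", "light_dark"),
                           move_threshold = 2) {
  partition <- match.arg(partition)
  stopifnot(inherits(traj, "trajectory"), inherits(arena, "arena"))
  if (nrow(traj) < 2L) stop("need at least 2 samples")
  if (is.null(moving)) moving <- classify_movement(step_speeds(traj),
                                                   move_threshold)
  stopifnot(length(moving) == nrow(traj) - 1L)
  pts <- cbind(traj$x, traj$y)[-nrow(traj), , drop = FALSE]
  zone <- if (partition == "border_center") {
    zone_of_point(arena, pts)
  } else {
    light_side_of_point(arena, pts)
  }
  zones <- if (partition == "border_center") c("border", "center")
           else c("light", "dark")
  dt <- 1 / attr(traj, "sample_rate")
  out <- data.frame(
    zone = zones,
    duration_moving = vapply(zones, function(z) sum(zone == z & moving) * dt,
                             numeric(1)),
    duration_not_moving = vapply(zones, function(z)
      sum(zone == z & !moving) * dt, numeric(1)),
    row.names = NULL
  )
  class(out) <- c("zone_occupancy", "data.frame")
  out
}

occupancy_time <- function(occ, zone) {
  i <- match(zone, occ$zone)
  occ$duration_moving[i] + occ$duration_not_moving[i]
}

#' Thigmotaxis index (percent of time in the border zone)
#'
#' `100 * (moving + not-moving time in the border) / total time`.  The
#' complementary center index is `100 - thigmotaxis_index`.
#'
#' @param occ A `zone_occupancy` over the border/center partition.
#' @return Percent in `[0, 100]`.
#' @export
thigmotaxis_index <- function(occ) {
  zone_time_index(occ, "border")
}

#' Phototaxis index (percent of time in the light half)
#'
#' @param occ A `zone_occupancy` over the light/dark partition.
#' @return Percent in `[0, 100]`.
#' @export
phototaxis_index <- function(occ) {
  zone_time_index(occ, "light")
}

zone_time_index <- function(occ, zone) {
  stopifnot(inherits(occ, "zone_occupancy"), zone %in% occ$zone)
  total <- sum(occ$duration_moving) + sum(occ$duration_not_moving)
  if (total <= 0) stop("zone index undefined: total duration is zero")
  100 * occupancy_time(occ, zone) / total
}

#' Three-class light-preference response
#'
#' Classifies a phototaxis index: above 70% is phototaxis, below 30% is
#' scototaxis, the closed interval 30-70% is no preference.
#'
#' @param index Phototaxis index in percent, in `[0, 100]`.
#' @return Factor with levels `phototaxis`, `no_preference`, `scototaxis`.
#' @export
classify_light_preference <- function(index) {
  if (any(!is.finite(index) | index < 0 | index > 100)) {
    stop("phototaxis index must lie in [0, 100]")
  }
  cls <- ifelse(index > 70, "phototaxis",
                ifelse(index < 30, "scototaxis", "no_preference"))
  factor(cls, levels = c("phototaxis", "no_preference", "scototaxis"))
}

#' Activity filter
#'
#' Rejects subjects that were not active during the whole recording: total
#' distance strictly below `min_distance` mm (default 10).
#'
#' @param trajs List of [trajectory()] objects.
#' @param min_distance Rejection threshold in mm.
#' @return List with `kept` and `rejected` trajectory lists and a data frame
#'   `log` (`subject_id`, `total_distance`, `kept`).
#' @export
activity_filter <- function(trajs, min_distance = 10) {
  dist <- vapply(trajs, total_distance, numeric(1))
  keep <- dist >= min_distance
  log <- data.frame(
    subject_id = vapply(trajs, function(x) attr(x, "subject_id"),
                        character(1)),
    total_distance = dist,
    kept = keep,
    reason = ifelse(keep, "", sprintf("total distance %.3g mm < %.3g mm",
                                      dist, min_distance))
  )
  list(kept = trajs[keep], rejected = trajs[!keep], log = log)
}

#' Per-bin, per-zone metric summaries
#'
#' Splits the recording into time bins (e.g. two 5 min periods) and reports,
#' per bin, the whole-arena totals plus the per-zone splits: total distance
#' (mm), mean velocity (mm/s), fast-movement event count, and moving /
#' not-moving durations.
#'
#' @param traj A [trajectory()].
#' @param arena An [arena()].
#' @param bins List of `c(start, end)` pairs in seconds (or a 2-column
#'   matrix); bins must lie within the recording.
#' @param partition `"border_center"` or `"light_dark"`.
#' @param move_threshold Movement threshold (mm/s).
#' @param fast_threshold Fast-movement threshold (mm/s).
#' @param velocity_mode `"bin_time"` (distance / bin duration, default) or
#'   `"moving_time"` (distance / time in motion).
#' @return Data frame with one row per bin x zone (`zone = "all"` rows give
#'   whole-arena metrics).
#' @export
bin_metrics <- function(traj, arena, bins,
                        partition = c("border_center", "light_dark"),
                        move_threshold = 2, fast_threshold = 20,
                        velocity_mode = c("bin_time", "moving_time")) {
  partition <- match.arg(partition)
  velocity_mode <- match.arg(velocity_mode)
  stopifnot(inherits(traj, "trajectory"))
  if (is.matrix(bins)) bins <- split(bins, row(bins))
  rec_end <- traj$time[nrow(traj)]
  sr <- attr(traj, "sample_rate")
  speeds <- step_speeds(traj)
  moving <- classify_movement(speeds, move_threshold)
  step_start <- traj$time[-nrow(traj)]
  pts <- cbind(traj$x, traj$y)[-nrow(traj), , drop = FALSE]
  zone <- if (partition == "border_center") zone_of_point(arena, pts)
          else light_side_of_point(arena, pts)
  zones <- c("all", unique(if (partition == "border_center")
    c("border", "center") else c("light", "dark")))
  step_len <- speeds / sr

  rows <- list()
  for (b in bins) {
    if (b[1] < traj$time[1] - 1e-9 || b[2] > rec_end + 1e-9 || b[2] <= b[1]) {
      stop("bin outside the recording")
    }
    in_bin <- step_start >= b[1] - 1e-9 & step_start < b[2] - 1e-9
    if (!any(in_bin)) stop("empty bin: no samples in the requested window")
    for (z in zones) {
      sel <- in_bin & (z == "all" | zone == z)
      d <- sum(step_len[sel])
      t_mov <- sum(sel & moving) / sr
      t_not <- sum(sel & !moving) / sr
      denom <- if (velocity_mode == "bin_time") {
        if (z == "all") b[2] - b[1] else t_mov + t_not
      } else t_mov
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = attr(traj, "subject_id"),
        genotype = attr(traj, "genotype"),
        treatment = attr(traj, "treatment"),
        bin_start = b[1], bin_end = b[2], zone = z,
        total_distance = d,
        mean_velocity = if (denom > 0) d / denom else NA_real_,
        fast_movement_count = count_fast_movements(
          ifelse(sel, speeds, 0), fast_threshold),
        duration_moving = t_mov,
        duration_not_moving = t_not
      )
    }
  }
  do.call(rbind, rows)
}
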