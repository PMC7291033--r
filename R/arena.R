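#' Circular arena geometry
#'
#' Describes the circular well (open-field assay) or dish (light-preference
#' assay) a larva swims in.  The disc is partitioned two ways: a border
#' annulus of width `border_width` measured inward from the wall versus the
#' central disc, and a dark versus light half-plane split on the sign of the
#' x-coordinate.
#'
#' @param radius Arena radius in mm (> 0).
#' @param border_width Width of the border annulus in mm, measured inward
#'   from the wall; must lie strictly between 0 and `radius`.  Default 4 mm,
#'   roughly one body length of a 4 dpf larva.
#' @param shape `"circular_well"` (12-well plate well) or `"circular_dish"`
#'   (Petri dish, used for the light-preference assay).
#' @param dark_half Which half-plane is dark: `"x_negative"` (default) or
#'   `"x_positive"`.  Points exactly on x = 0 count as light.
#' @return An object of class `arena`.
#' @examples
#' a <- arena(radius = 11, border_width = 4)
#' zone_of_point(a, c(0, 0))
#' @export
arena <- function(radius, border_width = 4,
                  shape = c("circular_well", "circular_dish"),
                  dark_half = c("x_negative", "x_positive")) {
  shape <- match.arg(shape)
  dark_half <- match.arg(dark_half)
  stopifnot(is.numeric(radius), length(radius) == 1L, is.finite(radius))
  if (radius <= 0) stop("arena radius must be > 0")
  if (!is.numeric(border_width) || length(border_width) != 1L ||
      border_width <= 0 || border_width >= radius) {
    stop("border_width must satisfy 0 < border_width < radius")
  }
  structure(
    list(shape = shape, radius = radius, border_width = border_width,
         dark_half = dark_half),
    class = "arena"
  )
}

#' @export
print.arena <- function(x, ...) {
  cat(sprintf("<arena> %s, radius %.6g mm, border width %.6g mm, dark half: %s\n",
              x$shape, x$radius, x$border_width, x$dark_half))
  invisible(x)
}

#' Border/center zone of a point
#'
#' A point is in the border zone iff its distance from the wall,
#' `radius - sqrt(x^2 + y^2)`, is less than or equal to `border_width`.
#'
#' @param arena An [arena()].
#' @param point Numeric of length 2 `(x, y)` in mm, or an n x 2 matrix of
#'   points (origin at the arena center).
#' @param tol Points up to `tol * radius` outside the wall are treated as on
#'   the wall (tracking jitter); beyond that is an error.
#' @return Character vector, `"border"` or `"center"` per point.
#' @export
zone_of_point <- function(arena, point, tol = 0.02) {
  pts <- as_points(point)
  r <- sqrt(pts[, 1]^2 + pts[, 2]^2)
  if (any(r > arena$radius * (1 + tol))) {
    stop("point outside the arena beyond the clamping tolerance")
  }
  r <- pmin(r, arena$radius)
  ifelse(arena$radius - r <= arena$border_width, "border", "center")
}

#' Light/dark side of a point
#'
#' Half of the dish is covered so that one half-plane is dark.  Under the
#' default convention x < 0 is dark; x = 0 exactly is assigned to light
#' (a deterministic tie-break of measure zero).
#'
#' @inheritParams zone_of_point
#' @return Character vector, `"light"` or `"dark"` per point.
#' @export
light_side_of_point <- function(arena, point) {
  pts <- as_points(point)
  x <- pts[, 1]
  dark <- if (arena$dark_half == "x_negative") x < 0 else x > 0
  ifelse(dark, "dark", "light")
}

as_points <- function(point) {
  if (is.matrix(point)) {
    stopifnot(ncol(point) == 2L)
    return(point)
  }
  stopifnot(is.numeric(point), length(point) == 2L)
  matrix(point, ncol = 2L)
}

#' Single-subject trajectory
#'
#' A uniformly sampled 2-D track for one larva, with genotype and treatment
#' labels.  Coordinates are mm with the origin at the arena center; time is
#' seconds from recording start.
#'
#' @param time Numeric vector of sample times (s), strictly increasing and
#'   uniformly spaced.
#' @param x,y Coordinates in mm, same length as `time`.
#' @param subject_id Identifier string.
#' @param genotype `"WT"` or `"mutant"`.
#' @param treatment Treatment label, e.g. `"none"`, `"PTZ_15mM"`,
#'   `"glutamate_600uM"`.
#' @param sample_rate Sampling rate in Hz; inferred from `time` when `NULL`.
#' @return An object of class `trajectory`: a data frame with columns
#'   `time`, `x`, `y` and attributes for the labels and sample rate.
#' @export
trajectory <- function(time, x, y, subject_id = "s1", genotype = "WT",
                       treatment = "none", sample_rate = NULL) {
  n <- length(time)
  stopifnot(n >= 1L, length(x) == n, length(y) == n)
  if (n >= 2L) {
    dt <- diff(time)
    if (any(dt <= 0) || max(abs(dt - dt[1])) > 1e-6 * dt[1] + 1e-9) {
      stop("trajectory timestamps must be strictly increasing and uniform")
    }
    inferred <- 1 / dt[1]
  } else {
    inferred <- if (is.null(sample_rate)) 1 else sample_rate
  }
  if (is.null(sample_rate)) sample_rate <- inferred
  out <- data.frame(time = time, x = x, y = y)
  attr(out, "subject_id") <- as.character(subject_id)
  attr(out, "genotype") <- as.character(genotype)
  attr(out, "treatment") <- as.character(treatment)
  attr(out, "sample_rate") <- sample_rate
  class(out) <- c("trajectory", "data.frame")
  out
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> subject %s (%s, %s): %d samples at %.6g Hz, %.6g s\n",
              attr(x, "subject_id"), attr(x, "genotype"), attr(x, "treatment"),
              nrow(x), attr(x, "sample_rate"),
              nrow(x) / attr(x, "sample_rate")))
  invisible(x)
}

#' Validate and clean a trajectory against an arena
#'
#' Asserts uniform sampling, clamps small excursions beyond the wall
#' (tracking jitter, up to `tol` of the radius) back onto the wall, and
#' rejects tracks with larger excursions as corrupt.
#'
#' @param traj A [trajectory()].
#' @param arena An [arena()].
#' @param tol Clamping tolerance as a fraction of the radius (default 0.02).
#' @return The cleaned trajectory, with an attribute `n_clamped` giving the
#'   number of clamped samples.
#' @export
validate_trajectory <- function(traj, arena, tol = 0.02) {
  stopifnot(inherits(traj, "trajectory"), inherits(arena, "arena"))
  if (nrow(traj) == 0L) stop("trajectory is empty")
  r <- sqrt(traj$x^2 + traj$y^2)
  bad <- r > arena$radius * (1 + tol)
  if (any(bad)) {
    stop(sprintf(
      "%d sample(s) lie more than %.1f%% of the radius outside the wall; tracking data considered corrupt",
      sum(bad), 100 * tol))
  }
  out <- traj
  clamp <- r > arena$radius
  if (any(clamp)) {
    scale <- arena$radius / r[clamp]
    out$x[clamp] <- out$x[clamp] * scale
    out$y[clamp] <- out$y[clamp] * scale
  }
  attr(out, "n_clamped") <- sum(clamp)
  out
}

#' Light-phase schedule
#'
#' Ordered, contiguous, half-open `[start, end)` intervals of constant light
#' intensity, e.g. the visual-motor-response protocol: baseline 0-600 s at
#' 0% light, low-activity 600-1200 s at 70%, high-activity 1200-1800 s at 0%.
#'
#' @param name Character vector of phase names.
#' @param start,end Phase boundaries in seconds; must be contiguous
#'   (`end[i] == start[i+1]`) and start at the recording origin.
#' @param light_intensity Percent of maximum light per phase.
#' @return An object of class `phase_schedule` (a data frame).
#' @export
phase_schedule <- function(name, start, end, light_intensity) {
  n <- length(name)
  stopifnot(n >= 1L, length(start) == n, length(end) == n,
            length(light_intensity) == n)
  if (any(end <= start)) stop("each phase must have end > start")
  if (n > 1L && any(abs(start[-1] - end[-n]) > 1e-9)) {
    stop("phases must be contiguous and non-overlapping")
  }
  out <- data.frame(name = as.character(name), start = start, end = end,
                    light_intensity = light_intensity)
  class(out) <- c("phase_schedule", "data.frame")
  out
}

#' The standard three-phase visual-motor-response schedule
#'
#' Baseline (0% light), low-activity (70% light), high-activity (0% light),
#' each `phase_length` seconds long.
#'
#' @param phase_length Length of each phase in seconds (default 600).
#' @return A [phase_schedule()].
#' @export
vmr_schedule <- function(phase_length = 600) {
  phase_schedule(
    name = c("baseline", "low_activity", "high_activity"),
    start = c(0, 1, 2) * phase_length,
    end = c(1, 2, 3) * phase_length,
    light_intensity = c(0, 70, 0)
  )
}

#' Phase label for each time point
#'
#' @param schedule A [phase_schedule()].
#' @param t Numeric vector of times (s).  Times at or beyond the final phase
#'   end are assigned to the final phase (the recording endpoint).
#' @return Character vector of phase names.
#' @export
phase_at <- function(schedule, t) {
  idx <- findInterval(t, schedule$start)
  idx[idx < 1L] <- 1L
  idx[idx > nrow(schedule)] <- nrow(schedule)
  schedule$name[idx]
}

#' Light-transition times of a schedule
#'
#' @param schedule A [phase_schedule()].
#' @return Numeric vector of interior phase-boundary times (s) at which the
#'   light intensity changes; empty when there is no change.
#' @export
schedule_transitions <- function(schedule) {
  if (nrow(schedule) < 2L) return(numeric(0))
  chg <- which(diff(schedule$light_intensity) != 0)
  schedule$start[chg + 1L]
}
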