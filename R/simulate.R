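#' Behavior simulation parameters
#'
#' Parameters of the correlated-random-walk larva model: a two-state
#' (quiescent/bout) speed process, Gaussian heading turns with an optional
#' attraction toward the nearest wall (thigmotaxis), per-phase speed
#' modulation with a post-transition startle boost, and Poisson-timed
#' seizure-like bursts rendered as fast constant-speed circling.
#'
#' @param bout_rate Probability per second of entering a swim bout (1/s).
#' @param bout_speed_mean Mean bout speed (mm/s).
#' @param bout_speed_shape Gamma shape of the bout-speed distribution.
#' @param turn_sd Heading turn SD per step (radians).
#' @param wall_bias Strength (1/s) of heading attraction toward the nearest
#'   wall; 0 gives an unbiased walk.
#' @param light_speed_multiplier Named list/vector mapping phase names to
#'   speed factors (phases not named get factor 1).
#' @param startle_boost Speed factor applied for `startle_window` seconds
#'   after each light transition.
#' @param startle_window Duration of the startle boost (s).
#' @param seizure_rate Seizure-like burst rate (events/min).
#' @param seizure_speed Speed during a burst (mm/s).
#' @param seizure_angular_velocity Signed magnitude of circling angular
#'   velocity during a burst (rad/s); the sign is drawn per burst.
#' @param seizure_duration Burst duration (s).
#' @param rng_seed Integer seed; the same parameters and seed reproduce the
#'   trajectory bit for bit.
#' @return An object of class `behavior_params`.
#' @export
behavior_params <- function(bout_rate = 1, bout_speed_mean = 4,
                            bout_speed_shape = 4, turn_sd = 0.6,
                            wall_bias = 0,
                            light_speed_multiplier = list(),
                            startle_boost = 1, startle_window = 5,
                            seizure_rate = 0, seizure_speed = 8,
                            seizure_angular_velocity = 2 * pi / 5,
                            seizure_duration = 5,
                            rng_seed = 1L) {
  p <- list(bout_rate = bout_rate, bout_speed_mean = bout_speed_mean,
            bout_speed_shape = bout_speed_shape, turn_sd = turn_sd,
            wall_bias = wall_bias,
            light_speed_multiplier = as.list(light_speed_multiplier),
            startle_boost = startle_boost, startle_window = startle_window,
            seizure_rate = seizure_rate, seizure_speed = seizure_speed,
            seizure_angular_velocity = seizure_angular_velocity,
            seizure_duration = seizure_duration,
            rng_seed = as.integer(rng_seed))
  nonneg <- c("bout_rate", "bout_speed_mean", "turn_sd", "wall_bias",
              "seizure_rate", "seizure_speed", "seizure_duration",
              "startle_window")
  for (f in nonneg) if (p[[f]] < 0) stop(sprintf("%s must be >= 0", f))
  if (p$bout_speed_shape <= 0) stop("bout_speed_shape must be > 0")
  if (p$startle_boost <= 0) stop("startle_boost must be > 0")
  if (any(unlist(p$light_speed_multiplier) <= 0)) {
    stop("light_speed_multiplier factors must be > 0")
  }
  structure(p, class = "behavior_params")
}

# Bout speeds are gamma draws capped here, so the maximum step speed the
# simulator can produce is bounded in closed form.
bout_speed_cap <- function(params) 5 * params$bout_speed_mean

# Fixed burst-swim bout duration (s); typical 4 dpf larval burst length.
BOUT_DURATION <- 0.2

#' Simulate one larva trajectory
#'
#' Correlated random walk in a circular arena.  Each step the heading gains
#' a Gaussian turn plus `wall_bias * dt` times the wrapped angle toward the
#' outward radial (nearest-wall) direction.  Quiescent larvae are still;
#' with probability `bout_rate * dt` a 0.2 s bout starts, with speed drawn
#' from a gamma distribution (mean `bout_speed_mean`, shape
#' `bout_speed_shape`, capped at five times the mean).  The per-phase speed
#' factor from `light_speed_multiplier` applies, and for `startle_window`
#' seconds after each light transition speeds are further multiplied by
#' `startle_boost`.  Poisson-timed seizure-like bursts override locomotion
#' with constant speed `seizure_speed` and constant signed angular velocity
#' (whirlpool-like circling).  Positions are reflected at the wall.
#'
#' @param params A [behavior_params()].
#' @param arena An [arena()].
#' @param schedule A [phase_schedule()] spanning the requested duration.
#' @param sample_rate Sampling rate in Hz (default 25).
#' @param duration Recording length in s; defaults to the schedule span.
#' @param subject_id,genotype,treatment Labels stored on the trajectory.
#' @return A [trajectory()] with an attribute `seizure_starts` giving the
#'   ground-truth burst onset times (s).
#' @export
simulate_trajectory <- function(params, arena, schedule,
                                sample_rate = 25, duration = NULL,
                                subject_id = "sim1", genotype = "WT",
                                treatment = "none") {
  stopifnot(inherits(params, "behavior_params"), inherits(arena, "arena"),
            inherits(schedule, "phase_schedule"))
  if (is.null(duration)) duration <- max(schedule$end)
  if (max(schedule$end) < duration - 1e-9) {
    stop("schedule does not span the requested duration")
  }
  dt <- 1 / sample_rate
  vmax <- max(bout_speed_cap(params), params$seizure_speed)
  if (vmax * dt > 2 * arena$radius) {
    stop("unsatisfiable geometry: one step exceeds the arena diameter")
  }
  n <- floor(duration * sample_rate) + 1L
  tt <- (seq_len(n) - 1L) * dt

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(params$rng_seed)

  # precompute per-sample multipliers and seizure state
  phase <- phase_at(schedule, tt)
  mult <- rep(1, n)
  for (nm in names(params$light_speed_multiplier)) {
    mult[phase == nm] <- params$light_speed_multiplier[[nm]]
  }
  trans <- schedule_transitions(schedule)
  if (length(trans) && params$startle_boost != 1) {
    for (tr in trans) {
      w <- tt >= tr & tt < tr + params$startle_window
      mult[w] <- mult[w] * params$startle_boost
    }
  }
  n_sz <- stats::rpois(1, params$seizure_rate / 60 * duration)
  sz_start <- sort(stats::runif(n_sz, 0, duration))
  sz_sign <- sample(c(-1, 1), n_sz, replace = TRUE)
  in_seizure <- integer(n)  # 0 = none, else index of active burst
  for (k in seq_len(n_sz)) {
    w <- tt >= sz_start[k] & tt < sz_start[k] + params$seizure_duration
    in_seizure[w] <- k
  }

  x <- y <- numeric(n)
  # start at a uniform random point in the disc
  r0 <- arena$radius * sqrt(stats::runif(1))
  a0 <- stats::runif(1, 0, 2 * pi)
  x[1] <- r0 * cos(a0); y[1] <- r0 * sin(a0)
  theta <- stats::runif(1, 0, 2 * pi)
  bout_left <- 0
  bout_v <- 0
  turns <- stats::rnorm(n, 0, params$turn_sd)
  bout_trigger <- stats::runif(n) < params$bout_rate * dt
  speed_draws <- pmin(
    stats::rgamma(n, shape = params$bout_speed_shape,
                  scale = params$bout_speed_mean / params$bout_speed_shape),
    bout_speed_cap(params))

  for (i in 2:n) {
    sz <- in_seizure[i - 1L]
    if (sz > 0L) {
      v <- params$seizure_speed
      theta <- theta + sz_sign[sz] * params$seizure_angular_velocity * dt
    } else {
      if (bout_left <= 0 && bout_trigger[i]) {
        bout_left <- BOUT_DURATION
        bout_v <- speed_draws[i]
      }
      v <- if (bout_left > 0) bout_v * mult[i - 1L] else 0
      v <- min(v, bout_speed_cap(params))
      bout_left <- bout_left - dt
      theta <- theta + turns[i]
      if (params$wall_bias > 0 && v > 0) {
        outward <- atan2(y[i - 1L], x[i - 1L])
        d <- wrap_angle(outward - theta)
        theta <- theta + params$wall_bias * d * dt
      }
    }
    xn <- x[i - 1L] + v * dt * cos(theta)
    yn <- y[i - 1L] + v * dt * sin(theta)
    rn <- sqrt(xn^2 + yn^2)
    if (rn > arena$radius) {
      # fold the radial overshoot back inside and reflect the heading
      phi <- atan2(yn, xn)
      rr <- max(2 * arena$radius - rn, 0)
      xn <- rr * cos(phi); yn <- rr * sin(phi)
      theta <- wrap_angle(2 * phi + pi - theta)
    }
    x[i] <- xn; y[i] <- yn
  }

  out <- trajectory(tt, x, y, subject_id = subject_id, genotype = genotype,
                    treatment = treatment, sample_rate = sample_rate)
  attr(out, "seizure_starts") <- sz_start
  out
}

wrap_angle <- function(a) {
  ((a + pi) %% (2 * pi)) - pi
}

# Deterministic per-subject seed from a master seed; keeps cohorts
# reproducible independent of cohort size. Stays below 2^31.
derive_seed <- function(master_seed, index) {
  as.integer((as.double(master_seed) * 48271 + index * 16807) %% 2147483647)
}

#' Simulate a labeled cohort of trajectories
#'
#' Independent subjects per genotype with distinct per-subject seeds derived
#' deterministically from `master_seed`, so the same master seed always
#' reproduces the same cohort.
#'
#' @param genotype_params Named list mapping genotype label to a
#'   [behavior_params()] (its `rng_seed` is ignored in favor of derived
#'   per-subject seeds).
#' @param n_per_group Subjects per genotype (>= 1).
#' @param arena,schedule,sample_rate,duration Passed to
#'   [simulate_trajectory()].
#' @param master_seed Integer master seed.
#' @param treatment Treatment label applied to all subjects.
#' @return List of [trajectory()] objects.
#' @export
simulate_cohort <- function(genotype_params, n_per_group, arena, schedule,
                            sample_rate = 25, duration = NULL,
                            master_seed = 1L, treatment = "none") {
  stopifnot(n_per_group >= 1, length(genotype_params) >= 1,
            !is.null(names(genotype_params)))
  out <- list()
  idx <- 0L
  for (g in names(genotype_params)) {
    p <- genotype_params[[g]]
    for (j in seq_len(n_per_group)) {
      idx <- idx + 1L
      p$rng_seed <- derive_seed(master_seed, idx)
      out[[idx]] <- simulate_trajectory(
        p, arena, schedule, sample_rate = sample_rate, duration = duration,
        subject_id = sprintf("%s_%02d", g, j), genotype = g,
        treatment = treatment)
    }
  }
  out
}

#' Calcium simulation parameters
#'
#' Parameters of the synthetic GCaMP-like fluorescence model: per cell,
#' Poisson-timed transients, each a difference-of-exponentials kernel
#' (rise `rise_tau`, decay `decay_tau`, normalized to unit peak) scaled by
#' a gamma-distributed amplitude, on top of a baseline, linear drift and
#' white Gaussian noise.
#'
#' @param n_cells Number of cells.
#' @param duration Recording length (s); default 300 (5 min).
#' @param sample_rate Frames per second; default 1.
#' @param event_rate Transient rate per cell (Hz).
#' @param amplitude_mean Mean transient amplitude (AU).
#' @param amplitude_cv Coefficient of variation of amplitudes.
#' @param decay_tau,rise_tau Kernel time constants (s), `decay_tau >
#'   rise_tau > 0`.
#' @param baseline Baseline fluorescence (AU).
#' @param noise_sd White-noise SD (AU).
#' @param drift_slope Linear drift (AU/s).
#' @param rng_seed Integer seed.
#' @return An object of class `calcium_params`.
#' @export
calcium_params <- function(n_cells = 50, duration = 300, sample_rate = 1,
                           event_rate = 0.033, amplitude_mean = 10,
                           amplitude_cv = 0.2, decay_tau = 1.5,
                           rise_tau = 0.2, baseline = 100, noise_sd = 1,
                           drift_slope = 0, rng_seed = 1L) {
  if (!(decay_tau > rise_tau && rise_tau > 0)) {
    stop("must have decay_tau > rise_tau > 0")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (n_cells < 1) stop("n_cells must be >= 1")
  structure(list(n_cells = as.integer(n_cells), duration = duration,
                 sample_rate = sample_rate, event_rate = event_rate,
                 amplitude_mean = amplitude_mean, amplitude_cv = amplitude_cv,
                 decay_tau = decay_tau, rise_tau = rise_tau,
                 baseline = baseline, noise_sd = noise_sd,
                 drift_slope = drift_slope, rng_seed = as.integer(rng_seed)),
            class = "calcium_params")
}

# Difference-of-exponentials transient, normalized to unit peak.
calcium_kernel <- function(t, rise_tau, decay_tau) {
  raw <- function(s) ifelse(s < 0, 0, exp(-s / decay_tau) - exp(-s / rise_tau))
  tpk <- log(decay_tau / rise_tau) / (1 / rise_tau - 1 / decay_tau)
  raw(t) / raw(tpk)
}

#' Simulate GCaMP-like fluorescence traces
#'
#' @param params A [calcium_params()].
#' @return A list with `traces` (frames x cells matrix, column names
#'   `cell_01` ...), `time` (s), and ground truth `events` (list per cell of
#'   event times, s) and `amplitudes` (list per cell, AU).
#' @export
simulate_calcium_traces <- function(params) {
  stopifnot(inherits(params, "calcium_params"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(params$rng_seed)

  n <- floor(params$duration * params$sample_rate)
  tt <- (seq_len(n) - 1L) / params$sample_rate
  traces <- matrix(0, nrow = n, ncol = params$n_cells)
  events <- vector("list", params$n_cells)
  amps <- vector("list", params$n_cells)
  shape <- if (params$amplitude_cv > 0) 1 / params$amplitude_cv^2 else Inf
  for (c in seq_len(params$n_cells)) {
    k <- stats::rpois(1, params$event_rate * params$duration)
    et <- sort(stats::runif(k, 0, params$duration))
    ea <- if (k == 0) numeric(0) else if (is.finite(shape)) {
      stats::rgamma(k, shape = shape, scale = params$amplitude_mean / shape)
    } else rep(params$amplitude_mean, k)
    v <- params$baseline + params$drift_slope * tt
    for (j in seq_len(k)) {
      v <- v + ea[j] * calcium_kernel(tt - et[j], params$rise_tau,
                                      params$decay_tau)
    }
    if (params$noise_sd > 0) v <- v + stats::rnorm(n, 0, params$noise_sd)
    traces[, c] <- v
    events[[c]] <- et
    amps[[c]] <- ea
  }
  colnames(traces) <- sprintf("cell_%02d", seq_len(params$n_cells))
  list(traces = traces, time = tt, events = events, amplitudes = amps)
}
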