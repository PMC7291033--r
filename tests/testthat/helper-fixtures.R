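# Fixture builders shared across the suite.  Everything is generated in
# code; no stored data files.

default_arena <- function() arena(radius = 11, border_width = 4)

dish_arena <- function() arena(radius = 30, border_width = 4,
                               shape = "circular_dish")

# Trajectory that realizes a prescribed per-step speed series at 1 Hz by
# walking along +x then bouncing between two x positions (stays near the
# origin so it remains inside any reasonable arena when scaled down).
traj_from_speeds <- function(speeds, sample_rate = 1, subject_id = "s1",
                             genotype = "WT") {
  dt <- 1 / sample_rate
  step <- speeds * dt
  # fold the path back and forth along x inside [-1, 1] * sum(step)
  x <- cumsum(c(0, step * rep_len(c(1, -1), length(step))))
  trajectory(seq_along(x) * dt - dt, x, rep(0, length(x)),
             subject_id = subject_id, genotype = genotype,
             sample_rate = sample_rate)
}

# Stationary subject at a fixed point.
still_traj <- function(n = 11, at = c(0, 0), sample_rate = 1,
                       subject_id = "still") {
  trajectory((seq_len(n) - 1) / sample_rate, rep(at[1], n), rep(at[2], n),
             subject_id = subject_id, sample_rate = sample_rate)
}

# Circular path: `revs` full revolutions over `duration` seconds.
circle_traj <- function(radius = 5, revs = 1, duration = 60,
                        sample_rate = 25) {
  n <- duration * sample_rate + 1
  a <- seq(0, 2 * pi * revs, length.out = n)
  trajectory((seq_len(n) - 1) / sample_rate, radius * cos(a),
             radius * sin(a), subject_id = "circle",
             sample_rate = sample_rate)
}

# Trajectory whose distance in consecutive 60 s windows equals
# `per_minute` mm (constant speed within each minute), at 1 Hz.
traj_per_minute <- function(per_minute, sample_rate = 1) {
  speeds <- rep(per_minute / 60, each = 60 * sample_rate) * 1
  traj_from_speeds(speeds, sample_rate = sample_rate)
}

# Independent brute-force oracles -------------------------------------------

# Run-length count of supra-threshold events, written as an explicit loop.
oracle_fast_events <- function(speeds, thr) {
  count <- 0L
  inside <- FALSE
  for (s in speeds) {
    if (s > thr && !inside) {
      count <- count + 1L
      inside <- TRUE
    } else if (s <= thr) inside <- FALSE
  }
  count
}

# Tumbling-window seizure scan, explicit loop over windows.
oracle_seizure <- function(traj, window, thr) {
  t0 <- traj$time[1]
  rec <- traj$time[nrow(traj)] - t0
  n_win <- floor(rec / window + 1e-9)
  hits <- numeric(0)
  starts <- numeric(0)
  for (w in seq_len(n_win)) {
    a <- t0 + (w - 1) * window
    b <- a + window
    d <- 0
    for (i in seq_len(nrow(traj) - 1L)) {
      if (traj$time[i] >= a - 1e-9 && traj$time[i] < b - 1e-9) {
        d <- d + sqrt((traj$x[i + 1] - traj$x[i])^2 +
                        (traj$y[i + 1] - traj$y[i])^2)
      }
    }
    if (d > thr) {
      hits <- c(hits, d)
      starts <- c(starts, a)
    }
  }
  list(starts = starts, amplitudes = hits)
}

# Local-maximum peak finder with the same sequential prominence rule,
# written against the smoothed trace without the slope-sign machinery.
oracle_peaks <- function(v, smooth_window, min_rise) {
  s <- larvatrax:::moving_average(v, smooth_window)
  n <- length(s)
  is_max <- logical(n)
  for (i in 2:(n - 1)) {
    # strict local max, or right edge of a plateau that then falls
    if (s[i] > s[i - 1] && s[i] >= s[i + 1]) {
      j <- i
      while (j < n && s[j + 1] == s[i]) j <- j + 1
      if (j == n || s[j + 1] < s[i]) is_max[i] <- TRUE
    }
  }
  cand <- which(is_max)
  acc <- integer(0)
  from <- 1L
  for (p in cand) {
    tr <- min(s[from:p])
    if (s[p] - tr >= min_rise) {
      acc <- c(acc, p)
      from <- p
    }
  }
  acc
}

# Exact two-sided Mann-Whitney p by full enumeration of rank assignments.
oracle_ranksum_exact <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  us <- apply(combos, 2, function(idx) sum(idx) - n1 * (n1 + 1) / 2)
  mu <- n1 * n2 / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Noise-free synthetic event train rendered with the package kernel.
event_train_trace <- function(event_times, amps, n = 120, rise = 0.2,
                              decay = 1.5) {
  tt <- seq_len(n) - 1
  v <- rep(0, n)
  for (j in seq_along(event_times)) {
    v <- v + amps[j] * larvatrax:::calcium_kernel(tt - event_times[j],
                                                  rise, decay)
  }
  v
}
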