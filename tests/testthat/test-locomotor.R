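test_that("step speeds follow the Euclidean step-length rule", {
  tr <- trajectory(0:1, c(0, 3), c(0, 4))
  expect_equal(step_speeds(tr), 5)
  expect_equal(step_speeds(still_traj(5)), rep(0, 4))
  sq <- trajectory(0:4, c(0, 1, 1, 0, 0), c(0, 0, 1, 1, 0))
  expect_equal(step_speeds(sq), rep(1, 4))
  expect_error(step_speeds(trajectory(0, 0, 0)), "2 samples")
})

test_that("movement classification and moving fraction behave", {
  expect_equal(classify_movement(c(0, 0, 5), 2), c(FALSE, FALSE, TRUE))
  expect_true(all(classify_movement(c(1, 2, 3), 0)))
  # sinusoidal speed cut at its median moves half the time
  sp <- 5 + 4 * sin(seq(0, 8 * pi, length.out = 400))
  mv <- classify_movement(sp, stats::median(sp))
  expect_lt(abs(mean(mv) - 0.5), 1 / length(sp) * 4)
})

test_that("fast movements are counted as maximal supra-threshold runs", {
  expect_equal(count_fast_movements(c(10, 25, 30, 5), 20), 1L)
  expect_equal(count_fast_movements(c(5, 10, 20), 20), 0L)  # strict >
  expect_equal(count_fast_movements(c(25, 5, 25), 20), 2L)
})

test_that("run counting matches a brute-force scan on random series", {
  set.seed(42)
  for (i in 1:1000) {
    sp <- stats::rexp(sample(5:60, 1), rate = 1 / 15)
    thr <- stats::runif(1, 5, 30)
    expect_identical(count_fast_movements(sp, thr),
                     oracle_fast_events(sp, thr))
  }
})

test_that("zone occupancy assigns intervals by starting point and conserves time", {
  a <- default_arena()
  # alternate center (0,0) and border (10,0) every second for 10 s
  xs <- rep(c(0, 10), 5)
  tr <- trajectory(0:9, xs, rep(0, 10))
  occ <- zone_occupancy(tr, a, partition = "border_center")
  expect_equal(occupancy_time <- occ$duration_moving + occ$duration_not_moving,
               c(4, 5)[match(occ$zone, c("border", "center"))])
  expect_equal(sum(occ$duration_moving) + sum(occ$duration_not_moving),
               9)  # n - 1 intervals of 1 s

  # stationary at center: all time not-moving in center
  st <- still_traj(301)
  occ2 <- zone_occupancy(st, a)
  expect_equal(occ2$duration_not_moving[occ2$zone == "center"], 300)
  expect_equal(sum(occ2$duration_moving), 0)
})

test_that("thigmotaxis and phototaxis indices are normalized percentages", {
  a <- default_arena()
  st <- still_traj(301, at = c(10, 0))  # border, also light side
  occ <- zone_occupancy(st, a, partition = "border_center")
  expect_equal(thigmotaxis_index(occ), 100)

  # 241 of 300 interval-seconds start in the border
  xs <- c(rep(10, 241), rep(0, 60))
  tr <- trajectory(seq_along(xs) - 1, xs, rep(0, length(xs)))
  occ <- zone_occupancy(tr, a, partition = "border_center")
  expect_equal(thigmotaxis_index(occ), 100 * 241 / 300)

  # complementarity holds exactly for arbitrary occupancies
  set.seed(7)
  for (i in 1:20) {
    o <- structure(data.frame(zone = c("border", "center"),
                              duration_moving = runif(2, 0, 100),
                              duration_not_moving = runif(2, 0, 100)),
                   class = c("zone_occupancy", "data.frame"))
    expect_equal(thigmotaxis_index(o) +
                   larvatrax:::zone_time_index(o, "center"), 100)
    o$zone <- c("light", "dark")
    expect_equal(phototaxis_index(o) +
                   larvatrax:::zone_time_index(o, "dark"), 100)
  }

  d <- dish_arena()
  lightward <- still_traj(301, at = c(5, 0))
  expect_equal(phototaxis_index(
    zone_occupancy(lightward, d, partition = "light_dark")), 100)
})

test_that("light-preference classes use the printed cutoffs", {
  expect_equal(as.character(classify_light_preference(75)), "phototaxis")
  expect_equal(as.character(classify_light_preference(25)), "scototaxis")
  expect_equal(as.character(classify_light_preference(50)), "no_preference")
  # boundaries are unclaimed by the strict printed rules -> no preference
  expect_equal(as.character(classify_light_preference(c(30, 70))),
               rep("no_preference", 2))
  expect_error(classify_light_preference(101), "\\[0, 100\\]")
  expect_error(classify_light_preference(-1), "\\[0, 100\\]")
})

test_that("activity filter rejects inactive larvae at the 10 mm rule", {
  lazy <- traj_from_speeds(rep(0.5, 10))   # 5 mm total
  edge <- traj_from_speeds(rep(1, 10))     # exactly 10 mm -> kept
  busy <- traj_from_speeds(rep(5, 100))    # 500 mm
  res <- activity_filter(list(lazy, edge, busy))
  expect_length(res$kept, 2)
  expect_length(res$rejected, 1)
  expect_equal(res$log$kept, c(FALSE, TRUE, TRUE))
  expect_match(res$log$reason[1], "< 10 mm")
})

test_that("binned metrics satisfy the distance identities", {
  a <- default_arena()
  tr <- traj_from_speeds(rep(3, 300))  # 3 mm/s for 300 s
  m <- bin_metrics(tr, a, list(c(0, 300)))
  all_row <- m[m$zone == "all", ]
  expect_equal(all_row$total_distance, 900)
  expect_equal(all_row$mean_velocity, 3)

  # per-bin distances sum to the total distance exactly
  m2 <- bin_metrics(tr, a, list(c(0, 150), c(150, 300)))
  expect_equal(sum(m2$total_distance[m2$zone == "all"]), total_distance(tr))

  # two halves of a time-homogeneous walk travel similar distances
  p <- behavior_params(bout_rate = 2, bout_speed_mean = 5, rng_seed = 13)
  sim <- simulate_trajectory(p, a, phase_schedule("flat", 0, 600, 0),
                             sample_rate = 10)
  m3 <- bin_metrics(sim, a, list(c(0, 300), c(300, 600)))
  d <- m3$total_distance[m3$zone == "all"]
  expect_lt(abs(d[1] - d[2]) / mean(d), 0.25)
  expect_equal(sum(d), total_distance(sim), tolerance = 1e-9)

  expect_error(bin_metrics(tr, a, list(c(250, 400))), "outside")
})

test_that("wall-biased cohorts show higher thigmotaxis, detected by rank-sum", {
  a <- default_arena()
  s <- phase_schedule("flat", 0, 120, 0)
  gp <- list(unbiased = behavior_params(bout_rate = 3, bout_speed_mean = 6,
                                        turn_sd = 1.2, wall_bias = 0),
             biased = behavior_params(bout_rate = 3, bout_speed_mean = 6,
                                      turn_sd = 1.2, wall_bias = 6))
  cohort <- simulate_cohort(gp, 20, a, s, sample_rate = 5, master_seed = 99)
  idx <- vapply(cohort, function(tr)
    thigmotaxis_index(zone_occupancy(tr, a)), numeric(1))
  g <- vapply(cohort, function(tr) attr(tr, "genotype"), character(1))
  expect_gt(stats::median(idx[g == "biased"]),
            stats::median(idx[g == "unbiased"]))
  r <- rank_sum(idx[g == "biased"], idx[g == "unbiased"])
  expect_lt(r$p_value, 0.05)
})
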