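test_that("detrending removes lines and preserves bump height", {
  tt <- 0:199
  line <- calcium_trace(3 + 0.05 * tt)
  expect_equal(detrend_trace(line, "none")$values, line$values)
  expect_lt(max(abs(detrend_trace(line, "linear")$values)), 1e-9)

  bump <- 6 * exp(-(tt - 100)^2 / 18)
  ramp <- calcium_trace(3 + 0.02 * tt + bump)
  det <- detrend_trace(ramp, "linear")$values
  height <- max(det) - stats::median(det[c(1:60, 140:200)])
  expect_lt(abs(height - 6) / 6, 0.05)
})

test_that("slope peak detection finds isolated bumps and nothing on flat traces", {
  tt <- 0:299
  v <- 1 * exp(-(tt - 80)^2 / 8) + 1 * exp(-(tt - 200)^2 / 8)
  pk <- detect_peaks_slope(calcium_trace(v), smooth_window = 3,
                           min_rise = 0.5)
  expect_length(pk, 2)
  expect_lte(abs(pk[1] - 81), 1)  # bump maxima at samples 81, 201 (1-based)
  expect_lte(abs(pk[2] - 201), 1)

  flat <- detect_peaks_slope(calcium_trace(rep(2, 50)), min_rise = 0.1)
  expect_length(flat, 0)
  expect_error(detect_peaks_slope(calcium_trace(rep(1, 10)),
                                  smooth_window = 11), "shorter")
})

test_that("peak count is monotone non-increasing in min_rise", {
  set.seed(5)
  for (i in 1:20) {
    v <- event_train_trace(sort(runif(8, 5, 115)), runif(8, 2, 10))
    counts <- vapply(c(0.5, 1, 2, 4, 8), function(mr)
      length(detect_peaks_slope(calcium_trace(v), min_rise = mr)),
      numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("slope detector equals the local-maximum oracle on noise-free trains", {
  set.seed(99)
  for (i in 1:1000) {
    k <- sample(1:6, 1)
    v <- event_train_trace(sort(runif(k, 3, 110)), runif(k, 2, 10), n = 120)
    mr <- runif(1, 0.3, 2)
    sw <- sample(c(1, 3, 5), 1)
    got <- as.integer(detect_peaks_slope(calcium_trace(v), sw, mr))
    want <- oracle_peaks(v, sw, mr)
    expect_identical(got, want)
  }
})

test_that("oscillation statistics satisfy the frequency identity", {
  sim <- simulate_calcium_traces(calcium_params(n_cells = 10, duration = 300,
                                                event_rate = 0.04,
                                                noise_sd = 1, rng_seed = 55))
  for (j in 1:10) {
    tr <- calcium_trace(sim$traces[, j], sample_rate = 1)
    pk <- detect_peaks_slope(tr)
    st <- oscillation_stats(tr, pk)
    expect_equal(st$frequency * 300, st$n_peaks)
  }

  # closed cases: 0 peaks -> frequency 0, amplitude missing
  quiet <- calcium_trace(rep(1, 300))
  st0 <- oscillation_stats(quiet, detect_peaks_slope(quiet, min_rise = 1))
  expect_equal(st0$frequency, 0)
  expect_true(is.na(st0$mean_amplitude))

  # single clean bump of height 2 from baseline 0
  tt <- 0:299
  one <- calcium_trace(2 * exp(-(tt - 150)^2 / 18))
  pk1 <- detect_peaks_slope(one, smooth_window = 1, min_rise = 0.5)
  st1 <- oscillation_stats(one, pk1)
  expect_equal(st1$n_peaks, 1L)
  expect_equal(st1$mean_amplitude, 2, tolerance = 1e-6)
})

test_that("detector recovers simulated events at high SNR", {
  sim <- simulate_calcium_traces(calcium_params(
    n_cells = 50, duration = 300, event_rate = 0.05, amplitude_mean = 10,
    noise_sd = 1, rng_seed = 11))
  matched <- 0; total <- 0; false_pk <- 0; n_pk <- 0
  for (j in 1:50) {
    tr <- calcium_trace(sim$traces[, j])
    pt <- (detect_peaks_slope(tr) - 1)  # seconds at 1 Hz
    ev <- sim$events[[j]]
    total <- total + length(ev)
    n_pk <- n_pk + length(pt)
    matched <- matched +
      sum(vapply(ev, function(e) any(abs(pt - e) <= 3), logical(1)))
    if (length(pt)) {
      false_pk <- false_pk +
        sum(vapply(pt, function(p)
          length(ev) == 0 || all(abs(ev - p) > 3), logical(1)))
    }
  }
  expect_gte(matched / total, 0.90)
  expect_lte(false_pk / n_pk, 0.10)
})

test_that("estimated frequency tracks the simulated event rate", {
  rel_err <- vapply(1:20, function(seed) {
    sim <- simulate_calcium_traces(calcium_params(
      n_cells = 20, duration = 300, event_rate = 0.04, amplitude_mean = 10,
      noise_sd = 1, rng_seed = 1000 + seed))
    freq <- vapply(1:20, function(j) {
      tr <- calcium_trace(sim$traces[, j])
      oscillation_stats(tr, detect_peaks_slope(tr))$frequency
    }, numeric(1))
    abs(mean(freq) - 0.04) / 0.04
  }, numeric(1))
  expect_true(all(rel_err <= 0.15))
})

test_that("group tables carry labels and flag unlabeled cells", {
  sim <- simulate_calcium_traces(calcium_params(n_cells = 6, duration = 120,
                                                rng_seed = 2))
  stats_list <- lapply(1:6, function(j) {
    tr <- calcium_trace(sim$traces[, j], cell_id = sprintf("c%d", j))
    oscillation_stats(tr, detect_peaks_slope(tr))
  })
  tab <- group_oscillations(stats_list, rep(c("f1", "f2"), each = 3),
                            rep(c("WT", "mutant"), each = 3))
  expect_equal(nrow(tab), 6)
  expect_equal(tab$animal_id, rep(c("f1", "f2"), each = 3))
  expect_error(group_oscillations(stats_list, rep(NA, 6), rep("WT", 6)),
               "unlabeled")

  agg <- group_oscillations(stats_list, rep(c("f1", "f2"), each = 3),
                            rep(c("WT", "mutant"), each = 3),
                            aggregate_by_animal = TRUE)
  expect_equal(nrow(agg), 2)
  expect_equal(agg$frequency[agg$animal_id == "f1"],
               mean(tab$frequency[tab$animal_id == "f1"]))
})

test_that("genotype differences in event rate reach significance at the cell level", {
  simA <- simulate_calcium_traces(calcium_params(n_cells = 50, duration = 300,
                                                 event_rate = 0.02,
                                                 noise_sd = 1, rng_seed = 71))
  simB <- simulate_calcium_traces(calcium_params(n_cells = 50, duration = 300,
                                                 event_rate = 0.04,
                                                 noise_sd = 1, rng_seed = 72))
  freq <- function(sim) vapply(seq_len(ncol(sim$traces)), function(j) {
    tr <- calcium_trace(sim$traces[, j])
    oscillation_stats(tr, detect_peaks_slope(tr))$frequency
  }, numeric(1))
  r <- rank_sum(freq(simB), freq(simA))
  expect_lt(r$p_value, 0.05)
  expect_gt(stats::median(freq(simB)), stats::median(freq(simA)))
})
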