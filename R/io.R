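#' Assay configuration
#'
#' All analysis constants live here so a saved config fully determines a
#' run: arena geometry, the light-phase schedule, the thresholds (movement
#' 2 mm/s, fast movement 20 mm/s, seizure 200 mm per 60 s, activity filter
#' 10 mm, light-preference cutoffs 30/70%), calcium detector parameters,
#' and the master RNG seed.
#'
#' @param arena_radius,border_width Arena geometry (mm).
#' @param arena_shape `"circular_well"` or `"circular_dish"`.
#' @param schedule A [phase_schedule()]; default the three-phase
#'   visual-motor-response protocol.
#' @param move_threshold,fast_threshold Speed thresholds (mm/s).
#' @param seizure_window,seizure_distance Episode window (s) and distance
#'   threshold (mm).
#' @param activity_min_distance Activity-filter threshold (mm).
#' @param pref_low,pref_high Light-preference classifier cutoffs (percent).
#' @param smooth_window,min_rise_k Calcium peak-detector parameters.
#' @param startle_window Startle window after light transitions (s).
#' @param sample_rate Tracking sample rate (Hz).
#' @param master_seed Master RNG seed.
#' @return An object of class `assay_config` (a named list).
#' @export
assay_config <- function(arena_radius = 11, border_width = 4,
                         arena_shape = "circular_well",
                         schedule = vmr_schedule(),
                         move_threshold = 2, fast_threshold = 20,
                         seizure_window = 60, seizure_distance = 200,
                         activity_min_distance = 10,
                         pref_low = 30, pref_high = 70,
                         smooth_window = 3, min_rise_k = 1.5,
                         startle_window = 5,
                         sample_rate = 25, master_seed = 1L) {
  cfg <- list(arena_radius = arena_radius, border_width = border_width,
              arena_shape = arena_shape, schedule = schedule,
              move_threshold = move_threshold, fast_threshold = fast_threshold,
              seizure_window = seizure_window,
              seizure_distance = seizure_distance,
              activity_min_distance = activity_min_distance,
              pref_low = pref_low, pref_high = pref_high,
              smooth_window = smooth_window, min_rise_k = min_rise_k,
              startle_window = startle_window,
              sample_rate = sample_rate, master_seed = as.integer(master_seed))
  for (f in c("move_threshold", "fast_threshold", "seizure_window",
              "seizure_distance", "activity_min_distance", "sample_rate")) {
    if (cfg[[f]] <= 0) stop(sprintf("%s must be positive", f))
  }
  class(cfg) <- "assay_config"
  cfg
}

config_arena <- function(cfg) {
  arena(cfg$arena_radius, cfg$border_width, cfg$arena_shape)
}

#' Write / read an assay configuration as YAML
#'
#' Round-trip stable: `read_config(write_config(cfg, f))` reproduces `cfg`.
#'
#' @param cfg An [assay_config()].
#' @param path File path.
#' @return `read_config` returns the `assay_config`; `write_config` returns
#'   `path` invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "assay_config"))
  x <- unclass(cfg)
  x$schedule <- lapply(seq_len(nrow(cfg$schedule)), function(i)
    as.list(cfg$schedule[i, , drop = FALSE]))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  sched <- do.call(rbind, lapply(x$schedule, as.data.frame))
  x$schedule <- phase_schedule(sched$name, sched$start, sched$end,
                               sched$light_intensity)
  do.call(assay_config, x)
}

#' Write trajectories to a tracking CSV
#'
#' Canonical long format: columns `subject_id`, `genotype`, `treatment`,
#' `time_s`, `x_mm`, `y_mm`.
#'
#' @param trajs List of [trajectory()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(trajs, path) {
  tab <- do.call(rbind, lapply(trajs, function(tr) {
    data.frame(subject_id = attr(tr, "subject_id"),
               genotype = attr(tr, "genotype"),
               treatment = attr(tr, "treatment"),
               time_s = tr$time, x_mm = tr$x, y_mm = tr$y)
  }))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Read trajectories from a tracking CSV
#'
#' The generic dialect expects columns `subject_id`, `time_s`, `x_mm`,
#' `y_mm` (plus optional `genotype`, `treatment`).  Vendor exports are
#' handled through `column_map`, which renames file columns onto the
#' generic ones and can rescale pixel units and shift a top-left origin to
#' the arena center.  Every trajectory is validated against the arena
#' (uniform sampling, wall clamping).
#'
#' @param path CSV path.
#' @param arena An [arena()] used for validation; `NULL` skips clamping.
#' @param column_map Optional named list mapping generic names
#'   (`subject_id`, `time_s`, `x_mm`, `y_mm`, ...) to file column names,
#'   with optional entries `scale_mm_per_unit` (numeric) and
#'   `origin_offset` (length-2 numeric subtracted after scaling).
#' @return List of validated [trajectory()] objects.
#' @export
read_tracks <- function(path, arena = NULL, column_map = NULL) {
  if (!file.exists(path)) stop("tracking file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  scale <- 1
  offset <- c(0, 0)
  if (!is.null(column_map)) {
    if (!is.null(column_map$scale_mm_per_unit))
      scale <- column_map$scale_mm_per_unit
    if (!is.null(column_map$origin_offset))
      offset <- column_map$origin_offset
    for (generic in intersect(names(column_map),
                              c("subject_id", "genotype", "treatment",
                                "time_s", "x_mm", "y_mm"))) {
      src <- column_map[[generic]]
      if (!src %in% names(tab)) {
        stop(sprintf("mapped column '%s' not present in %s", src, path))
      }
      names(tab)[names(tab) == src] <- generic
    }
  }
  need <- c("subject_id", "time_s", "x_mm", "y_mm")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("missing required columns: ", paste(miss, collapse = ", "))
  }
  for (col in c("time_s", "x_mm", "y_mm")) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(v) & !is.na(tab[[col]]))
    if (any(is.na(v))) {
      stop(sprintf("non-numeric values in column '%s' (e.g. row %d)", col,
                   if (length(bad)) bad[1] else which(is.na(v))[1]))
    }
    tab[[col]] <- v
  }
  if (!"genotype" %in% names(tab)) tab$genotype <- "WT"
  if (!"treatment" %in% names(tab)) tab$treatment <- "none"
  out <- lapply(split(tab, tab$subject_id), function(d) {
    d <- d[order(d$time_s), , drop = FALSE]
    dt <- diff(d$time_s)
    if (length(dt) && (any(dt <= 0) || max(abs(dt - dt[1])) > 1e-6 * dt[1])) {
      bad <- which(abs(dt - dt[1]) > 1e-6 * dt[1])[1]
      stop(sprintf(
        "subject %s: non-uniform timestamps near row %d (gap %.6g s vs %.6g s)",
        d$subject_id[1], bad + 1L, dt[bad], dt[1]))
    }
    tr <- trajectory(d$time_s, d$x_mm * scale - offset[1],
                     d$y_mm * scale - offset[2],
                     subject_id = d$subject_id[1], genotype = d$genotype[1],
                     treatment = d$treatment[1])
    if (!is.null(arena)) tr <- validate_trajectory(tr, arena)
    tr
  })
  unname(out[unique(tab$subject_id)])
}

#' Write / read fluorescence trace matrices
#'
#' CSV with a `time_s` first column and one column per cell (header = cell
#' id), the format produced by the calcium simulator.
#'
#' @param traces Frames x cells numeric matrix.
#' @param time Frame times (s).
#' @param path CSV path.
#' @return `write_traces` returns `path` invisibly; `read_traces` returns a
#'   list of [calcium_trace()] objects.
#' @export
write_traces <- function(traces, time, path) {
  stopifnot(nrow(traces) == length(time))
  tab <- data.frame(time_s = time, traces, check.names = FALSE)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  tab <- utils::read.csv(path, check.names = FALSE)
  if (names(tab)[1] != "time_s") stop("first column must be time_s")
  tt <- tab$time_s
  dt <- diff(tt)
  if (length(dt) && (any(dt <= 0) || max(abs(dt - dt[1])) > 1e-6 * dt[1])) {
    stop("non-uniform time column in trace file")
  }
  sr <- if (length(dt)) 1 / dt[1] else 1
  lapply(names(tab)[-1], function(id)
    calcium_trace(tab[[id]], cell_id = id, sample_rate = sr))
}
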