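#' Run a complete assay pipeline
#'
#' Dispatches one of the pipeline subcommands, writes its CSV tables and a
#' plain-text report into `out_dir`, and returns a run report invisibly.
#' Output files are a pure function of `(config, inputs, seed)`: two runs
#' with the same arguments are byte-identical.
#'
#' Subcommands:
#' \describe{
#'   \item{`simulate-tracks`}{Simulate a labeled cohort; writes
#'     `tracks.csv`.  Needs `genotype_params` and `n_per_group`.}
#'   \item{`simulate-calcium`}{Simulate fluorescence traces; writes one
#'     `traces_<label>.csv` per entry of `calcium_param_list`.}
#'   \item{`openfield`}{Open-field assay on `input` tracks: activity
#'     filter, per-bin border/center metrics, thigmotaxis indices,
#'     border-vs-center paired t within genotype and genotype rank-sum
#'     comparisons.}
#'   \item{`lightpref`}{Light-preference assay: phototaxis indices,
#'     three-class response distribution and Pearson chi-square on the
#'     genotype x response table.}
#'   \item{`vmr`}{Visual-motor response: per-phase metrics, startle
#'     distances, seizure-like episodes, genotype comparisons per phase.}
#'   \item{`calcium`}{Slope-based peak detection and oscillation
#'     statistics; genotype rank-sum on frequency and amplitude.  `input`
#'     is a data frame with columns `path`, `animal_id`, `genotype`.}
#'   \item{`compare`}{Generic harness on a tidy CSV with columns `value`
#'     and `group`: rank-sum for two groups, Kruskal-Wallis plus BH
#'     post hocs for more.}
#' }
#'
#' @param command Subcommand name (see Details).
#' @param config An [assay_config()].
#' @param input Input path or table, per subcommand.
#' @param out_dir Output directory (created if needed).
#' @param genotype_params Named list of [behavior_params()] for
#'   `simulate-tracks`.
#' @param n_per_group Cohort size per genotype for `simulate-tracks`.
#' @param duration Recording length (s) for simulation; default the
#'   schedule span.
#' @param calcium_param_list Named list of [calcium_params()] for
#'   `simulate-calcium`.
#' @return Invisibly, a `run_report` list: config snapshot, tables written,
#'   comparison results, rejection log, package version, and timestamp
#'   (the timestamp lives only on this in-memory object, never in the
#'   output files).
#' @export
run_assay <- function(command, config = assay_config(), input = NULL,
                      out_dir = ".", genotype_params = NULL,
                      n_per_group = NULL, duration = NULL,
                      calcium_param_list = NULL) {
  stopifnot(inherits(config, "assay_config"))
  commands <- c("simulate-tracks", "simulate-calcium", "openfield",
                "lightpref", "vmr", "calcium", "compare")
  if (!command %in% commands) {
    stop("unknown command '", command, "'; expected one of: ",
         paste(commands, collapse = ", "))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(command = command, config = config,
                 version = as.character(utils::packageVersion("larvatrax")),
                 timestamp = Sys.time(), tables = character(0),
                 comparisons = list(), log = character(0))

  emit <- function(tab, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(tab, path, row.names = FALSE)
    report$tables <<- c(report$tables, name)
    path
  }
  note <- function(...) report$log <<- c(report$log, sprintf(...))
  add_cmp <- function(label, cmp) {
    report$comparisons[[label]] <<- cmp
  }

  arena <- config_arena(config)

  if (command == "simulate-tracks") {
    if (is.null(genotype_params) || is.null(n_per_group)) {
      stop("simulate-tracks needs genotype_params and n_per_group")
    }
    trajs <- simulate_cohort(genotype_params, n_per_group, arena,
                             config$schedule,
                             sample_rate = config$sample_rate,
                             duration = duration,
                             master_seed = config$master_seed)
    write_tracks(trajs, file.path(out_dir, "tracks.csv"))
    report$tables <- c(report$tables, "tracks.csv")
    note("simulated %d trajectories", length(trajs))
  } else if (command == "simulate-calcium") {
    if (is.null(calcium_param_list)) {
      stop("simulate-calcium needs calcium_param_list")
    }
    for (lbl in names(calcium_param_list)) {
      sim <- simulate_calcium_traces(calcium_param_list[[lbl]])
      write_traces(sim$traces, sim$time,
                   file.path(out_dir, sprintf("traces_%s.csv", lbl)))
      report$tables <- c(report$tables, sprintf("traces_%s.csv", lbl))
    }
  } else if (command %in% c("openfield", "lightpref", "vmr")) {
    trajs <- if (is.character(input)) read_tracks(input, arena) else input
    flt <- activity_filter(trajs, config$activity_min_distance)
    for (i in which(!flt$log$kept)) {
      note("rejected %s: %s", flt$log$subject_id[i], flt$log$reason[i])
    }
    emit(flt$log, "activity_filter.csv")
    report$rejected <- flt$log[!flt$log$kept, , drop = FALSE]
    trajs <- flt$kept
    if (!length(trajs)) stop("no subjects survive the activity filter")
    switch(command,
      openfield = assay_openfield(trajs, arena, config, emit, add_cmp, note),
      lightpref = assay_lightpref(trajs, arena, config, emit, add_cmp, note),
      vmr = assay_vmr(trajs, arena, config, emit, add_cmp, note))
  } else if (command == "calcium") {
    assay_calcium(input, config, emit, add_cmp, note)
  } else if (command == "compare") {
    tab <- if (is.character(input)) utils::read.csv(input) else input
    stopifnot(all(c("value", "group") %in% names(tab)))
    groups <- split(tab$value, tab$group)
    if (length(groups) == 2) {
      add_cmp("rank_sum", rank_sum(groups[[1]], groups[[2]]))
    } else {
      add_cmp("kruskal_wallis", kruskal_wallis(groups))
      ph <- posthoc_pairwise(groups)
      for (r in ph) add_cmp(r$test_name, r)
    }
    emit(comparisons_table(report$comparisons), "comparisons.csv")
  }

  if (length(report$comparisons) && command != "compare") {
    emit(comparisons_table(report$comparisons), "comparisons.csv")
  }
  write_report_text(report, file.path(out_dir, "report.txt"))
  invisible(structure(report, class = "run_report"))
}

assay_openfield <- function(trajs, arena, config, emit, add_cmp, note) {
  rec_len <- trajs[[1]]$time[nrow(trajs[[1]])]
  bins <- list(c(0, rec_len / 2), c(rec_len / 2, rec_len))
  met <- do.call(rbind, lapply(trajs, bin_metrics, arena = arena,
                               bins = bins, partition = "border_center",
                               move_threshold = config$move_threshold,
                               fast_threshold = config$fast_threshold))
  emit(met, "openfield_metrics.csv")
  idx <- do.call(rbind, lapply(trajs, function(tr) {
    occ <- zone_occupancy(tr, arena, partition = "border_center",
                          move_threshold = config$move_threshold)
    data.frame(subject_id = attr(tr, "subject_id"),
               genotype = attr(tr, "genotype"),
               thigmotaxis_index = thigmotaxis_index(occ),
               border_time = occupancy_time(occ, "border"),
               center_time = occupancy_time(occ, "center"),
               total_distance = total_distance(tr))
  }))
  emit(idx, "thigmotaxis.csv")
  for (g in unique(idx$genotype)) {
    d <- idx[idx$genotype == g, ]
    if (nrow(d) >= 2 && stats::sd(d$border_time - d$center_time) > 0) {
      add_cmp(sprintf("border_vs_center_time_%s", g),
              paired_t(d$border_time, d$center_time))
    } else note("skipped paired t for %s (degenerate or n < 2)", g)
  }
  gts <- unique(idx$genotype)
  if (length(gts) == 2) {
    for (v in c("thigmotaxis_index", "total_distance")) {
      add_cmp(sprintf("%s_%s_vs_%s", v, gts[1], gts[2]),
              rank_sum(idx[[v]][idx$genotype == gts[1]],
                       idx[[v]][idx$genotype == gts[2]]))
    }
  }
  invisible(NULL)
}

assay_lightpref <- function(trajs, arena, config, emit, add_cmp, note) {
  idx <- do.call(rbind, lapply(trajs, function(tr) {
    occ <- zone_occupancy(tr, arena, partition = "light_dark",
                          move_threshold = config$move_threshold)
    data.frame(subject_id = attr(tr, "subject_id"),
               genotype = attr(tr, "genotype"),
               phototaxis_index = phototaxis_index(occ),
               light_time = occupancy_time(occ, "light"),
               dark_time = occupancy_time(occ, "dark"))
  }))
  idx$response <- classify_light_preference(idx$phototaxis_index)
  emit(idx, "phototaxis.csv")
  counts <- table(idx$genotype, idx$response)
  dist_tab <- as.data.frame.matrix(counts)
  dist_tab <- cbind(genotype = rownames(dist_tab), dist_tab)
  emit(dist_tab, "response_distribution.csv")
  if (nrow(counts) >= 2) {
    m <- as.matrix(unclass(counts))
    m <- m[, colSums(m) > 0, drop = FALSE]
    if (ncol(m) >= 2) {
      add_cmp("response_distribution_chi2", pearson_chi2(m))
    } else note("chi-square skipped: fewer than 2 response classes observed")
  }
  for (g in unique(idx$genotype)) {
    d <- idx[idx$genotype == g, ]
    if (nrow(d) >= 2 && stats::sd(d$light_time - d$dark_time) > 0) {
      add_cmp(sprintf("light_vs_dark_time_%s", g),
              paired_t(d$light_time, d$dark_time))
    }
  }
  invisible(NULL)
}

assay_vmr <- function(trajs, arena, config, emit, add_cmp, note) {
  pm <- do.call(rbind, lapply(trajs, phase_metrics,
                              schedule = config$schedule))
  emit(pm, "phase_metrics.csv")
  st <- do.call(rbind, lapply(trajs, function(tr) {
    s <- startle_response(tr, config$schedule, config$startle_window)
    if (!nrow(s)) return(NULL)
    cbind(subject_id = attr(tr, "subject_id"),
          genotype = attr(tr, "genotype"), s)
  }))
  if (!is.null(st)) emit(st, "startle.csv")
  ep <- do.call(rbind, lapply(trajs, function(tr) {
    e <- detect_seizure_episodes(tr, config$seizure_window,
                                 config$seizure_distance)
    data.frame(subject_id = attr(tr, "subject_id"),
               genotype = attr(tr, "genotype"),
               treatment = attr(tr, "treatment"),
               n_episodes = nrow(e),
               mean_amplitude = if (nrow(e)) mean(e$window_distance)
                                else NA_real_)
  }))
  emit(ep, "seizure_episodes.csv")
  gts <- unique(pm$genotype)
  if (length(gts) == 2) {
    for (ph in unique(pm$phase)) {
      x <- pm$total_distance[pm$phase == ph & pm$genotype == gts[1]]
      y <- pm$total_distance[pm$phase == ph & pm$genotype == gts[2]]
      add_cmp(sprintf("distance_%s_%s_vs_%s", ph, gts[1], gts[2]),
              rank_sum(x, y))
    }
    add_cmp(sprintf("episodes_%s_vs_%s", gts[1], gts[2]),
            rank_sum(ep$n_episodes[ep$genotype == gts[1]],
                     ep$n_episodes[ep$genotype == gts[2]]))
  }
  invisible(NULL)
}

assay_calcium <- function(input, config, emit, add_cmp, note) {
  stopifnot(is.data.frame(input),
            all(c("path", "animal_id", "genotype") %in% names(input)))
  stats_list <- list(); animals <- character(0); gts <- character(0)
  for (i in seq_len(nrow(input))) {
    traces <- read_traces(input$path[i])
    for (tr in traces) {
      pk <- detect_peaks_slope(tr, config$smooth_window,
                               min_rise = "auto_mad", k = config$min_rise_k)
      stats_list[[length(stats_list) + 1L]] <- oscillation_stats(tr, pk)
      animals <- c(animals, input$animal_id[i])
      gts <- c(gts, input$genotype[i])
    }
  }
  tab <- group_oscillations(stats_list, animals, gts)
  emit(tab, "oscillations.csv")
  g <- unique(tab$genotype)
  if (length(g) == 2) {
    add_cmp(sprintf("frequency_%s_vs_%s", g[1], g[2]),
            rank_sum(tab$frequency[tab$genotype == g[1]],
                     tab$frequency[tab$genotype == g[2]]))
    amp <- tab[!is.na(tab$mean_amplitude), ]
    if (all(table(amp$genotype) >= 1) && length(unique(amp$genotype)) == 2) {
      add_cmp(sprintf("amplitude_%s_vs_%s", g[1], g[2]),
              rank_sum(amp$mean_amplitude[amp$genotype == g[1]],
                       amp$mean_amplitude[amp$genotype == g[2]]))
    }
  }
  invisible(NULL)
}

comparisons_table <- function(cmps) {
  do.call(rbind, lapply(names(cmps), function(nm) {
    r <- cmps[[nm]]
    data.frame(comparison = nm, test = r$test_name, statistic = r$statistic,
               df = r$df, p_value = r$p_value, p_adjusted = r$p_adjusted,
               n = paste(r$n, collapse = "/"))
  }))
}

write_report_text <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("larvatrax run report")
  w("command: %s", report$command)
  w("package version: %s", report$version)
  w("")
  w("config:")
  cfg <- report$config
  for (f in setdiff(names(cfg), "schedule")) {
    w("  %s: %s", f, paste(format(cfg[[f]]), collapse = " "))
  }
  w("  schedule:")
  for (i in seq_len(nrow(cfg$schedule))) {
    w("    %s: [%g, %g) s at %g%% light", cfg$schedule$name[i],
      cfg$schedule$start[i], cfg$schedule$end[i],
      cfg$schedule$light_intensity[i])
  }
  w("")
  if (length(report$log)) {
    w("log:")
    for (l in report$log) w("  %s", l)
    w("")
  }
  if (length(report$comparisons)) {
    w("comparisons:")
    for (nm in names(report$comparisons)) {
      r <- report$comparisons[[nm]]
      w("  %s [%s]: statistic = %.6g, p = %.6g%s", nm, r$test_name,
        r$statistic, r$p_value,
        if (is.finite(r$p_adjusted))
          sprintf(", adj. p = %.6g", r$p_adjusted) else "")
    }
    w("")
  }
  w("tables written: %s", paste(report$tables, collapse = ", "))
}
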