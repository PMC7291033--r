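#' Per-cell calcium trace
#'
#' @param values Fluorescence values (AU), finite, length >= 10.
#' @param cell_id Identifier.
#' @param sample_rate Frames per second (default 1).
#' @return An object of class `calcium_trace`.
#' @export
calcium_trace <- function(values, cell_id = "cell_01", sample_rate = 1) {
  stopifnot(is.numeric(values), length(values) >= 10, all(is.finite(values)))
  structure(list(cell_id = as.character(cell_id), values = as.numeric(values),
                 sample_rate = sample_rate),
            class = "calcium_trace")
}

#' @export
print.calcium_trace <- function(x, ...) {
  cat(sprintf("<calcium_trace> %s: %d frames at %.3g Hz\n",
              x$cell_id, length(x$values), x$sample_rate))
  invisible(x)
}

#' Detrend a fluorescence trace
#'
#' @param trace A [calcium_trace()].
#' @param method `"none"` (identity), `"linear"` (subtract the
#'   least-squares line) or `"percentile_baseline"` (subtract a running
#'   10th-percentile baseline).
#' @param window Running-baseline window in samples (percentile method).
#' @param percentile Baseline percentile (default 0.10).
#' @return A [calcium_trace()] with detrended values.
#' @export
detrend_trace <- function(trace,
                          method = c("none", "linear", "percentile_baseline"),
                          window = 61, percentile = 0.10) {
  method <- match.arg(method)
  stopifnot(inherits(trace, "calcium_trace"))
  v <- trace$values
  if (method == "linear") {
    i <- seq_along(v)
    v <- as.numeric(stats::residuals(stats::lm(v ~ i)))
  } else if (method == "percentile_baseline") {
    half <- floor(window / 2)
    n <- length(v)
    base <- vapply(seq_len(n), function(i) {
      lo <- max(1L, i - half); hi <- min(n, i + half)
      stats::quantile(v[lo:hi], percentile, names = FALSE)
    }, numeric(1))
    v <- v - base
  }
  out <- trace
  out$values <- v
  out
}

# Centered moving average; the window shrinks symmetrically at the edges so
# the smoothed trace has the same length as the input.
moving_average <- function(v, window) {
  if (window <= 1L) return(v)
  half <- (window - 1L) %/% 2L
  n <- length(v)
  cs <- cumsum(c(0, v))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Slope-change peak detection
#'
#' Smooths the trace with a centered moving average, takes the discrete
#' first difference, and marks a candidate peak at every positive-to-
#' negative sign change of the difference (a change in slope).  A candidate
#' is accepted iff the rise from the minimum of the smoothed trace since
#' the previously accepted peak (the preceding trough) is at least
#' `min_rise`; with `min_rise = "auto_mad"` the threshold is `k` times the
#' median absolute deviation of the first-differenced raw trace.
#'
#' @param trace A [calcium_trace()].
#' @param smooth_window Moving-average window in samples; odd, >= 1,
#'   default 3 (at 1 Hz a wider window flattens transients whose decay is
#'   only a few samples long).
#' @param min_rise Minimum trough-to-peak rise (AU), or `"auto_mad"`.
#' @param k Multiplier for the `auto_mad` threshold (default 1.5).
#' @return Integer vector of accepted peak sample indices (1-based), with
#'   attributes `troughs` (index of the preceding trough per peak) and
#'   `smoothed` (the smoothed trace) used by [oscillation_stats()].
#' @export
detect_peaks_slope <- function(trace, smooth_window = 3,
                               min_rise = "auto_mad", k = 1.5) {
  stopifnot(inherits(trace, "calcium_trace"))
  v <- trace$values
  n <- length(v)
  if (smooth_window >= n) stop("smooth_window must be shorter than the trace")
  if (smooth_window < 1 || smooth_window %% 2 == 0) {
    stop("smooth_window must be odd and >= 1")
  }
  if (identical(min_rise, "auto_mad")) {
    min_rise <- k * stats::mad(diff(v))
  }
  s <- moving_average(v, smooth_window)
  d <- diff(s)
  sign_d <- sign(d)
  # carry the previous nonzero sign through plateaus
  for (i in seq_along(sign_d)[-1]) {
    if (sign_d[i] == 0) sign_d[i] <- sign_d[i - 1]
  }
  cand <- which(sign_d[-length(sign_d)] > 0 & sign_d[-1] < 0) + 1L
  peaks <- integer(0)
  troughs <- integer(0)
  search_from <- 1L
  for (p in cand) {
    seg <- search_from:p
    tr <- seg[which.min(s[seg])]
    if (s[p] - s[tr] >= min_rise) {
      peaks <- c(peaks, p)
      troughs <- c(troughs, tr)
      search_from <- p
    }
  }
  structure(peaks, troughs = troughs, smoothed = s, min_rise = min_rise)
}

#' Oscillation frequency and amplitude statistics
#'
#' Frequency is the peak count divided by the recording duration (Hz).
#' Each peak's amplitude is the smoothed value at the peak minus the
#' smoothed value at the preceding trough (for the first peak, the minimum
#' of the smoothed trace before it); `mean_amplitude` averages over peaks
#' and is `NA` when no peak was detected.
#'
#' @param trace A [calcium_trace()].
#' @param peaks Result of [detect_peaks_slope()] on this trace.
#' @return One-row data frame: `cell_id`, `n_peaks`, `frequency` (Hz),
#'   `mean_amplitude` (AU), and `peak_times` (list column, s).
#' @export
oscillation_stats <- function(trace, peaks) {
  stopifnot(inherits(trace, "calcium_trace"))
  duration <- length(trace$values) / trace$sample_rate
  n_peaks <- length(peaks)
  s <- attr(peaks, "smoothed")
  tr <- attr(peaks, "troughs")
  if (is.null(s)) s <- moving_average(trace$values, 3)
  amp <- if (n_peaks == 0) NA_real_ else {
    if (is.null(tr)) {
      tr <- vapply(seq_len(n_peaks), function(i) {
        from <- if (i == 1) 1L else peaks[i - 1L]
        seg <- from:peaks[i]
        seg[which.min(s[seg])]
      }, integer(1))
    }
    mean(s[peaks] - s[tr])
  }
  out <- data.frame(cell_id = trace$cell_id, n_peaks = n_peaks,
                    frequency = n_peaks / duration, mean_amplitude = amp)
  out$peak_times <- list((peaks - 1) / trace$sample_rate)
  out
}

#' Long-format oscillation table for group comparison
#'
#' Binds per-cell oscillation statistics with animal and genotype labels
#' into the tidy table the statistical harness consumes.  Comparisons at
#' the cell level treat cells as replicates (pseudo-replication across
#' cells of one animal is a known caveat); per-animal aggregation averages
#' cells within each animal first.
#'
#' @param stats_list List of one-row data frames from [oscillation_stats()].
#' @param animal_ids Character vector, one animal id per cell.
#' @param genotypes Character vector, one genotype per cell.
#' @param aggregate_by_animal If `TRUE`, return one row per animal with
#'   cell-averaged frequency and amplitude.
#' @return Data frame with columns `cell_id`, `animal_id`, `genotype`,
#'   `frequency`, `mean_amplitude` (or per-animal means).
#' @export
group_oscillations <- function(stats_list, animal_ids, genotypes,
                               aggregate_by_animal = FALSE) {
  n <- length(stats_list)
  if (length(animal_ids) != n || length(genotypes) != n) {
    stop("every cell must carry an animal id and a genotype label")
  }
  if (any(is.na(animal_ids)) || any(is.na(genotypes))) {
    stop("unlabeled cells: animal id or genotype missing")
  }
  tab <- do.call(rbind, lapply(seq_len(n), function(i) {
    s <- stats_list[[i]]
    data.frame(cell_id = s$cell_id, animal_id = animal_ids[i],
               genotype = genotypes[i], frequency = s$frequency,
               mean_amplitude = s$mean_amplitude)
  }))
  if (!aggregate_by_animal) return(tab)
  agg <- stats::aggregate(cbind(frequency, mean_amplitude) ~ animal_id +
                            genotype, data = tab, FUN = mean,
                          na.action = stats::na.omit)
  agg[order(agg$genotype, agg$animal_id), , drop = FALSE]
}

#' Analyze a set of traces end to end
#'
#' Convenience wrapper: optional detrending, slope peak detection, and
#' oscillation statistics per trace.
#'
#' @param traces List of [calcium_trace()] objects or a frames x cells
#'   matrix (1 Hz assumed for a bare matrix).
#' @param detrend Detrending method, see [detrend_trace()].
#' @param smooth_window,min_rise,k See [detect_peaks_slope()].
#' @param sample_rate Used when `traces` is a matrix.
#' @return Data frame, one row per cell.
#' @export
analyze_traces <- function(traces, detrend = "none", smooth_window = 3,
                           min_rise = "auto_mad", k = 1.5, sample_rate = 1) {
  if (is.matrix(traces)) {
    ids <- colnames(traces)
    if (is.null(ids)) ids <- sprintf("cell_%02d", seq_len(ncol(traces)))
    traces <- lapply(seq_len(ncol(traces)), function(j)
      calcium_trace(traces[, j], cell_id = ids[j], sample_rate = sample_rate))
  }
  do.call(rbind, lapply(traces, function(tr) {
    tr <- detrend_trace(tr, detrend)
    pk <- detect_peaks_slope(tr, smooth_window, min_rise, k)
    oscillation_stats(tr, pk)
  }))
}
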