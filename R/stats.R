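#' @title Statistical comparison harness
#' @description Wrappers around the classical tests the assays report,
#'   returning a uniform `comparison_result` record: test name, statistic,
#'   df, two-sided p, optional BH-adjusted p, and group summaries
#'   (medians with quartiles for rank tests, means with SD for t-tests).
#' @name stats_compare
NULL

comparison_result <- function(test_name, statistic, df = NA_real_, p_value,
                              p_adjusted = NA_real_, group_summaries = NULL,
                              n = NULL) {
  structure(list(test_name = test_name, statistic = unname(statistic),
                 df = unname(df), p_value = unname(p_value),
                 p_adjusted = p_adjusted,
                 group_summaries = group_summaries, n = n),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.6g%s, p = %.4g%s\n", x$test_name,
              x$statistic,
              if (is.finite(x$df)) sprintf(", df = %.6g", x$df) else "",
              x$p_value,
              if (is.finite(x$p_adjusted))
                sprintf(", adj. p = %.4g", x$p_adjusted) else ""))
  invisible(x)
}

rank_summary <- function(v) {
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
  c(q1 = q[1], median = q[2], q3 = q[3])
}

#' Paired t-test
#'
#' Classical paired t statistic on matched observations (e.g. border versus
#' center time within the same larva), df = n - 1, two-sided p.
#'
#' @param x,y Paired numeric vectors of equal length >= 2.
#' @return A `comparison_result`.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  if (stats::sd(d) == 0) {
    stop("degenerate data: paired differences have zero variance")
  }
  ht <- stats::t.test(x, y, paired = TRUE)
  comparison_result("paired_t", ht$statistic, ht$parameter, ht$p.value,
                    group_summaries = list(
                      x = c(mean = mean(x), sd = stats::sd(x)),
                      y = c(mean = mean(y), sd = stats::sd(y))),
                    n = length(x))
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided Mann-Whitney U.  The exact null distribution is used when
#' `n1 + n2 <= exact_limit` and there are no ties; otherwise the normal
#' approximation with tie correction (no continuity correction).
#'
#' @param x,y Numeric samples, both non-empty.
#' @param exact_limit Largest combined sample size for the exact p
#'   (default 12).
#' @return A `comparison_result` with the U statistic for `x`.
#' @export
rank_sum <- function(x, y, exact_limit = 12) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y)) <= exact_limit && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = FALSE))
  comparison_result(
    if (exact) "rank_sum_exact" else "rank_sum_normal",
    ht$statistic, p_value = ht$p.value,
    group_summaries = list(x = rank_summary(x), y = rank_summary(y)),
    n = c(length(x), length(y)))
}

#' Kruskal-Wallis test
#'
#' Rank-based k-group test with tie correction; chi-square p with
#' df = k - 1.
#'
#' @param groups List of numeric vectors (>= 2 groups, each non-empty).
#' @return A `comparison_result`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2,
            all(lengths(groups) >= 1))
  v <- unlist(groups)
  if (length(unique(v)) == 1L) {
    stop("degenerate data: all values identical across groups")
  }
  g <- factor(rep(seq_along(groups), lengths(groups)))
  ht <- stats::kruskal.test(v, g)
  comparison_result("kruskal_wallis", ht$statistic, ht$parameter, ht$p.value,
                    group_summaries = lapply(groups, rank_summary),
                    n = lengths(groups))
}

#' Pairwise rank-sum post hocs with BH correction
#'
#' All pairwise Mann-Whitney comparisons among >= 3 groups, with
#' Benjamini-Hochberg adjustment across the pairs.
#'
#' @param groups Named list of numeric vectors (>= 3 groups).
#' @return List of `comparison_result`s, one per pair, `p_adjusted` filled.
#' @export
posthoc_pairwise <- function(groups) {
  stopifnot(is.list(groups))
  if (length(groups) < 3) {
    stop("post hoc requires >= 3 groups; use rank_sum() for two")
  }
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  pairs <- utils::combn(names(groups), 2, simplify = FALSE)
  res <- lapply(pairs, function(pr) {
    r <- rank_sum(groups[[pr[1]]], groups[[pr[2]]])
    r$test_name <- sprintf("%s: %s vs %s", r$test_name, pr[1], pr[2])
    r
  })
  adj <- bh_adjust(vapply(res, function(r) r$p_value, numeric(1)))
  for (i in seq_along(res)) res[[i]]$p_adjusted <- adj[i]
  res
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement; order-preserving.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Pearson's chi-square test on a contingency table
#'
#' `sum((O - E)^2 / E)` with expected counts from the margins, df =
#' `(r - 1)(c - 1)`, upper-tail p.  No continuity correction by default
#' (matching how the light-preference response distribution is compared).
#'
#' @param table Matrix of non-negative integer counts, at least 2 x 2,
#'   with positive row and column totals.
#' @param correct Apply the Yates continuity correction (2 x 2 only).
#' @return A `comparison_result`.
#' @export
pearson_chi2 <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (nrow(table) < 2 || ncol(table) < 2) stop("need at least a 2x2 table")
  if (any(table < 0) || any(abs(table - round(table)) > 1e-9)) {
    stop("counts must be non-negative integers")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("degenerate table: a row or column margin is zero")
  }
  ht <- suppressWarnings(stats::chisq.test(table, correct = correct))
  comparison_result("pearson_chi2", ht$statistic, ht$parameter, ht$p.value,
                    n = sum(table))
}

#' Delta-delta-Ct relative fold change
#'
#' `fold = 2^-((Ct_target,sample - Ct_ref,sample) -
#' (Ct_target,control - Ct_ref,control))`, the standard relative qPCR
#' quantification against a reference gene and a control condition.
#' Vectors of replicate Ct values give per-replicate fold changes with the
#' mean and SD propagated.
#'
#' @param ct_target_sample,ct_ref_sample Ct values in the sample condition
#'   (target and reference gene), replicate-wise.
#' @param ct_target_control,ct_ref_control Ct values in the control
#'   condition; replicate means are used for the control delta.
#' @return List with `fold_changes` (per sample replicate), `mean_fold`,
#'   `sd_fold`, and `ddct` per replicate.
#' @export
ddct_fold_change <- function(ct_target_sample, ct_ref_sample,
                             ct_target_control, ct_ref_control) {
  stopifnot(all(is.finite(c(ct_target_sample, ct_ref_sample,
                            ct_target_control, ct_ref_control))))
  d_sample <- ct_target_sample - ct_ref_sample
  d_control <- mean(ct_target_control) - mean(ct_ref_control)
  ddct <- d_sample - d_control
  fc <- 2^(-ddct)
  list(fold_changes = fc, mean_fold = mean(fc),
       sd_fold = if (length(fc) > 1) stats::sd(fc) else NA_real_,
       ddct = ddct)
}

#' Per-gene two-sample t-tests on an expression table
#'
#' Equal-variance Student's t per gene on normalized expression values
#' (e.g. FPKM) between two groups, fold change as the ratio of group means,
#' and BH adjustment across genes (a false-discovery-rate column).  Genes
#' with zero variance in both groups get `NA` p-values and are flagged, and
#' are excluded from the BH family.
#'
#' @param expr Genes x samples numeric matrix with gene row names.
#' @param groups Character/factor vector of length `ncol(expr)` with
#'   exactly two levels; the first level is the reference (denominator of
#'   the fold change).
#' @param var_equal Use the pooled-variance Student's t (default `TRUE`);
#'   `FALSE` gives Welch.
#' @return Data frame, one row per gene: `gene`, group means, `fold_change`,
#'   `t`, `df`, `p_value`, `fdr`, `flagged`.
#' @export
de_group_test <- function(expr, groups, var_equal = TRUE) {
  expr <- as.matrix(expr)
  groups <- factor(groups)
  stopifnot(nlevels(groups) == 2, length(groups) == ncol(expr),
            all(table(groups) >= 2))
  if (any(expr < 0)) stop("expression values must be >= 0")
  ref <- levels(groups)[1]; alt <- levels(groups)[2]
  a <- expr[, groups == ref, drop = FALSE]
  b <- expr[, groups == alt, drop = FALSE]
  res <- lapply(seq_len(nrow(expr)), function(i) {
    xa <- a[i, ]; xb <- b[i, ]
    degen <- stats::sd(xa) == 0 && stats::sd(xb) == 0
    if (degen) {
      data.frame(t = NA_real_, df = NA_real_, p_value = NA_real_)
    } else {
      ht <- stats::t.test(xb, xa, var.equal = var_equal)
      data.frame(t = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value)
    }
  })
  res <- do.call(rbind, res)
  mean_ref <- rowMeans(a); mean_alt <- rowMeans(b)
  out <- data.frame(
    gene = if (is.null(rownames(expr))) sprintf("gene_%d", seq_len(nrow(expr)))
           else rownames(expr),
    mean_ref = mean_ref, mean_alt = mean_alt,
    fold_change = ifelse(mean_ref > 0, mean_alt / mean_ref, NA_real_),
    t = res$t, df = res$df, p_value = res$p_value,
    fdr = NA_real_, flagged = is.na(res$p_value),
    row.names = NULL)
  ok <- !out$flagged
  if (any(ok)) out$fdr[ok] <- bh_adjust(out$p_value[ok])
  out
}
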