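test_that("paired t matches the closed form on hand-computable triples", {
  # differences (1, 2, 3): t = mean/(sd/sqrt(n)) = 2/(1/sqrt(3)) = 2*sqrt(3)
  r <- paired_t(c(2, 4, 6), c(1, 2, 3))
  expect_equal(r$statistic, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(r$df, 2)
  expect_equal(r$p_value, 2 * stats::pt(-2 * sqrt(3), df = 2),
               tolerance = 1e-12)

  set.seed(3)
  for (i in 1:20) {
    x <- rnorm(sample(3:8, 1)); y <- rnorm(length(x))
    r <- paired_t(x, y)
    d <- x - y
    expect_equal(r$statistic, mean(d) / (stats::sd(d) / sqrt(length(d))),
                 tolerance = 1e-12)
  }

  expect_error(paired_t(1:5, 1:5 + 2), "zero variance")
  expect_error(paired_t(1:5, 1:5), "zero variance")
})

test_that("rank-sum exact p equals full enumeration for all small tie-free inputs", {
  r <- rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p_value, 0.1)
  expect_equal(rank_sum(5, 9)$p_value, 1)

  # exhaustive: every rank assignment for n1 + n2 <= 8, tie-free
  for (n in 4:8) {
    for (n1 in 1:(n - 1)) {
      combos <- utils::combn(n, n1)
      for (j in seq_len(ncol(combos))) {
        xr <- combos[, j]
        yr <- setdiff(seq_len(n), xr)
        expect_equal(rank_sum(xr, yr)$p_value,
                     oracle_ranksum_exact(xr, yr), tolerance = 1e-12)
      }
    }
  }
})

test_that("rank-sum falls back to a tie-corrected normal approximation", {
  x <- c(1, 1, 2, 3, 3, 4, 8); y <- c(2, 2, 3, 5, 6, 7, 7)
  r <- rank_sum(x, y)
  expect_equal(r$test_name, "rank_sum_normal")
  expect_true(r$p_value > 0 && r$p_value < 1)
  # near-identical samples give a central p
  set.seed(1)
  z <- rnorm(10)
  expect_gt(rank_sum(z, z)$p_value, 0.95)
})

test_that("Kruskal-Wallis reproduces the hand-computed H and degenerates", {
  # groups (1,2),(3,4),(5,6): rank sums 3, 7, 11
  # H = 12/(6*7) * (9/2 + 49/2 + 121/2) - 3*7 = 2/7*179/2... = 4.571428...
  r <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(r$statistic, 12 / 42 * (9 / 2 + 49 / 2 + 121 / 2) - 21,
               tolerance = 1e-12)
  expect_equal(r$df, 2)

  # two tie-free groups: H equals the squared rank-sum z statistic
  x <- c(1.2, 3.4, 5.1, 7.8); y <- c(2.2, 4.9, 9.3, 11.1, 13.0)
  h <- kruskal_wallis(list(x, y))$statistic
  w <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
  z2 <- stats::qnorm(w$p.value / 2)^2
  expect_equal(h, z2, tolerance = 1e-9)

  expect_error(kruskal_wallis(list(c(1, 1), c(1, 1))), "identical")
})

test_that("BH adjustment is the step-up procedure with its invariants", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(8)
  for (i in 1:20) {
    p <- runif(sample(2:12, 1))
    q <- bh_adjust(p)
    # order-preserving, monotone, never below the raw p
    expect_true(all(diff(q[order(p)]) >= -1e-12))
    expect_true(all(q >= p - 1e-12))
  }
  # a fully tied vector is a fixed point of the step-up
  tied <- bh_adjust(rep(0.2, 6))
  expect_equal(bh_adjust(tied), tied)
})

test_that("pairwise post hocs BH-adjust across all pairs", {
  set.seed(12)
  g <- list(a = rnorm(8), b = rnorm(8, 1), c = rnorm(8, 2))
  res <- posthoc_pairwise(g)
  expect_length(res, 3)
  raw <- vapply(res, function(r) r$p_value, numeric(1))
  adj <- vapply(res, function(r) r$p_adjusted, numeric(1))
  expect_equal(adj, bh_adjust(raw))
  expect_error(posthoc_pairwise(list(a = 1:3, b = 4:6)), ">= 3 groups")
})

test_that("Pearson chi-square follows the O/E arithmetic and invariances", {
  r <- pearson_chi2(rbind(c(10, 0), c(0, 10)))
  expect_equal(r$statistic, 20)
  expect_equal(r$df, 1)

  flat <- pearson_chi2(rbind(c(5, 5), c(5, 5)))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)

  m <- rbind(c(8, 2, 1), c(5, 1, 4))
  perm <- m[c(2, 1), c(3, 1, 2)]
  expect_equal(pearson_chi2(m)$statistic, pearson_chi2(perm)$statistic)

  # chi2 = 0 iff the rows are proportional
  prop <- rbind(c(2, 4, 6), c(3, 6, 9))
  expect_equal(pearson_chi2(prop)$statistic, 0, tolerance = 1e-12)

  expect_error(pearson_chi2(rbind(c(1, 0), c(2, 0))), "margin")
  expect_error(pearson_chi2(matrix(1:3, 1)), "2x2")
})

test_that("delta-delta-Ct fold changes follow the power rule", {
  expect_equal(ddct_fold_change(20, 18, 21, 19)$mean_fold, 1)
  expect_equal(ddct_fold_change(18, 18, 20, 18)$mean_fold, 4)   # ddCt = -2
  expect_equal(ddct_fold_change(21, 18, 20, 18)$mean_fold, 0.5) # ddCt = +1
  r <- ddct_fold_change(c(18, 19), c(18, 18), c(20, 20), c(18, 18))
  expect_equal(r$fold_changes, c(4, 2))
  expect_equal(r$mean_fold, 3)
  expect_equal(r$sd_fold, stats::sd(c(4, 2)))
})

test_that("per-gene group tests rank true shifts on top and flag degenerates", {
  set.seed(24)
  n_genes <- 100
  expr <- matrix(stats::rlnorm(n_genes * 4, meanlog = 3, sdlog = 0.1),
                 nrow = n_genes,
                 dimnames = list(sprintf("g%03d", 1:n_genes), NULL))
  shifted <- 1:5
  expr[shifted, 3:4] <- expr[shifted, 3:4] * 4
  expr[7, ] <- 5  # identical in both groups
  res <- de_group_test(expr, c("a_WT", "a_WT", "b_mut", "b_mut"))
  expect_true(res$flagged[7])
  expect_equal(res$fold_change[7], 1)
  # at n = 2 + 2 the pooled-variance estimate is unstable, so a null gene
  # can occasionally edge into the extreme ranks; the shifted genes still
  # dominate the top of the list
  expect_true(all(rank(res$p_value)[shifted] <= 10))
  expect_true(all(res$p_value[shifted] < 0.05))
  expect_equal(res$fold_change[shifted],
               unname(rowMeans(expr[shifted, 3:4]) /
                        rowMeans(expr[shifted, 1:2])))
  ok <- !res$flagged
  expect_equal(res$fdr[ok], bh_adjust(res$p_value[ok]))

  # doubling group B for one gene gives fold 2
  e2 <- matrix(c(2, 2.2, 4.2, 4.0), nrow = 1)
  r2 <- de_group_test(e2, c("a", "a", "b", "b"))
  expect_equal(r2$fold_change, (4.2 + 4.0) / (2 + 2.2))
})
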