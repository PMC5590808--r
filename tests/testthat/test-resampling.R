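# Permutation test, percentile bootstrap and Welch t: oracles, invariants
# and calibration.

test_that("exact permutation p equals brute-force enumeration on a 4-unit toy", {
  d <- data.frame(island = rep(c("Koram", "NomSao"), each = 4),
                  unit_id = rep(c("a", "b", "c", "d"), each = 2),
                  y = c(1, 2, 4, 5, 10, 11, 13, 15))
  diff_means <- function(dd)
    mean(dd$y[dd$island == "NomSao"]) - mean(dd$y[dd$island == "Koram"])

  # independent oracle: enumerate all C(4,2) = 6 assignments by hand
  unit_means <- tapply(d$y, d$unit_id, mean)
  obs <- diff_means(d)
  stats <- apply(utils::combn(4, 2), 2, function(k)
    mean(unit_means[-k]) - mean(unit_means[k]))
  p_oracle <- mean(abs(stats) >= abs(obs) - 1e-12)

  res <- permutation_island_test(d, diff_means, unit = "individual",
                                 exact = TRUE)
  expect_equal(res$n_perm, 6)
  expect_equal(res$p_value, p_oracle)
  expect_equal(res$observed_stat, obs)
})

test_that("individual-level relabeling moves whole units and keeps group sizes", {
  set.seed(2)
  d <- data.frame(island = rep(c("Koram", "NomSao"), c(6, 9)),
                  unit_id = rep(c("a", "b", "c", "d", "e"), each = 3),
                  y = rnorm(15))
  check_stat <- function(dd) {
    per_unit <- tapply(dd$island, dd$unit_id, function(x) length(unique(x)))
    stopifnot(all(per_unit == 1))  # units never split
    stopifnot(sum(tapply(dd$island, dd$unit_id, `[`, 1) == "Koram") == 2)
    mean(dd$y[dd$island == "Koram"])
  }
  res <- permutation_island_test(d, check_stat, n_perm = 50, seed = 4)
  expect_length(res$null_stats, 50)
  expect_gte(res$p_value, 1 / 51)

  expect_error(permutation_island_test(d[d$island == "Koram", ], check_stat),
               "both islands")
  calls <- 0
  bad_stat <- function(dd) {
    calls <<- calls + 1
    if (calls > 1) stop("boom")  # observed stat fine, relabelings fail
    0
  }
  expect_error(permutation_island_test(d, bad_stat, n_perm = 5, seed = 1),
               "relabeling 1.*boom")
})

test_that("permutation p-values are uniform under the null", {
  set.seed(42)
  pvals <- replicate(150, {
    d <- data.frame(island = rep(c("Koram", "NomSao"), each = 10),
                    y = rnorm(20))
    permutation_island_test(
      d, function(dd) mean(dd$y[dd$island == "Koram"]) -
        mean(dd$y[dd$island == "NomSao"]),
      n_perm = 299, unit = "record")$p_value
  })
  # p-values are discrete, so ties trigger a spurious ks.test warning
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif")$p.value), 0.01)
})

test_that("permutation p is invariant to identical monotone transforms for rank stats", {
  set.seed(9)
  d <- data.frame(island = rep(c("Koram", "NomSao"), each = 8),
                  y = rlnorm(16))
  rank_stat <- function(dd) sum(rank(dd$y)[dd$island == "NomSao"])
  p1 <- permutation_island_test(d, rank_stat, n_perm = 200, seed = 3,
                                unit = "record")$p_value
  d$y <- log(d$y)  # monotone transform leaves ranks unchanged
  p2 <- permutation_island_test(d, rank_stat, n_perm = 200, seed = 3,
                                unit = "record")$p_value
  expect_equal(p1, p2)
})

test_that("bootstrap CI follows the documented resampling stream", {
  v <- c(1, 2, 3)
  ci <- bootstrap_mean_ci(v, n_boot = 200, level = 0.9, seed = 7)
  # independent re-implementation of the documented stream
  set.seed(7)
  stats <- sapply(1:200, function(b) mean(v[sample.int(3, 3, replace = TRUE)]))
  qs <- quantile(stats, c(0.05, 0.95), names = FALSE, type = 7)
  expect_equal(ci$point, 2)
  expect_equal(c(ci$lower, ci$upper), qs)
})

test_that("degenerate and empty bootstrap inputs behave as specified", {
  ci <- bootstrap_mean_ci(c(5, 5, 5, 5), n_boot = 50, seed = 1)
  expect_equal(c(ci$lower, ci$point, ci$upper), c(5, 5, 5))
  expect_error(bootstrap_mean_ci(numeric(0)), "nonempty")
})

test_that("bootstrap CI width shrinks like 1/sqrt(n)", {
  set.seed(10)
  widths <- sapply(c(25, 100, 400), function(n) {
    mean(replicate(25, {
      ci <- bootstrap_mean_ci(rnorm(n), n_boot = 300)
      ci$upper - ci$lower
    }))
  })
  expect_true(all(diff(widths) < 0))
  expect_equal(widths[1] / widths[3], 4, tolerance = 0.3)
})

test_that("bootstrap group comparison reports interval overlap symmetrically", {
  cmp <- bootstrap_group_compare(c(0, 0, 0), c(9, 9, 9), n_boot = 50, seed = 2)
  expect_false(cmp$overlap)
  same <- bootstrap_group_compare(1:5, 1:5, n_boot = 50, seed = 2)
  expect_true(same$overlap)

  set.seed(31)
  a <- rnorm(40); b <- rnorm(40, 0.5)
  ab <- bootstrap_group_compare(a, b, n_boot = 200, seed = 5)
  ba <- bootstrap_group_compare(b, a, n_boot = 200, seed = 5)
  expect_equal(ab$overlap, ba$overlap)
})

test_that("groups separated by 3 SDs give non-overlapping CIs", {
  set.seed(12)
  sep <- replicate(50, {
    bootstrap_group_compare(rnorm(100), rnorm(100, 3), n_boot = 200)$overlap
  })
  expect_lte(mean(sep), 0.01)
})

test_that("welch_t_test matches the closed-form Welch formulas", {
  welch_oracle <- function(a, b) {
    va <- var(a) / length(a); vb <- var(b) / length(b)
    t <- (mean(a) - mean(b)) / sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
    list(t = t, df = df, p = 2 * pt(-abs(t), df))
  }
  a <- c(1, 2, 3, 4); b <- c(2, 3, 4, 5)
  res <- welch_t_test(a, b)
  ora <- welch_oracle(a, b)
  expect_equal(res$statistic, ora$t, tolerance = 1e-12)
  expect_equal(res$df, ora$df, tolerance = 1e-12)
  expect_equal(res$p_value, ora$p, tolerance = 1e-12)

  set.seed(4)
  for (i in 1:10) {
    a <- rnorm(sample(5:40, 1)); b <- rnorm(sample(5:40, 1), sd = runif(1, 0.5, 2))
    res <- welch_t_test(a, b); ora <- welch_oracle(a, b)
    expect_equal(res$statistic, ora$t, tolerance = 1e-10)
    expect_equal(res$df, ora$df, tolerance = 1e-10)
  }

  x <- rnorm(10)
  same <- welch_t_test(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(welch_t_test(c(1, 1, 1), c(2, 2, 2)), "degenerate")
  expect_error(welch_t_test(1, 1:3), "at least 2")
})
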