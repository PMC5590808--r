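# Resampling inference: cluster-level island permutation test, percentile
# bootstrap CIs, and the two-sample t-test wrapper used by every comparison
# battery.

#' Permutation test of an island effect
#'
#' Builds the null distribution of an arbitrary statistic by randomly
#' reassigning island labels. With `unit = "individual"` whole sampling
#' units (all records of one individual) are relabelled together, so the
#' within-individual dependence structure is preserved; island group sizes
#' in units are preserved under every relabelling. The two-sided p-value
#' uses the add-one estimator `p = (#\{|null| >= |observed|\} + 1) /
#' (n_perm + 1)`, which never returns 0 and satisfies `p >= 1/(n_perm+1)`.
#'
#' With `exact = TRUE` the null is the full enumeration of island
#' assignments to units (feasible only for small unit counts) and the
#' p-value is the exact proportion of assignments, including the observed
#' one, with `|stat|` at least as large as observed.
#'
#' @param data Data frame with an `island` column and, for
#'   `unit = "individual"`, a `unit_id` (or `user_id`) column constant
#'   within individual.
#' @param stat_fn Function `data.frame -> single number`, evaluated on the
#'   observed data and on every relabelling.
#' @param n_perm Number of Monte Carlo relabellings (default 10000).
#' @param unit `"individual"` (relabel whole individuals) or `"record"`.
#' @param seed Integer seed for the relabelling stream.
#' @param exact Enumerate all assignments instead of sampling.
#' @return A `permutation_result`: `observed_stat`, `null_stats`,
#'   `p_value`, `n_perm`, `unit`, `seed`, `exact`.
#' @export
permutation_island_test <- function(data, stat_fn, n_perm = 10000,
                                    unit = c("individual", "record"),
                                    seed = NULL, exact = FALSE) {
  unit <- match.arg(unit)
  if (!"island" %in% names(data)) stop("data must have an island column")
  island <- as.character(data$island)
  if (length(unique(island)) < 2)
    stop("permutation test needs records from both islands")

  if (unit == "individual") {
    idcol <- intersect(c("unit_id", "user_id"), names(data))[1]
    if (is.na(idcol))
      stop("unit = 'individual' requires a unit_id or user_id column")
    ids <- as.character(data[[idcol]])
    if (any(is.na(ids))) stop("missing unit ids; use unit = 'record'")
    unit_island <- tapply(island, ids, function(x) {
      u <- unique(x)
      if (length(u) > 1) stop("unit spans both islands", call. = FALSE)
      u
    })
    unit_ids <- names(unit_island)
    rec_unit <- match(ids, unit_ids)
  } else {
    unit_island <- island
    rec_unit <- seq_along(island)
  }
  n_units <- length(unit_island)
  if (min(table(unit_island)) < 1)
    stop("each island needs at least one unit")

  observed <- stat_fn(data)
  eps <- 1e-12
  relabel_stat <- function(new_unit_island, b) {
    d <- data
    d$island <- as.character(new_unit_island)[rec_unit]
    tryCatch(stat_fn(d), error = function(e)
      stop("stat_fn failed at relabeling ", b, ": ", conditionMessage(e),
           call. = FALSE))
  }

  if (exact) {
    lev <- sort(unique(as.character(unit_island)))
    n1 <- sum(unit_island == lev[1])
    sets <- utils::combn(n_units, n1, simplify = FALSE)
    null_stats <- vapply(seq_along(sets), function(b) {
      lab <- rep(lev[2], n_units)
      lab[sets[[b]]] <- lev[1]
      relabel_stat(lab, b)
    }, numeric(1))
    p <- mean(abs(null_stats) >= abs(observed) - eps)
    n_perm <- length(sets)
  } else {
    if (!is.null(seed)) set.seed(seed)
    null_stats <- vapply(seq_len(n_perm), function(b) {
      relabel_stat(sample(unit_island), b)
    }, numeric(1))
    p <- (sum(abs(null_stats) >= abs(observed) - eps) + 1) / (n_perm + 1)
  }

  structure(list(observed_stat = observed, null_stats = null_stats,
                 p_value = p, n_perm = n_perm, unit = unit, seed = seed,
                 exact = exact),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Permutation test (%s-level%s): observed = %.4g, p = %.4g (%d relabelings)\n",
              x$unit, if (x$exact) ", exact" else "", x$observed_stat,
              x$p_value, x$n_perm))
  invisible(x)
}

#' Percentile bootstrap confidence interval for a mean
#'
#' Resamples the values with replacement at the original sample size and
#' takes the percentile interval of the resampled statistic. The resampling
#' stream is defined as: `set.seed(seed)`, then `n_boot` successive calls to
#' `sample.int(n, n, replace = TRUE)`; quantiles use base type 7. Fixing the
#' seed makes the interval exactly reproducible.
#'
#' @param values Numeric vector (length >= 1).
#' @param n_boot Number of resamples (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed.
#' @param stat_fn Statistic to bootstrap (default [mean()]).
#' @return A `bootstrap_ci`: `point`, `lower`, `upper`, `level`, `n_boot`,
#'   `seed`, `n`.
#' @export
bootstrap_mean_ci <- function(values, n_boot = 1000, level = 0.95,
                              seed = NULL, stat_fn = mean) {
  values <- as.numeric(values)
  if (!length(values) || any(is.na(values)))
    stop("values must be a nonempty numeric vector without NAs")
  if (!is.null(seed)) set.seed(seed)
  n <- length(values)
  stats <- vapply(seq_len(n_boot), function(b)
    stat_fn(values[sample.int(n, n, replace = TRUE)]), numeric(1))
  qs <- stats::quantile(stats, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE, type = 7)
  structure(list(point = stat_fn(values), lower = qs[1], upper = qs[2],
                 level = level, n_boot = n_boot, seed = seed, n = n),
            class = "bootstrap_ci")
}

#' @export
print.bootstrap_ci <- function(x, ...) {
  cat(sprintf("%.4g [%g%% CI %.4g, %.4g] (n = %d, %d resamples)\n",
              x$point, 100 * x$level, x$lower, x$upper, x$n, x$n_boot))
  invisible(x)
}

#' Compare two groups by bootstrap confidence intervals
#'
#' Bootstraps each group's mean separately (group `b` uses `seed + 1` when a
#' seed is given) and reports whether the two percentile intervals overlap.
#' The overlap verdict is symmetric in the two groups.
#'
#' @inheritParams bootstrap_mean_ci
#' @param a,b Numeric vectors, both nonempty.
#' @return List with `ci_a`, `ci_b` ([bootstrap_mean_ci()] results) and
#'   logical `overlap`.
#' @export
bootstrap_group_compare <- function(a, b, n_boot = 1000, level = 0.95,
                                    seed = NULL) {
  ci_a <- bootstrap_mean_ci(a, n_boot, level, seed)
  ci_b <- bootstrap_mean_ci(b, n_boot, level,
                            if (is.null(seed)) NULL else seed + 1)
  overlap <- ci_a$lower <= ci_b$upper && ci_b$lower <= ci_a$upper
  list(ci_a = ci_a, ci_b = ci_b, overlap = overlap)
}

#' Two-sample t-test with unequal variances
#'
#' Welch's t-test (the default) or the pooled-variance Student test.
#' Delegates to [stats::t.test()]; the returned object standardises the
#' fields used throughout the comparison batteries and also carries the
#' Welch-Satterthwaite df rounded to an integer for report display.
#'
#' @param a,b Numeric vectors, each with at least 2 values; at least one
#'   group must have nonzero variance.
#' @param var_equal Use the pooled-variance test instead of Welch.
#' @return A `test_result`: `statistic`, `df`, `df_int`, `p_value`, `kind`,
#'   `n`.
#' @export
welch_t_test <- function(a, b, var_equal = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 values")
  if (stats::var(a) == 0 && stats::var(b) == 0)
    stop("degenerate variance: both groups are constant")
  tt <- stats::t.test(a, b, var.equal = var_equal)
  structure(list(statistic = unname(tt$statistic), df = unname(tt$parameter),
                 df_int = as.integer(round_half_up(unname(tt$parameter))),
                 p_value = tt$p.value,
                 kind = if (var_equal) "t_student" else "t_welch",
                 n = length(a) + length(b)),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: t(%d) = %.3f, p = %.4g (N = %d)\n", x$kind, x$df_int,
              x$statistic, x$p_value, x$n))
  invisible(x)
}
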