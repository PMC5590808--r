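# Model-fitting stages: random-intercept mixed model for oyster-tool
# weights, linear models for snail-tool weights and snail maturation, their
# likelihood-ratio tests, leave-one-out stability, and the bootstrap/t-test
# comparison batteries for prey sizes, snail availability and stone supply.

new_fit_result <- function(model, term, estimate, se, statistic, stat_kind,
                           df1, df2, p_value, transform, n, n_units = NA,
                           singular = FALSE, fallback = FALSE,
                           diagnostics = NULL) {
  structure(list(model = model, term = term, estimate = unname(estimate),
                 se = unname(se), statistic = unname(statistic),
                 stat_kind = stat_kind, df1 = df1, df2 = df2,
                 p_value = unname(p_value), transform = transform, n = n,
                 n_units = n_units, reference_level = "Koram",
                 singular = singular, fallback = fallback,
                 diagnostics = diagnostics),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  stat <- if (x$stat_kind == "chisq")
    sprintf("chi^2 = %.3f, df = %d", x$statistic, x$df1)
  else
    sprintf("F(%d,%d) = %.3f", x$df1, x$df2, x$statistic)
  cat(sprintf("%s [%s scale, N = %d]: E = %.3f, SE = %.3f, %s, p = %.4g\n",
              x$model, x$transform, x$n, x$estimate, x$se, stat, x$p_value))
  if (x$singular) cat("  note: singular random-effect fit; LM fallback used\n")
  invisible(x)
}

residual_diagnostics <- function(fitted, resid) {
  shapiro_p <- if (length(resid) >= 3 && length(resid) <= 5000 &&
                   stats::sd(resid) > 0)
    stats::shapiro.test(resid)$p.value else NA_real_
  # Breusch-Pagan-style auxiliary regression of squared residuals on fitted
  bp_p <- if (stats::sd(fitted) > 0 && stats::sd(resid) > 0) {
    aux <- stats::lm(I(resid^2) ~ fitted)
    f <- summary(aux)$fstatistic
    if (is.null(f)) NA_real_ else
      unname(stats::pf(f[1], f[2], f[3], lower.tail = FALSE))
  } else NA_real_
  list(shapiro_p = shapiro_p, bp_p = bp_p)
}

subset_tools <- function(tools, task, adult_males_only = FALSE) {
  d <- validate_table(tools, "tools")
  d <- d[d$task == task, , drop = FALSE]
  if (adult_males_only && "user_class" %in% names(d))
    d <- d[is.na(d$user_class) | d$user_class == "adult_male", , drop = FALSE]
  if (length(unique(d$island)) < 2)
    stop("tool records from only one island; need both")
  d$island <- check_island(d$island)
  d
}

#' Mixed model for oyster-tool weights
#'
#' Fits `sqrt(weight_g) ~ island + (1 | user_id)` by maximum likelihood
#' (lme4), restricted to oyster tools used by adult males, and tests the
#' island term by a likelihood-ratio test against the island-free model
#' (chi-square, df = 1). The estimate is the effect of NomSao relative to
#' the Koram reference on the sqrt-gram scale. A singular fit (zero
#' between-individual variance) triggers a warning and a fall back to the
#' ordinary linear model, flagged in the result.
#'
#' @param tools A `tools` data frame.
#' @param adult_males_only Restrict to `user_class == "adult_male"`
#'   (default TRUE, the comparability restriction of the field protocol).
#' @return A `fit_result` with `stat_kind = "chisq"`, plus the fitted lme4
#'   model in attribute `"fit"`.
#' @export
fit_oyster_tool_lmm <- function(tools, adult_males_only = TRUE) {
  d <- subset_tools(tools, "oyster", adult_males_only)
  d <- d[!is.na(d$user_id), , drop = FALSE]
  per_island <- tapply(d$user_id, d$island, function(x) length(unique(x)))
  if (any(is.na(per_island)) || any(per_island < 2))
    stop("need at least 2 individuals per island")
  d$resp <- sqrt(d$weight_g)

  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore")
  full <- suppressMessages(
    lme4::lmer(resp ~ island + (1 | user_id), data = d, REML = FALSE,
               control = ctrl))
  if (lme4::isSingular(full, tol = 1e-5)) {
    warning("singular random-intercept fit; falling back to linear model",
            call. = FALSE)
    res <- lm_island_fit(d, "resp", model = "oyster_tool_lm",
                         transform = "sqrt")
    res$singular <- TRUE
    res$fallback <- TRUE
    return(res)
  }
  null <- suppressMessages(
    lme4::lmer(resp ~ 1 + (1 | user_id), data = d, REML = FALSE,
               control = ctrl))
  an <- stats::anova(null, full)
  est <- lme4::fixef(full)[["islandNomSao"]]
  se <- sqrt(diag(as.matrix(stats::vcov(full))))[["islandNomSao"]]
  diag_ <- residual_diagnostics(stats::fitted(full), stats::residuals(full))
  res <- new_fit_result("oyster_tool_lmm", "islandNomSao", est, se,
                        an$Chisq[2], "chisq", df1 = an$Df[2], df2 = NA,
                        p_value = an$`Pr(>Chisq)`[2], transform = "sqrt",
                        n = nrow(d), n_units = length(unique(d$user_id)),
                        diagnostics = diag_)
  attr(res, "fit") <- full
  res
}

# shared OLS island fit with F-form LRT against the island-free model
lm_island_fit <- function(d, resp, model, transform) {
  full <- stats::lm(stats::reformulate("island", resp), data = d)
  null <- stats::lm(stats::reformulate("1", resp), data = d)
  an <- stats::anova(null, full, test = "F")
  sm <- summary(full)$coefficients
  diag_ <- residual_diagnostics(stats::fitted(full), stats::residuals(full))
  cooks <- stats::cooks.distance(full)
  diag_$high_leverage <- which(cooks > 4 / nrow(d))
  res <- new_fit_result(model, "islandNomSao",
                        sm["islandNomSao", "Estimate"],
                        sm["islandNomSao", "Std. Error"],
                        an$F[2], "F", df1 = an$Df[2], df2 = an$Res.Df[2],
                        p_value = an$`Pr(>F)`[2], transform = transform,
                        n = nrow(d), diagnostics = diag_)
  attr(res, "fit") <- full
  res
}

#' Linear model for snail-tool weights
#'
#' Fits `log(weight_g) ~ island` by ordinary least squares (individual
#' identity is unknown for snail tools, so no random effect is possible)
#' and tests the island term with an F-form likelihood-ratio test. Estimate
#' is NomSao relative to Koram on the log-gram scale, i.e. a multiplicative
#' weight effect.
#'
#' @param tools A `tools` data frame.
#' @return A `fit_result` with `stat_kind = "F"`.
#' @export
fit_snail_tool_lm <- function(tools) {
  d <- subset_tools(tools, "snail")
  if (any(d$weight_g <= 0)) stop("non-positive weights; cannot log-transform")
  if (min(table(d$island)) < 2) stop("need at least 2 records per island")
  d$resp <- log(d$weight_g)
  lm_island_fit(d, "resp", "snail_tool_lm", "log")
}

#' Linear models for snail maturation
#'
#' Models the size category of sampled snails as a function of species,
#' island and maturation stage. Two results are returned: the full model
#' (`size_category ~ species + island * stage`) against the intercept-only
#' null (F-form LRT, "does maturation stage track size at all"), and the
#' island term tested by dropping it from the additive model
#' (`~ species + stage + island` vs `~ species + stage`), whose estimate is
#' the island shift in size category at a given stage. Degrees of freedom
#' are reported as computed from the data.
#'
#' @param samples A `maturation` data frame.
#' @param exclude Species dropped from the cross-island comparison
#'   (default `"M_labio"`, too rare on one island to sample all sizes).
#' @return List with `fit_result` elements `full_vs_null` and
#'   `island_effect`.
#' @export
fit_maturation_lm <- function(samples, exclude = "M_labio") {
  d <- validate_table(samples, "maturation")
  d <- d[!d$species %in% exclude, , drop = FALSE]
  if (length(unique(d$island)) < 2) stop("need samples from both islands")
  if (length(unique(d$species)) < 2) stop("need at least 2 species")
  if (length(unique(d$stage)) < 2) stop("need at least 2 maturation stages")
  per_island_stages <- tapply(d$stage, d$island, function(x)
    length(unique(x)))
  if (any(per_island_stages < 2)) {
    tab <- table(factor(d$island, island_levels()), factor(d$stage, 1:4))
    empty <- which(tab == 0, arr.ind = TRUE)
    stop("rank-deficient design; empty island x stage cells: ",
         paste(sprintf("%s:stage%s", rownames(tab)[empty[, 1]],
                       colnames(tab)[empty[, 2]]), collapse = ", "))
  }
  d$island <- check_island(d$island)

  full <- stats::lm(size_category ~ species + island * stage, data = d)
  null <- stats::lm(size_category ~ 1, data = d)
  an <- stats::anova(null, full, test = "F")
  full_res <- new_fit_result(
    "maturation_full_vs_null", "all_predictors", estimate = NA, se = NA,
    statistic = an$F[2], stat_kind = "F", df1 = an$Df[2],
    df2 = an$Res.Df[2], p_value = an$`Pr(>F)`[2], transform = "none",
    n = nrow(d),
    diagnostics = residual_diagnostics(stats::fitted(full),
                                       stats::residuals(full)))

  m1 <- stats::lm(size_category ~ species + stage + island, data = d)
  m0 <- stats::lm(size_category ~ species + stage, data = d)
  an_i <- stats::anova(m0, m1, test = "F")
  sm <- summary(m1)$coefficients
  island_res <- new_fit_result(
    "maturation_island", "islandNomSao",
    estimate = sm["islandNomSao", "Estimate"],
    se = sm["islandNomSao", "Std. Error"],
    statistic = an_i$F[2], stat_kind = "F", df1 = an_i$Df[2],
    df2 = an_i$Res.Df[2], p_value = an_i$`Pr(>F)`[2], transform = "none",
    n = nrow(d))

  list(full_vs_null = full_res, island_effect = island_res)
}

#' Leave-one-out stability of a fitted island effect
#'
#' Refits a model once per sampling unit (individual) with that unit's
#' records removed, and flags units whose exclusion moves the island-effect
#' estimate by more than `threshold_se` full-model standard errors.
#'
#' @param tools Data frame passed to `fitter`.
#' @param fitter Function returning a `fit_result` (e.g.
#'   [fit_oyster_tool_lmm()]).
#' @param unit_col Column identifying the sampling unit (default
#'   `"user_id"`).
#' @param threshold_se Influence cutoff in SE units (default 1).
#' @return A `stability_report`: named vector `estimates`, `range`,
#'   character vectors `influential` and `failed`, plus the full-model
#'   estimate and SE.
#' @export
leave_one_out_stability <- function(tools, fitter, unit_col = "user_id",
                                    threshold_se = 1) {
  units <- unique(stats::na.omit(tools[[unit_col]]))
  if (length(units) < 3) stop("need at least 3 sampling units")
  full <- suppressWarnings(fitter(tools))
  est <- stats::setNames(rep(NA_real_, length(units)), units)
  failed <- character()
  for (u in units) {
    fit_u <- tryCatch(
      suppressWarnings(fitter(tools[is.na(tools[[unit_col]]) |
                                      tools[[unit_col]] != u, , drop = FALSE])),
      error = function(e) NULL)
    if (is.null(fit_u)) failed <- c(failed, u) else est[u] <- fit_u$estimate
  }
  ok <- !is.na(est)
  influential <- names(est)[ok & abs(est - full$estimate) >
                              threshold_se * full$se]
  structure(list(estimates = est, range = range(est[ok]),
                 influential = influential, failed = failed,
                 full_estimate = full$estimate, full_se = full$se,
                 threshold_se = threshold_se),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("Leave-one-out stability over %d units: estimates in [%.3f, %.3f] (full %.3f, SE %.3f)\n",
              length(x$estimates), x$range[1], x$range[2], x$full_estimate,
              x$full_se))
  cat(if (length(x$influential))
    paste("  influential:", paste(x$influential, collapse = ", "), "\n")
    else "  no influential cases\n")
  if (length(x$failed))
    cat("  failed refits:", paste(x$failed, collapse = ", "), "\n")
  invisible(x)
}

new_group_comparison <- function(what, taxon, test, ci_koram, ci_nomsao,
                                 overlap, n, skipped = FALSE,
                                 skip_reason = NULL) {
  structure(list(what = what, taxon = taxon, test = test,
                 ci_koram = ci_koram, ci_nomsao = ci_nomsao,
                 overlap = overlap, n = n, skipped = skipped,
                 skip_reason = skip_reason),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  if (x$skipped) {
    cat(sprintf("%s / %s: skipped (%s)\n", x$what, x$taxon, x$skip_reason))
    return(invisible(x))
  }
  cat(sprintf("%s / %s (N = %d + %d):\n", x$what, x$taxon, x$n[1], x$n[2]))
  print(x$test)
  cat("  Koram  "); print(x$ci_koram)
  cat("  NomSao "); print(x$ci_nomsao)
  cat("  95% CIs", if (x$overlap) "overlap\n" else "do not overlap\n")
  invisible(x)
}

#' Compare prey sizes between islands for one taxon
#'
#' Welch t-test on the derived size (area for oysters, conical volume for
#' snails) plus per-island percentile bootstrap CIs of the mean size. If
#' either island has fewer than `min_n` records the comparison is skipped
#' and a skip report returned instead (prey too rare to compare).
#'
#' @param sizes A `prey_sizes` data frame.
#' @param taxon One of [prey_taxa()].
#' @param method Size proxy passed to [compute_prey_size()]; default picks
#'   `oyster_area` for oysters and `snail_volume` for snails.
#' @param n_boot,level,seed Bootstrap settings, see [bootstrap_mean_ci()].
#' @param min_n Minimum per-island sample size (default 5).
#' @return A `group_comparison` (or a skip report with `skipped = TRUE`).
#' @export
compare_prey_sizes <- function(sizes, taxon, method = NULL, n_boot = 1000,
                               level = 0.95, seed = NULL, min_n = 5) {
  d <- validate_table(sizes, "prey_sizes")
  d <- d[d$taxon == taxon, , drop = FALSE]
  if (!nrow(d)) stop("no size records for taxon ", taxon)
  n <- c(Koram = sum(d$island == "Koram"), NomSao = sum(d$island == "NomSao"))
  if (any(n < min_n)) {
    return(new_group_comparison(
      "prey_size", taxon, NULL, NULL, NULL, NA, n, skipped = TRUE,
      skip_reason = sprintf("fewer than %d records on %s (N = %d vs %d)",
                            min_n, names(n)[which.min(n)], n[1], n[2])))
  }
  method <- method %||% if (taxon == "oyster") "oyster_area" else "snail_volume"
  d$size <- compute_prey_size(d$length_mm, d$width_mm, method)
  k <- d$size[d$island == "Koram"]; s <- d$size[d$island == "NomSao"]
  bc <- bootstrap_group_compare(k, s, n_boot, level, seed)
  new_group_comparison("prey_size", taxon, welch_t_test(k, s),
                       bc$ci_a, bc$ci_b, bc$overlap, n)
}

#' Compare per-plot snail availability between islands
#'
#' Welch t-test on per-plot counts of one species plus per-island bootstrap
#' CIs of the mean per-plot count.
#'
#' @param transects A `snail_transects` data frame.
#' @param species One of [snail_species()].
#' @inheritParams compare_prey_sizes
#' @return A `group_comparison`.
#' @export
compare_availability <- function(transects, species, n_boot = 1000,
                                 level = 0.95, seed = NULL) {
  d <- validate_table(transects, "snail_transects")
  if (!species %in% snail_species())
    stop("unknown species '", species, "'; expected one of ",
         paste(snail_species(), collapse = ", "))
  d <- d[d$species == species, , drop = FALSE]
  if (length(unique(d$island)) < 2)
    stop("need transect counts from both islands for ", species)
  k <- d$count[d$island == "Koram"]; s <- d$count[d$island == "NomSao"]
  test <- tryCatch(welch_t_test(k, s), error = function(e)
    stop("availability comparison for ", species, " is degenerate: ",
         conditionMessage(e), call. = FALSE))
  bc <- bootstrap_group_compare(k, s, n_boot, level, seed)
  new_group_comparison("availability", species, test, bc$ci_a, bc$ci_b,
                       bc$overlap, c(Koram = length(k), NomSao = length(s)))
}

#' Compare natural stone supply between islands
#'
#' Two tests: per-quadrat stone counts (availability) and per-stone weights
#' (size), each Welch. Per-plot counts are zero-filled over the full
#' sampling design of 7 locations x the zones surveyed on each island, so
#' quadrats in which no candidate stone was found still count as zeros.
#' Bootstrap CIs of mean count and mean weight are reported separately per
#' island and littoral zone.
#'
#' @param quadrats A `stone_quadrats` data frame (one row per stone).
#' @inheritParams compare_prey_sizes
#' @param n_locations Locations per island in the design (default 7).
#' @return A `stone_supply_comparison`: `counts_test`, `weights_test`,
#'   `plot_counts` data frame, and a list `cis` keyed
#'   `island.zone.{count,weight}`.
#' @export
compare_stone_supply <- function(quadrats, n_boot = 1000, level = 0.95,
                                 seed = NULL, n_locations = 7) {
  d <- validate_table(quadrats, "stone_quadrats")
  if (length(unique(d$island)) < 2) stop("need quadrats from both islands")

  plot_counts <- list()
  for (isl in island_levels()) {
    zones <- unique(d$zone[d$island == isl])
    missing_zones <- setdiff(c("oyster_bed", "tidal"), zones)
    if (length(missing_zones))
      message("no ", paste(missing_zones, collapse = "/"), " quadrats on ",
              isl, "; CIs reported for present zones only")
    grid <- expand.grid(island = isl, location_index = seq_len(n_locations),
                        zone = zones, stringsAsFactors = FALSE)
    cnt <- stats::aggregate(list(count = d$stone_weight_g[d$island == isl]),
                            d[d$island == isl,
                              c("island", "location_index", "zone")], length)
    m <- merge(grid, cnt, all.x = TRUE)
    m$count[is.na(m$count)] <- 0
    plot_counts[[isl]] <- m
  }
  plot_counts <- do.call(rbind, plot_counts)
  rownames(plot_counts) <- NULL

  kc <- plot_counts$count[plot_counts$island == "Koram"]
  nc <- plot_counts$count[plot_counts$island == "NomSao"]
  kw <- d$stone_weight_g[d$island == "Koram"]
  nw <- d$stone_weight_g[d$island == "NomSao"]
  identical_groups <- function(a, b)
    length(a) == length(b) && isTRUE(all.equal(sort(a), sort(b)))
  # two identical degenerate groups: report t = 0, p = 1 rather than error
  safe_t <- function(a, b) {
    if (stats::var(a) == 0 && stats::var(b) == 0 && identical_groups(a, b))
      structure(list(statistic = 0, df = length(a) + length(b) - 2,
                     df_int = length(a) + length(b) - 2L, p_value = 1,
                     kind = "t_welch", n = length(a) + length(b)),
                class = "test_result")
    else welch_t_test(a, b)
  }
  counts_test <- safe_t(kc, nc)
  weights_test <- safe_t(kw, nw)

  cis <- list()
  sub_seed <- seed
  for (isl in island_levels()) for (z in unique(d$zone[d$island == isl])) {
    key <- paste(isl, z, sep = ".")
    pc <- plot_counts$count[plot_counts$island == isl & plot_counts$zone == z]
    sw <- d$stone_weight_g[d$island == isl & d$zone == z]
    cis[[paste0(key, ".count")]] <-
      bootstrap_mean_ci(pc, n_boot, level, sub_seed)
    if (length(sw))
      cis[[paste0(key, ".weight")]] <-
        bootstrap_mean_ci(sw, n_boot, level,
                          if (is.null(sub_seed)) NULL else sub_seed + 1)
    if (!is.null(sub_seed)) sub_seed <- sub_seed + 2
  }

  structure(list(counts_test = counts_test, weights_test = weights_test,
                 plot_counts = plot_counts, cis = cis,
                 n_stones = c(Koram = length(kw), NomSao = length(nw))),
            class = "stone_supply_comparison")
}

#' @export
print.stone_supply_comparison <- function(x, ...) {
  cat("Stone supply comparison\n  per-plot counts: "); print(x$counts_test)
  cat("  per-stone weights: "); print(x$weights_test)
  invisible(x)
}

#' Flatten fit results into a long report table
#'
#' @param results Named list of `fit_result` objects.
#' @param seed Seed to record alongside each row (optional).
#' @return Data frame with columns model, term, estimate, se, statistic,
#'   df1, df2, p, transform, n, seed.
#' @export
fit_results_table <- function(results, seed = NA) {
  rows <- lapply(results, function(r) data.frame(
    model = r$model, term = r$term,
    estimate = r$estimate %||% NA, se = r$se %||% NA,
    statistic = r$statistic, df1 = r$df1, df2 = r$df2 %||% NA,
    p = r$p_value, transform = r$transform, n = r$n, seed = seed,
    stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
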