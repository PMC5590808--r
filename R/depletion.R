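# Consumption-extrapolation depletion model: foraging areas, standing prey
# populations from transect densities, annual consumption, depletion
# ratios, undersize fractions and the life-history vulnerability mapping.
#
# Reported quantities follow the survey-report rounding convention: half-up
# (round_half_up), with density rounded to 2 decimals BEFORE multiplying by
# the foraging area. Years-to-depletion assumes no replenishment (larval
# import is outside the model).

profile_row <- function(profiles, island = NULL) {
  if (is.data.frame(profiles) && nrow(profiles) > 1) {
    if (is.null(island)) stop("profiles has several rows; give island=")
    profiles <- profiles[profiles$island == island, , drop = FALSE]
    if (!nrow(profiles)) stop("no profile for island ", island)
  }
  profiles
}

#' Foraging area of an island
#'
#' Accessible shoreline length multiplied by the average width of the
#' foraging strip; exact, no rounding.
#'
#' @param profile A one-row `island_profiles` data frame (see
#'   [island_profile()]), or a multi-row table plus `island`.
#' @param island Island to select when `profile` has several rows.
#' @return Area in m^2.
#' @examples
#' foraging_area(island_profile("Koram", 26, 1551))  # 4653
#' @export
foraging_area <- function(profile, island = NULL) {
  p <- profile_row(profile, island)
  check_number(p$accessible_shoreline_m, "accessible_shoreline_m", 0)
  check_number(p$strip_width_m, "strip_width_m", 0, strict = TRUE)
  p$accessible_shoreline_m * p$strip_width_m
}

#' Accessible shoreline per tool user
#'
#' @inheritParams foraging_area
#' @param decimals Report rounding, half-up (default 1).
#' @return Metres of shoreline per tool-using individual.
#' @examples
#' shoreline_per_user(island_profile("NomSao", 4, 653))  # 163.3
#' @export
shoreline_per_user <- function(profile, island = NULL, decimals = 1) {
  p <- profile_row(profile, island)
  if (p$n_tool_users < 1) stop("n_tool_users must be >= 1")
  round_half_up(p$accessible_shoreline_m / p$n_tool_users, decimals)
}

#' Per-plot counts of one species on one island
#'
#' @param transects A `snail_transects` data frame.
#' @param island,species Selection.
#' @return Integer vector of per-plot counts.
#' @export
plot_counts <- function(transects, island, species) {
  d <- validate_table(transects, "snail_transects")
  d$count[d$island == island & d$species == species]
}

#' Standing population from transect density
#'
#' Density is the total count over all plots divided by the number of
#' plots (each 1 m^2), rounded half-up to `density_decimals`; the standing
#' population is density times area, rounded half-up to the nearest
#' individual.
#'
#' @param counts Per-plot counts (e.g. [plot_counts()]), length >= 1.
#' @param area_m2 Habitat area in m^2, > 0.
#' @param density_decimals Decimals kept in the per-m^2 density (default 2).
#' @return Integer population estimate; the rounded density is attached as
#'   attribute `"density"`.
#' @examples
#' standing_population(rep(181 / 14, 14), 4653)  # 60163
#' @export
standing_population <- function(counts, area_m2, density_decimals = 2) {
  if (!length(counts)) stop("need at least one plot")
  check_number(area_m2, "area_m2", 0, strict = TRUE)
  density <- round_half_up(sum(counts) / length(counts), density_decimals)
  pop <- as.integer(round_half_up(density * area_m2))
  attr(pop, "density") <- density
  pop
}

#' Annual prey consumption of an island's tool users
#'
#' Extrapolates per-individual intake to the whole tool-using cohort over a
#' year. Basis `"daily_total"` uses the total items per day; basis
#' `"hourly_periwinkle"` uses the periwinkle rate per foraging hour times
#' the daily foraging window.
#'
#' @param rates A [consumption_rates()] row.
#' @param n_users Number of tool users (>= 0).
#' @param basis `"daily_total"` or `"hourly_periwinkle"`.
#' @param report_rounding `"none"` (exact) or `"nearest_thousand"`.
#' @return Items per year.
#' @examples
#' r <- consumption_rates()
#' annual_consumption(r, 26, "daily_total", "nearest_thousand")  # 441000
#' annual_consumption(r, 4, "hourly_periwinkle")                 # 9344
#' @export
annual_consumption <- function(rates,
                               n_users,
                               basis = c("daily_total", "hourly_periwinkle"),
                               report_rounding = c("none",
                                                   "nearest_thousand")) {
  basis <- match.arg(basis)
  report_rounding <- match.arg(report_rounding)
  check_number(n_users, "n_users", 0)
  per_day <- switch(basis,
    daily_total = rates$total_items_per_day,
    hourly_periwinkle = rates$periwinkles_per_hour *
      rates$foraging_hours_per_day)
  x <- per_day * n_users * rates$days_per_year
  if (report_rounding == "nearest_thousand") round_half_up(x / 1000) * 1000
  else x
}

#' Depletion ratio and years to depletion
#'
#' The depletion ratio is annual consumption divided by the standing
#' population; a ratio above 1 means one year's consumption exceeds the
#' current stock absent replenishment. Years to depletion is the
#' reciprocal, labelled "without replenishment" since larval import is
#' outside the model. Degenerate cases are encoded as 0/Inf rather than
#' errors.
#'
#' @param standing Standing population (>= 0).
#' @param annual Annual consumption (>= 0).
#' @return List `ratio`, `years_to_depletion`.
#' @export
depletion_assessment <- function(standing, annual) {
  check_number(standing, "standing", 0)
  check_number(annual, "annual", 0)
  ratio <- if (annual == 0) 0
  else if (standing == 0) Inf
  else annual / standing
  list(ratio = ratio,
       years_to_depletion = if (ratio > 0) 1 / ratio else Inf)
}

#' Fraction of prey below a reproductive size threshold
#'
#' @param lengths_mm Shell lengths, mm (nonempty).
#' @param reproductive_size_mm Literature threshold, mm (>= 0); strict
#'   inequality, so a shell exactly at the threshold is not undersize.
#' @return List `fraction`, `n`.
#' @examples
#' undersize_fraction(c(1, 2, 3, 4), 2.5)$fraction  # 0.5
#' @export
undersize_fraction <- function(lengths_mm, reproductive_size_mm) {
  if (!length(lengths_mm)) stop("need at least one size record")
  check_number(reproductive_size_mm, "reproductive_size_mm", 0)
  list(fraction = mean(lengths_mm < reproductive_size_mm),
       n = length(lengths_mm))
}

#' Life-history profile of a prey species
#'
#' The four categorical traits that drive recovery from harvesting:
#' spatial aggregation, size at sexual maturity, per-individual
#' reproductive output, and larval mode.
#'
#' @param species Species label.
#' @param aggregation `"high"` or `"low"`.
#' @param size_at_maturity `"large"` or `"small"`.
#' @param reproductive_output `"high"` or `"low"`.
#' @param larval_mode `"attached"` or `"planktonic"`.
#' @return A `life_history_profile` list.
#' @export
life_history_profile <- function(species, aggregation, size_at_maturity,
                                 reproductive_output, larval_mode) {
  structure(list(
    species = species,
    aggregation = match.arg(aggregation, c("high", "low")),
    size_at_maturity = match.arg(size_at_maturity, c("large", "small")),
    reproductive_output = match.arg(reproductive_output, c("high", "low")),
    larval_mode = match.arg(larval_mode, c("attached", "planktonic"))),
    class = "life_history_profile")
}

#' Built-in life histories of the two main prey species
#'
#' Rock oyster: highly aggregated, large at maturity (reproduces in its
#' first year at ~25 mm), very high output (50-200 million eggs),
#' planktonic larvae. Tropical periwinkle: highly aggregated, small at
#' maturity, low output (10,000-100,000, ~2% surviving to maturity),
#' planktonic larvae.
#'
#' @return Named list of [life_history_profile()] objects.
#' @export
builtin_life_histories <- function() {
  list(
    rock_oyster = life_history_profile("rock_oyster", "high", "large",
                                       "high", "planktonic"),
    tropical_periwinkle = life_history_profile("tropical_periwinkle", "high",
                                               "small", "low", "planktonic"))
}

#' Vulnerability assessment from life-history traits
#'
#' Applies the four factor rules: high aggregation -> slow recovery; large
#' size at sexual maturity -> slow recovery; high reproductive output ->
#' fast recovery; attached larvae -> slow recovery. The summary is
#' `vulnerable` only when every factor predicts slow recovery, `resilient`
#' only when every factor predicts fast recovery, otherwise `mixed`.
#'
#' @param profile A [life_history_profile()].
#' @return A `vulnerability_assessment`: `species`, named character
#'   `predictions`, and `summary`.
#' @export
assess_vulnerability <- function(profile) {
  stopifnot(inherits(profile, "life_history_profile"))
  slow <- "slow_recovery"; fast <- "fast_recovery"
  predictions <- c(
    aggregation = if (profile$aggregation == "high") slow else fast,
    size_at_maturity = if (profile$size_at_maturity == "large") slow else fast,
    reproductive_output =
      if (profile$reproductive_output == "high") fast else slow,
    larval_mode = if (profile$larval_mode == "attached") slow else fast)
  summary <- if (all(predictions == slow)) "vulnerable"
  else if (all(predictions == fast)) "resilient"
  else "mixed"
  structure(list(species = profile$species, predictions = predictions,
                 summary = summary),
            class = "vulnerability_assessment")
}

#' @export
print.vulnerability_assessment <- function(x, ...) {
  cat(sprintf("%s: %s\n", x$species, x$summary))
  for (f in names(x$predictions))
    cat(sprintf("  %-20s %s\n", f, x$predictions[f]))
  invisible(x)
}

#' Per-island depletion table for one prey species
#'
#' Combines island profiles, consumption rates and transect counts into the
#' full extrapolation: foraging area, per-m^2 density, standing population,
#' annual consumption, depletion ratio and years to depletion (without
#' replenishment).
#'
#' @param profiles An `island_profiles` data frame (both islands).
#' @param rates A [consumption_rates()] row.
#' @param transects A `snail_transects` data frame.
#' @param species Species to assess (default `"P_sulcatus"`).
#' @param basis Consumption basis, see [annual_consumption()]; the default
#'   `"hourly_periwinkle"` matches the periwinkle depletion extrapolation.
#' @param density_decimals See [standing_population()].
#' @return Data frame with one row per island.
#' @export
depletion_table <- function(profiles, rates, transects,
                            species = "P_sulcatus",
                            basis = "hourly_periwinkle",
                            density_decimals = 2) {
  profiles <- validate_table(profiles, "island_profiles")
  rows <- lapply(profiles$island, function(isl) {
    p <- profiles[profiles$island == isl, , drop = FALSE]
    area <- foraging_area(p)
    cnt <- plot_counts(transects, isl, species)
    standing <- standing_population(cnt, area, density_decimals)
    annual <- annual_consumption(rates, p$n_tool_users, basis)
    da <- depletion_assessment(standing, annual)
    data.frame(island = isl, species = species, area_m2 = area,
               density_per_m2 = attr(standing, "density"),
               standing_population = as.integer(standing),
               annual_consumption = annual, depletion_ratio = da$ratio,
               years_to_depletion = da$years_to_depletion,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Share of a cohort that uses tools, as a percentage
#'
#' @param n_users Tool users in the cohort.
#' @param n_cohort Cohort size (> 0).
#' @param decimals Half-up rounding of the percentage (default 1).
#' @return Percentage.
#' @examples
#' tool_user_share(25, 36)  # 69.4
#' @export
tool_user_share <- function(n_users, n_cohort, decimals = 1) {
  check_number(n_cohort, "n_cohort", 0, strict = TRUE)
  check_number(n_users, "n_users", 0)
  round_half_up(100 * n_users / n_cohort, decimals)
}

#' Population density of an island group
#'
#' @param n_individuals Group size.
#' @param area_km2 Island area, km^2 (> 0).
#' @return Individuals per km^2 (unrounded).
#' @examples
#' population_density(9, 0.10)  # 90
#' @export
population_density <- function(n_individuals, area_km2) {
  check_number(area_km2, "area_km2", 0, strict = TRUE)
  check_number(n_individuals, "n_individuals", 0)
  n_individuals / area_km2
}
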