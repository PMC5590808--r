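# Depletion model arithmetic, rounding conventions and vulnerability rules.

test_that("foraging areas and shoreline per tool user match the field profiles", {
  koram <- island_profile("Koram", 26, 1551)
  nomsao <- island_profile("NomSao", 4, 653)
  expect_equal(foraging_area(koram), 4653)
  expect_equal(foraging_area(nomsao), 1959)
  expect_equal(foraging_area(island_profile("Koram", 1, 0)), 0)

  expect_equal(shoreline_per_user(nomsao), 163.3)  # 163.25 rounds up
  expect_equal(shoreline_per_user(island_profile("Koram", 28, 1551)), 55.4)
  expect_equal(shoreline_per_user(island_profile("Koram", 1, 777)), 777)
})

test_that("standing population applies the density-rounding convention", {
  k <- standing_population(transects_from_totals(
    c(P_sulcatus = 181), c(P_sulcatus = 568)) |>
      plot_counts("Koram", "P_sulcatus"), 4653)
  expect_equal(as.integer(k), 60163L)
  expect_equal(attr(k, "density"), 12.93)

  n <- standing_population(rep(568 / 14, 14), 1959)
  expect_equal(as.integer(n), 79477L)
  expect_equal(as.integer(standing_population(rep(0, 14), 1000)), 0L)
  expect_error(standing_population(numeric(0), 100), "at least one plot")
})

test_that("annual consumption reproduces both extrapolation bases", {
  r <- consumption_rates()
  expect_equal(annual_consumption(r, 26, "daily_total"), 441285)
  expect_equal(annual_consumption(r, 26, "daily_total", "nearest_thousand"),
               441000)
  expect_equal(annual_consumption(r, 26, "hourly_periwinkle"), 60736)
  expect_equal(annual_consumption(r, 26, "hourly_periwinkle",
                                  "nearest_thousand"), 61000)
  expect_equal(annual_consumption(r, 4, "hourly_periwinkle"), 9344)
  expect_equal(annual_consumption(r, 0, "daily_total"), 0)
  expect_error(annual_consumption(r, 4, "weekly"), "arg")
})

test_that("depletion assessment handles ratios and degenerate stocks", {
  koram <- depletion_assessment(60163, 60736)
  expect_gt(koram$ratio, 1)
  nomsao <- depletion_assessment(79477, 9344)
  expect_equal(nomsao$ratio, 0.1176, tolerance = 1e-3)
  expect_equal(nomsao$years_to_depletion, 1 / nomsao$ratio)

  expect_equal(depletion_assessment(100, 0),
               list(ratio = 0, years_to_depletion = Inf))
  expect_equal(depletion_assessment(0, 10)$ratio, Inf)
  # ratio * standing = annual exactly, pre-rounding
  expect_equal(koram$ratio * 60163, 60736)
})

test_that("linear inputs scale the depletion quantities homogeneously", {
  p1 <- island_profile("Koram", 26, 700)
  p2 <- island_profile("Koram", 26, 1400)
  expect_equal(foraging_area(p2), 2 * foraging_area(p1))
  r <- consumption_rates()
  expect_equal(annual_consumption(r, 8, "daily_total"),
               2 * annual_consumption(r, 4, "daily_total"))
  cnt <- c(3, 7, 9, 2)
  s1 <- standing_population(cnt, 500, density_decimals = 8)
  s2 <- standing_population(cnt, 1000, density_decimals = 8)
  expect_equal(as.integer(s2), 2L * as.integer(s1))
})

test_that("undersize fraction counts strictly-below-threshold records", {
  expect_equal(undersize_fraction(c(1, 2, 3, 4), 2.5)$fraction, 0.5)
  expect_equal(undersize_fraction(c(1, 2, 3), 0)$fraction, 0)
  expect_equal(undersize_fraction(c(5, 6), 5)$fraction, 0)  # strict
  expect_error(undersize_fraction(numeric(0), 10), "at least one")
  # monotone non-decreasing in the threshold
  x <- c(2, 4, 4, 8, 9)
  fr <- sapply(1:10, function(th) undersize_fraction(x, th)$fraction)
  expect_false(is.unsorted(fr))
})

test_that("vulnerability mapping applies the four life-history rules", {
  lh <- builtin_life_histories()
  oyster <- assess_vulnerability(lh$rock_oyster)
  expect_equal(unname(oyster$predictions),
               c("slow_recovery", "slow_recovery", "fast_recovery",
                 "fast_recovery"))
  expect_equal(oyster$summary, "mixed")

  peri <- assess_vulnerability(lh$tropical_periwinkle)
  expect_equal(unname(peri$predictions),
               c("slow_recovery", "fast_recovery", "slow_recovery",
                 "fast_recovery"))
  expect_equal(peri$summary, "mixed")

  resilient <- assess_vulnerability(life_history_profile(
    "x", "low", "small", "high", "planktonic"))
  expect_equal(resilient$summary, "resilient")
  vulnerable <- assess_vulnerability(life_history_profile(
    "y", "high", "large", "low", "attached"))
  expect_equal(vulnerable$summary, "vulnerable")
})

test_that("the depletion table combines all pieces per island", {
  sc <- generate_consumption_scenario()
  tr <- transects_from_totals(c(P_sulcatus = 181), c(P_sulcatus = 568))
  tab <- depletion_table(sc$profiles, sc$rates, tr)
  expect_equal(tab$standing_population, c(60163L, 79477L))
  expect_equal(tab$annual_consumption, c(60736, 9344))
  expect_gt(tab$depletion_ratio[1], 1)
  expect_lt(tab$years_to_depletion[1], 1)
  expect_equal(tab$depletion_ratio[2], 0.118, tolerance = 0.01)
})

test_that("group-composition helpers follow the report rounding", {
  expect_equal(tool_user_share(25, 36), 69.4)
  expect_equal(population_density(9, 0.10), 90)
  expect_error(tool_user_share(5, 0), "> 0")
})
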