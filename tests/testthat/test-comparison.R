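# Model-fitting stages and comparison batteries.

test_that("snail-tool LM recovers an exact log-scale difference", {
  tools <- data.frame(island = rep(c("Koram", "NomSao"), each = 2),
                      task = "snail",
                      weight_g = c(exp(1), exp(1), exp(2), exp(2)))
  fit <- suppressWarnings(fit_snail_tool_lm(tools))  # zero-residual toy fit
  expect_equal(fit$estimate, 1.0, tolerance = 1e-12)
  expect_equal(fit$transform, "log")
  expect_equal(fit$reference_level, "Koram")
})

test_that("snail-tool LM equals a normal-equations oracle", {
  set.seed(6)
  for (i in 1:10) {
    n <- c(sample(10:40, 1), sample(10:40, 1))
    tools <- data.frame(island = rep(c("Koram", "NomSao"), n), task = "snail",
                        weight_g = rlnorm(sum(n), 5, 0.5))
    fit <- fit_snail_tool_lm(tools)

    # oracle: solve the normal equations by hand
    y <- log(tools$weight_g)
    X <- cbind(1, as.numeric(tools$island == "NomSao"))
    beta <- solve(t(X) %*% X, t(X) %*% y)
    resid <- y - X %*% beta
    s2 <- sum(resid^2) / (sum(n) - 2)
    se <- sqrt(s2 * solve(t(X) %*% X)[2, 2])
    rss0 <- sum((y - mean(y))^2)
    f <- (rss0 - sum(resid^2)) / (sum(resid^2) / (sum(n) - 2))

    expect_equal(fit$estimate, beta[2, 1], tolerance = 1e-8)
    expect_equal(fit$se, se, tolerance = 1e-8)
    expect_equal(fit$statistic, f, tolerance = 1e-8)
    expect_equal(fit$df2, sum(n) - 2)
  }
  expect_error(
    fit_snail_tool_lm(data.frame(island = c("Koram", "Koram", "NomSao",
                                            "NomSao"),
                                 task = "snail", weight_g = c(1, 2, -1, 3))),
    "> 0")
})

test_that("oyster-tool LMM recovers a planted island effect on the sqrt scale", {
  ds <- generate_dataset(simulation_config(seed = 14,
                                           island_effect_tool_sqrt = -1.7))
  fit <- fit_oyster_tool_lmm(ds$tools)
  expect_equal(fit$stat_kind, "chisq")
  expect_equal(fit$df1, 1)
  expect_equal(fit$transform, "sqrt")
  expect_equal(fit$n, 186)
  expect_lt(abs(fit$estimate - (-1.7)), 2 * fit$se)
})

test_that("LMM on zero-individual-variance data falls back to the LM estimate", {
  ds <- generate_dataset(simulation_config(seed = 15, individual_sd = 0))
  expect_warning(fit <- fit_oyster_tool_lmm(ds$tools), "singular")
  expect_true(fit$singular)
  lm_fit <- lm_ref <- stats::lm(sqrt(weight_g) ~ factor(island, island_levels()),
                                data = ds$tools[ds$tools$task == "oyster", ])
  expect_equal(fit$estimate, unname(coef(lm_ref)[2]), tolerance = 1e-4)
})

test_that("LMM requires both islands and >= 2 individuals each", {
  ds <- generate_dataset(simulation_config(seed = 16))
  oy <- ds$tools[ds$tools$task == "oyster", ]
  expect_error(fit_oyster_tool_lmm(oy[oy$island == "Koram", ]), "one island")
  few <- oy[oy$island == "Koram" | oy$user_id == "N_M01", ]
  expect_error(fit_oyster_tool_lmm(few), "2 individuals")
})

test_that("permutation companion agrees with the LMM likelihood-ratio test", {
  cfg <- simulation_config(seed = 23, n_tools_oyster = c(60, 60),
                           n_individuals_oyster = c(10, 10),
                           island_effect_tool_sqrt = 0.9)
  ds <- generate_dataset(cfg)
  oy <- ds$tools[ds$tools$task == "oyster", ]
  fit <- fit_oyster_tool_lmm(oy)
  perm <- permutation_island_test(
    oy, function(d) suppressWarnings(fit_oyster_tool_lmm(d))$statistic,
    n_perm = 400, unit = "individual", seed = 31)
  mc_sd <- sqrt(fit$p_value * (1 - fit$p_value) / 400)
  expect_lt(abs(perm$p_value - fit$p_value), max(3 * mc_sd, 0.04))
})

test_that("maturation models detect the size-stage link but no island term", {
  # identical stage-size structure duplicated across islands: island effect 0
  block <- expand.grid(species = c("P_sulcatus", "C_bifasciatus"),
                       stage = 1:4, rep = 1:2, stringsAsFactors = FALSE)
  block$size_category <- pmin(4, block$stage + (block$rep - 1))
  block$shell_size_mm <- 4 * block$size_category
  samples <- rbind(cbind(block, island = "Koram"),
                   cbind(block, island = "NomSao"))
  fits <- suppressWarnings(fit_maturation_lm(samples))  # exact-fit toy
  expect_equal(fits$island_effect$estimate, 0, tolerance = 1e-12)
  expect_equal(fits$island_effect$p_value, 1, tolerance = 1e-12)

  # synthetic data with a positive maturation slope: full vs null rejects
  ds <- generate_dataset(simulation_config(seed = 18))
  fits2 <- fit_maturation_lm(ds$maturation)
  expect_lt(fits2$full_vs_null$p_value, 0.001)
  expect_equal(fits2$full_vs_null$n,
               sum(ds$maturation$species != "M_labio"))
})

test_that("maturation model rejects rank-deficient designs with named cells", {
  bad <- data.frame(island = rep(c("Koram", "NomSao"), each = 4),
                    species = rep(c("P_sulcatus", "C_bifasciatus"), 4),
                    size_category = 1, shell_size_mm = 5,
                    stage = c(1, 2, 1, 2, 3, 3, 3, 3))
  expect_error(fit_maturation_lm(bad), "NomSao:stage")
})

test_that("leave-one-out stability flags only genuinely influential units", {
  # identical individuals: every reduced estimate equals the full estimate
  w <- lapply(c(K1 = 1, K2 = 1, K3 = 1, N1 = 1, N2 = 1, N3 = 1),
              function(i) c(100, 121, 144))
  tools <- tools_from_users(w)
  rep_same <- suppressWarnings(
    leave_one_out_stability(tools, fit_oyster_tool_lmm))
  expect_equal(unname(rep_same$estimates),
               rep(rep_same$full_estimate, 6), tolerance = 1e-6)
  expect_length(rep_same$influential, 0)

  # one planted outlier individual dominates its island's mean
  set.seed(77)
  w2 <- c(lapply(stats::setNames(nm = paste0("K", 1:6)),
                 function(u) rnorm(6, 100, 5)),
          lapply(stats::setNames(nm = paste0("N", 1:5)),
                 function(u) rnorm(6, 100, 5)),
          list(N9 = rnorm(6, 2500, 5)))
  rep_out <- suppressWarnings(
    leave_one_out_stability(tools_from_users(w2), fit_oyster_tool_lmm))
  expect_true("N9" %in% rep_out$influential)

  expect_error(leave_one_out_stability(tools_from_users(w[1:2]),
                                       fit_oyster_tool_lmm), "3 sampling units")
})

test_that("prey-size comparison skips rare taxa and degenerates to t = 0 on equal data", {
  same <- sizes_from_lengths(c(10, 12, 14, 16, 18), c(10, 12, 14, 16, 18))
  cmp <- compare_prey_sizes(same, "oyster", n_boot = 100, seed = 1)
  expect_equal(cmp$test$statistic, 0)
  expect_true(cmp$overlap)

  rare <- sizes_from_lengths(c(10, 11, 12, 13), rnorm(68, 14), "M_labio")
  skip_rep <- compare_prey_sizes(rare, "M_labio")
  expect_true(skip_rep$skipped)
  expect_match(skip_rep$skip_reason, "fewer than 5")
  expect_equal(unname(skip_rep$n), c(4, 68))

  expect_error(compare_prey_sizes(same, "C_bifasciatus"), "no size records")
})

test_that("prey-size comparison has power against a 2-SD island shift", {
  set.seed(50)
  rej <- replicate(30, {
    sizes <- sizes_from_lengths(rnorm(50, 20, 2), rnorm(50, 24, 2))
    compare_prey_sizes(sizes, "oyster", n_boot = 20)$test$p_value < 0.05
  })
  expect_gte(mean(rej), 0.99)
})

test_that("availability comparison surfaces degenerate counts cleanly", {
  tr <- transects_from_totals(c(P_sulcatus = 0), c(P_sulcatus = 0))
  expect_error(compare_availability(tr, "P_sulcatus"), "degenerate")
  expect_error(compare_availability(tr, "Nerita"), "unknown species")

  tr2 <- transects_from_totals(c(P_sulcatus = 181), c(P_sulcatus = 568))
  cmp <- compare_availability(tr2, "P_sulcatus", n_boot = 200, seed = 2)
  expect_equal(cmp$ci_koram$point, 181 / 14)
  expect_lt(cmp$test$p_value, 0.001)
})

test_that("stone-supply battery separates availability from size", {
  set.seed(33)
  mk <- function(island, shift) {
    counts <- c(3, 4, 5)
    do.call(rbind, lapply(1:3, function(loc) data.frame(
      island = island, location_index = loc, zone = "tidal",
      stone_weight_g = rnorm(counts[loc], 100, 1) + shift,
      stringsAsFactors = FALSE)))
  }
  q <- rbind(mk("Koram", 0), mk("NomSao", 10))
  res <- compare_stone_supply(q, n_boot = 100, seed = 3, n_locations = 3)
  expect_equal(res$counts_test$p_value, 1)       # identical count vectors
  expect_lt(res$weights_test$p_value, 1e-4)      # +10 g shift
  expect_named(res$cis, c("Koram.tidal.count", "Koram.tidal.weight",
                          "NomSao.tidal.count", "NomSao.tidal.weight"))

  # zone missing on one island: message, CIs only for present zones
  q2 <- rbind(q, data.frame(island = "Koram", location_index = 1,
                            zone = "oyster_bed", stone_weight_g = 90))
  expect_message(res2 <- compare_stone_supply(q2, n_boot = 50, seed = 1,
                                              n_locations = 3), "NomSao")
  expect_true("Koram.oyster_bed.weight" %in% names(res2$cis))
  expect_false("NomSao.oyster_bed.weight" %in% names(res2$cis))
})

test_that("fit results flatten into the long report table", {
  ds <- generate_dataset(simulation_config(seed = 41))
  tab <- fit_results_table(list(fit_snail_tool_lm(ds$tools)), seed = 41)
  expect_equal(names(tab), c("model", "term", "estimate", "se", "statistic",
                             "df1", "df2", "p", "transform", "n", "seed"))
  expect_equal(tab$transform, "log")
})
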