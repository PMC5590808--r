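# End-to-end orchestration: simulate (or load), compare tools / prey /
# stones, maturation, depletion; result CSVs plus a JSON run manifest.

#' Pipeline configuration
#'
#' Exactly one of `paths` (CSV survey tables, see [read_survey_tables()])
#' or `simulation` (a [simulation_config()]) must be given. Resampling
#' defaults follow the reference analysis: 10,000 permutations, 1,000
#' bootstrap resamples, 95% intervals.
#'
#' @param paths Named file paths, or `NULL`.
#' @param simulation A [simulation_config()], or `NULL`.
#' @param seed Master seed for all resampling streams.
#' @param n_perm Permutation relabelings (default 10000).
#' @param n_boot Bootstrap resamples (default 1000).
#' @param ci_level Confidence level (default 0.95).
#' @param density_decimals Density rounding in the depletion stage.
#' @param run_permutations Also run the permutation companions of the tool
#'   models (default FALSE; each permutation refits the model `n_perm`
#'   times, which is expensive for the mixed model).
#' @param depletion_species Species for the depletion table.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(paths = NULL, simulation = NULL, seed = 1L,
                            n_perm = 10000, n_boot = 1000, ci_level = 0.95,
                            density_decimals = 2, run_permutations = FALSE,
                            depletion_species = "P_sulcatus") {
  if (is.null(paths) == is.null(simulation))
    stop("exactly one of paths / simulation must be set")
  structure(list(paths = paths, simulation = simulation,
                 seed = as.integer(seed), n_perm = n_perm, n_boot = n_boot,
                 ci_level = ci_level, density_decimals = density_decimals,
                 run_permutations = isTRUE(run_permutations),
                 depletion_species = depletion_species),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML file may contain any [pipeline_config()] field; a `simulation`
#' block is forwarded to [simulation_config()].
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulation)) {
    if (!is.null(y$simulation$abundance_rate))
      y$simulation$abundance_rate <- lapply(y$simulation$abundance_rate,
                                            unlist)
    y$simulation <- do.call(simulation_config, y$simulation)
  }
  do.call(pipeline_config, y)
}

stage_try <- function(bundle, name, expr) {
  res <- tryCatch(list(ok = TRUE, value = expr),
                  error = function(e) list(ok = FALSE,
                                           error = conditionMessage(e)))
  bundle$stages[[name]] <- if (res$ok) "ok" else paste("error:", res$error)
  if (res$ok) bundle$results[[name]] <- res$value
  else bundle$errors[[name]] <- res$error
  bundle
}

comparison_row <- function(cmp) {
  if (cmp$skipped %||% FALSE)
    return(data.frame(what = cmp$what, taxon = cmp$taxon, n_koram = cmp$n[1],
                      n_nomsao = cmp$n[2], statistic = NA, df = NA, p = NA,
                      mean_koram = NA, lo_koram = NA, hi_koram = NA,
                      mean_nomsao = NA, lo_nomsao = NA, hi_nomsao = NA,
                      overlap = NA, skipped = TRUE,
                      reason = cmp$skip_reason, stringsAsFactors = FALSE))
  data.frame(what = cmp$what, taxon = cmp$taxon, n_koram = cmp$n[1],
             n_nomsao = cmp$n[2], statistic = cmp$test$statistic,
             df = cmp$test$df, p = cmp$test$p_value,
             mean_koram = cmp$ci_koram$point, lo_koram = cmp$ci_koram$lower,
             hi_koram = cmp$ci_koram$upper, mean_nomsao = cmp$ci_nomsao$point,
             lo_nomsao = cmp$ci_nomsao$lower, hi_nomsao = cmp$ci_nomsao$upper,
             overlap = cmp$overlap, skipped = FALSE, reason = NA,
             stringsAsFactors = FALSE)
}

#' Run the full two-island analysis pipeline
#'
#' Loads or simulates the survey dataset, then runs every stage for which
#' the required tables are present: tool-weight models (with optional
#' permutation companions), prey-size comparisons per taxon, snail
#' availability per species, stone supply, maturation models, and the
#' depletion table. Stages whose inputs are missing are skipped with a
#' logged reason; a stage error is recorded in the manifest and the
#' remaining stages still run. Re-running with the same config writes
#' byte-identical outputs.
#'
#' @param config A [pipeline_config()] or path to a YAML config.
#' @param out_dir Output directory for result CSVs and `manifest.json`;
#'   `NULL` skips writing.
#' @return Invisibly, a list with `dataset`, `results`, `stages`, `errors`
#'   and `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  seed <- stream_seed(config$seed, "pipeline")

  if (!is.null(config$simulation)) {
    ds <- generate_dataset(config$simulation)
    sc <- generate_consumption_scenario()
    ds$island_profiles <- sc$profiles
    ds$consumption_rates <- sc$rates
  } else {
    ds <- read_survey_tables(config$paths)
  }

  bundle <- list(dataset = ds, results = list(), stages = list(),
                 errors = list())

  if (!is.null(ds$tools)) {
    bundle <- stage_try(bundle, "tools_oyster_lmm",
                        fit_oyster_tool_lmm(ds$tools))
    bundle <- stage_try(bundle, "tools_snail_lm", fit_snail_tool_lm(ds$tools))
    if (config$run_permutations) {
      bundle <- stage_try(bundle, "tools_oyster_permutation",
        permutation_island_test(
          ds$tools[ds$tools$task == "oyster", ],
          function(d) suppressWarnings(fit_oyster_tool_lmm(d))$statistic,
          n_perm = config$n_perm, unit = "individual", seed = seed + 1))
      bundle <- stage_try(bundle, "tools_snail_permutation",
        permutation_island_test(
          ds$tools[ds$tools$task == "snail", ],
          function(d) fit_snail_tool_lm(d)$statistic,
          n_perm = config$n_perm, unit = "record", seed = seed + 2))
    }
  } else bundle$stages$tools <- "skipped: no tools table"

  if (!is.null(ds$prey_sizes)) {
    taxa <- intersect(prey_taxa(), unique(ds$prey_sizes$taxon))
    bundle <- stage_try(bundle, "prey_sizes", lapply(
      stats::setNames(taxa, taxa), function(tx)
        compare_prey_sizes(ds$prey_sizes, tx, n_boot = config$n_boot,
                           level = config$ci_level, seed = seed + 10)))
  } else bundle$stages$prey_sizes <- "skipped: no prey_sizes table"

  if (!is.null(ds$snail_transects)) {
    sps <- intersect(snail_species(), unique(ds$snail_transects$species))
    bundle <- stage_try(bundle, "availability", lapply(
      stats::setNames(sps, sps), function(sp)
        compare_availability(ds$snail_transects, sp, n_boot = config$n_boot,
                             level = config$ci_level, seed = seed + 20)))
  } else bundle$stages$availability <- "skipped: no snail_transects table"

  if (!is.null(ds$stone_quadrats)) {
    bundle <- stage_try(bundle, "stone_supply",
      compare_stone_supply(ds$stone_quadrats, n_boot = config$n_boot,
                           level = config$ci_level, seed = seed + 30))
  } else bundle$stages$stone_supply <- "skipped: no stone_quadrats table"

  if (!is.null(ds$maturation)) {
    bundle <- stage_try(bundle, "maturation", fit_maturation_lm(ds$maturation))
  } else bundle$stages$maturation <- "skipped: no maturation table"

  if (!is.null(ds$island_profiles) && !is.null(ds$consumption_rates) &&
      !is.null(ds$snail_transects)) {
    bundle <- stage_try(bundle, "depletion",
      depletion_table(ds$island_profiles, ds$consumption_rates,
                      ds$snail_transects, species = config$depletion_species,
                      density_decimals = config$density_decimals))
  } else bundle$stages$depletion <-
      "skipped: needs island_profiles + consumption_rates + snail_transects"

  bundle$manifest <- list(
    package_version = as.character(utils::packageVersion("shellforage")),
    seed = config$seed, derived_seed = seed, n_perm = config$n_perm,
    n_boot = config$n_boot, ci_level = config$ci_level,
    row_counts = lapply(Filter(Negate(is.null), unclass(ds)), nrow),
    stages = bundle$stages,
    errors = bundle$errors)

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    fits <- Filter(function(x) inherits(x, "fit_result"), c(
      bundle$results[c("tools_oyster_lmm", "tools_snail_lm")],
      bundle$results$maturation))
    if (length(fits))
      utils::write.csv(fit_results_table(fits, seed = config$seed),
                       file.path(out_dir, "model_results.csv"),
                       row.names = FALSE)
    cmps <- c(bundle$results$prey_sizes, bundle$results$availability)
    if (length(cmps))
      utils::write.csv(do.call(rbind, lapply(cmps, comparison_row)),
                       file.path(out_dir, "group_comparisons.csv"),
                       row.names = FALSE)
    if (!is.null(bundle$results$depletion))
      utils::write.csv(bundle$results$depletion,
                       file.path(out_dir, "depletion.csv"), row.names = FALSE)
    jsonlite::write_json(bundle$manifest,
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  if (length(bundle$errors))
    warning("pipeline finished with stage error(s): ",
            paste(names(bundle$errors), collapse = ", "), call. = FALSE)
  invisible(bundle)
}
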