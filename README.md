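# shellforage

Comparative analysis of tool-assisted shellfish foraging between a
high-predation and a low-predation island, for field primatologists and
intertidal ecologists. Two neighbouring islands host stone-tool-using
macaque groups of very different sizes; because the islands share growth
conditions, between-island contrasts in tool weights, prey sizes, prey
availability and prey maturation isolate the effect of predation pressure.
The package implements the full pipeline: typed survey tables, a
synthetic-data generator with the study's dependence structure,
cluster-level permutation tests and percentile bootstraps, the tool-weight
mixed model with likelihood-ratio tests and stability diagnostics, and a
consumption-extrapolation depletion model with a life-history
vulnerability assessment.

## The models at the core

Oyster-tool weights (repeated measures per tool user *i*):

    sqrt(w_ij) = mu + E * [island = NomSao] + b_i + e_ij,   b_i ~ N(0, s_b^2)

fitted by maximum likelihood, with the island effect `E` tested by a
likelihood-ratio chi-square against the island-free model, and by a
permutation companion that relabels islands at the level of whole
individuals. Snail-tool weights use `log(w) ~ island` by OLS with the
F-form LRT. Group contrasts (prey size, per-plot availability, stone
supply) pair Welch *t*-tests with percentile-bootstrap 95% CIs.

The depletion model extrapolates per-capita consumption to the tool-using
cohort and divides by the standing population estimated from point
transects:

    area = shoreline x 3 m        density = total count / n plots
    standing = density x area     annual  = rate x users x 365
    depletion ratio = annual / standing    (years to depletion = 1/ratio)

A ratio above 1 means one year of foraging would exhaust the current stock
absent replenishment.

## Worked example

```r
library(shellforage)

# simulate the reference study design (93/93 oyster tools from 14/4
# individuals, 45/22 snail tools, 14 transects per island)
ds  <- generate_dataset(simulation_config(seed = 42))
fit <- fit_oyster_tool_lmm(ds$tools)
fit
#> oyster_tool_lmm [sqrt scale, N = 186]: E = 1.692, SE = 0.594,
#>   chi^2 = 6.445, df = 1, p = 0.01113
```

The planted island effect (+1.73 on the sqrt-gram scale: NomSao tools are
heavier) is recovered as 1.69 +/- 0.59, and the LRT rejects at p = 0.011.
The depletion table uses the published island profiles, the observed
per-individual consumption rates and the transect totals (181 periwinkles
on Koram, 568 on NomSao, 14 one-square-metre plots each):

```r
sc <- generate_consumption_scenario()   # 1551 m / 26 users, 653 m / 4 users
tr <- rbind(
  data.frame(island = "Koram",  transect_index = 1:14,
             species = "P_sulcatus", count = c(rep(13, 13), 12)),
  data.frame(island = "NomSao", transect_index = 1:14,
             species = "P_sulcatus", count = c(rep(41, 8), rep(40, 6))))
depletion_table(sc$profiles, sc$rates, tr)
#>   island    species area_m2 density_per_m2 standing_population
#> 1  Koram P_sulcatus    4653          12.93               60163
#> 2 NomSao P_sulcatus    1959          40.57               79477
#>   annual_consumption depletion_ratio years_to_depletion
#> 1              60736          1.0095             0.9906
#> 2               9344          0.1176             8.5057
```

Koram's 26 tool users would consume slightly more periwinkles in a year
(60,736) than the island currently holds (60,163; ratio 1.01), while
NomSao's four users take just over a tenth of their stock. The
vulnerability mapping classifies both main prey species as mixed — easily
harvested because highly aggregated, but replenished by planktonic larvae:

```r
assess_vulnerability(builtin_life_histories()$tropical_periwinkle)
#> tropical_periwinkle: mixed
#>   aggregation          slow_recovery
#>   size_at_maturity     fast_recovery
#>   reproductive_output  slow_recovery
#>   larval_mode          fast_recovery
```

`run_pipeline(pipeline_config(simulation = simulation_config()), out_dir =
"out")` executes every stage and writes result CSVs plus a JSON manifest;
a YAML-driven shell wrapper lives in `inst/scripts/shellforage.R`.

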