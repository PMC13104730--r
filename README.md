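# illfit

Estimation of the **incipient limiting level (ILL)** — the food
concentration above which a fitness trait no longer increases — from
per-individual zooplankton life-history records collected along a food
gradient. Built for experimental aquatic ecologists comparing *Daphnia*
clonal lineages (or species, or treatments) in standardized feeding
experiments, where the question is: *at what algal concentration does
growth saturate, at what level does it reach zero, and do genotypes differ?*

## What it computes

From a records table (one row per animal: clone, nominal food
concentration in mg C L⁻¹, initial/final dry mass, age at first
reproduction, clutch size, survival flag) the pipeline derives two traits:

* somatic growth rate, `g = (ln M_t − ln M_0) / t` (day⁻¹);
* early-life intrinsic rate of increase `r`, solving the Euler–Lotka
  equation restricted to the first reproductive event,
  `1 = exp(−r·x) · l_x · m_x`, numerically per individual (stratum-level
  survival `l_x`, individual age `x` and clutch `m_x`).

Each clone's trait–food relationship is then fitted with a
three-parameter **quadratic-plateau** curve

```
y(x) = b0 + b1·x + b2·x²   for x ≤ cx,      b2 = −b1/(2·cx)
y(x) = b0 + b1·cx/2        for x > cx
```

(`cx` = ILL; the quadratic term is derived so the curve joins its plateau
with zero slope), plus a piecewise-linear **hockey-stick** alternative for
robustness. Derived quantities: plateau elevation (predicted response at
the ILL) and the **threshold food level (TFL)**, the curve's x-intercept.
Uncertainty comes from a nonparametric stratified bootstrap (default 1000
resamples, 95% percentile intervals; observations resampled within clone ×
concentration strata for `g`, individuals resampled with survival and `r`
recomputed for `r`), and clones are ordered by strict confidence-interval
separation (`A < B` only if A's upper bound is below B's lower bound).

A synthetic-data generator (`generate_dataset()`) reproduces the standard
experimental layout — 4 clones × 12 concentrations (0.0125–4.5 mg C L⁻¹) ×
10 replicates, 480 individuals — with known ground-truth curves, so every
stage is testable without external data.

## Worked example

```r
library(illfit)

cfg <- pipeline_config(traits = "g", models = "quadratic_plateau",
                       n_resamples = 200, seed = 1)
res <- run_pipeline(cfg)
res$results[, c("clone_id", "ill", "ill_lower", "ill_upper", "plateau", "tfl")]
#> # A tibble: 4 × 6
#>   clone_id   ill ill_lower ill_upper plateau    tfl
#>   <chr>    <dbl>     <dbl>     <dbl>   <dbl>  <dbl>
#> 1 B2       0.776     0.738     0.821   0.419 0.0244
#> 2 B3       0.647     0.599     0.694   0.393 0.0305
#> 3 D2       0.987     0.943     1.04    0.491 0.0370
#> 4 D4       1.12      1.04      1.23    0.383 0.0375
res$orderings$ordering[res$orderings$statistic == "ill"]
#> [1] "B3 < B2 < D2 = D4"
```

This is the synthetic default run (truth ILLs 0.74, 0.65, 1.02, 1.05
mg C L⁻¹): each fitted ILL lands within a few hundredths of its truth and
the ordering separates the low-saturating pair from the high-saturating
pair — the pattern of interest in clone-comparison experiments. TFLs near
0.02–0.04 mg C L⁻¹ are the concentrations at which predicted growth
crosses zero (slightly below the generating truths of 0.04–0.06, a known
small bias from the generator's truncation of negative true growth rates —
see the vignette).

To analyse real data instead, point the config at a CSV in the documented
schema (`clone_id, concentration_mgC_per_L, initial_mass_ug, final_mass_ug,
age_first_repro_d, clutch_size, survived`):

```r
res <- run_pipeline(pipeline_config(input_path = "records.csv", seed = 1))
write_results(res, "results/")
```

A thin command-line wrapper lives at `inst/scripts/illfit.R`
(`simulate` and `fit` subcommands). The methods vignette
(`vignettes/illfit-methods.Rmd`) documents the models, the bootstrap
schemes, the generator's assumptions and all numerical choices.

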