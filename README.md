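# forestaudit

Remote-sensing audits of additionality for improved forest management (IFM)
carbon-offset projects.

IFM projects are credited against a static business-as-usual baseline: a
large first issuance for initial carbon stocking above the baseline, then
annual issuances for incremental accumulation. Whether that carbon is
*additional* — beyond what the forest would have stored anyway — rests on an
unobserved counterfactual. Annual 30 m maps of aboveground live (AGL)
carbon and of binary harvest disturbance allow an independent check:
compare project lands to spatial control groups, before and after each
project's start (a before-after-control-impact design).

`forestaudit` is for researchers and offset-program analysts who want that
audit as tested, reproducible code. It provides:

* **Spatial controls** — 2 km surrounding buffers (exclusion of
  urban/agricultural, public, and other-project pixels), regional pools of
  private forest, and covariate-matched pixel sets: covariates (mean annual
  temperature, precipitation, site productivity class) block-aggregated to
  800 m, z-scored over the region, and ranked by Mahalanobis distance from
  the project mean, selecting n pixels to match project area.
* **The statistical core** — OLS trends with percent rates
  (`100 * slope / period-mean stock`), paired t tests across years, Chow
  structural-break tests
  `F = [(RSS_p − RSS_1 − RSS_2)/k] / [(RSS_1 + RSS_2)/(n_1 + n_2 − 2k)]`
  with k = 2, equal before/after windows around each start year, species
  composition contrasts (carbon-weighted fractions), and area-weighted
  portfolio aggregation with cross-project standard errors.
* **Crediting arithmetic** — CO2/C molar conversion (12.01/44.01), the
  0.806 AGL-of-total convention, 0.47 ton C per ton biomass, reported
  accumulation rates, and the initial-to-annual credit ratio, which equals
  the break-even time in years for incremental credits to match the
  initial payout.
* **A five-hypothesis audit** (`run_audit()`) producing per-project and
  portfolio verdicts: pre-project carbon trend (H1), pre-project harvest
  (H2), low-timber-value species composition (H3), post-project change in
  carbon slope (H4, Chow) and in harvest (H5, paired t) — each mapped to
  consistent-with-additionality / inconsistent / inconclusive.
* **A synthetic-landscape generator** (`generate_scene()`) with known
  ground truth: two-region logistic stand dynamics with calibrated net
  growth (+1.05 %/yr coastal analogue, ~0 interior), patchy Poisson
  harvest with logistic recovery, a saturating measurement model
  (underestimation above 210 ton C/ha), species layers, biased project
  placement, injected management effects, and fabricated crediting
  documents with configurable reporting inflation.

Raster stacks are read and written as ESRI ASCII grids with JSON sidecars,
polygons as GeoJSON, documents as CSV — all plain text.

## Worked example

```r
library(forestaudit)

scene <- generate_scene(landscape_config(rng_seed = 42))
scene
#> <synthetic_scene> 160x160 pixels, 36 years (1986-2021), 6 projects

report <- run_audit(scene, audit_config())
summary(report)
#> == buffer controls ==
#> H1: project 0.84 %/yr vs control 0.92 %/yr (p = 1.09e-14) -> inconsistent
#> H2: harvest diff 0.001284 (9% of control), p = 0.361 -> inconclusive
#> H3: tanoak 19.3% vs 19.6%, p = 0.836 -> inconclusive
#> H4: slope change -0.953 (control -0.225), p = 0.513 -> inconclusive
#> H5: harvest change +0.0005684 (control +0.001142), p = 0.846 -> inconclusive
#> ...

credit_summary(scene$projects[[1]])
#> <credit_summary> initial 10253, incremental 221.5/yr, ratio 46.3, break-even 46.3 yr
```

Read this as an audit of a business-as-usual landscape: projects accumulate
carbon at 0.84 %/yr before they start — significantly positive, so a flat
baseline would over-credit (H1 `inconsistent`) — and no hypothesis finds
evidence of changed management, because none was simulated. The credit
summary says this project's first issuance was 46 times its annual
incremental issuance: at current growth it would take 46 years for
incremental credits to overtake the initial payout.

Injecting real effects flips the post-project hypotheses:

```r
cfg <- landscape_config(effect_injection = c("stop_harvest", "growth_boost"),
                        project_start_years = rep(2010L, 6), rng_seed = 42)
report <- run_audit(generate_scene(cfg),
                    audit_config(control_methods = "region",
                                 pre_period = c(1986L, 2009L)))
report$hypotheses$region$H4$verdict
#> [1] "consistent-with-additionality"
```

## Not in scope

Producing the input rasters (disturbance attribution, nearest-neighbor
imputation, allometry), leakage and secondary effects, harvested-wood
products, and fire/drought attribution. The audit quantifies consistency
with additionality against imperfect spatial counterfactuals; it does not
prove additionality.
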