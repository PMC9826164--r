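---
title: "Auditing forest carbon offset additionality with spatial controls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing forest carbon offset additionality with spatial controls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forestaudit)
```

## The problem

Improved forest management (IFM) offset projects earn credits against a
static business-as-usual baseline: a project is paid once for its initial
carbon stocking above the baseline and annually thereafter for incremental
accumulation. Whether those credits represent *additional* climate benefit
depends on a counterfactual — what the forest would have done without the
program — that the crediting protocol never observes. Annual remote-sensing
maps of aboveground live (AGL) carbon and of harvest disturbance make an
independent audit possible: compare each project's carbon accumulation,
harvest rate and species composition against spatial control groups, before
and after the project started (a BACI design).

`forestaudit` implements that audit end to end and pairs it with a
synthetic-landscape generator with known ground truth, so that every stage —
zonal extraction, control construction, the statistical tests, and the
verdict logic — is testable without multi-gigabyte external rasters.

## The audit design

Five hypotheses distinguish an additional portfolio from a non-additional
one:

* **H1 — pre-project carbon trend.** If the flat baseline is realistic,
  historical accumulation should be near zero. A significantly positive
  pre-project trend (in % of the period-mean stock per year) is evidence
  against additionality.
* **H2 — pre-project harvest.** Projects harvested *more* than comparable
  lands before enrollment are plausibly earning credits for stands already
  recovering.
* **H3 — species composition.** Projects concentrated on low-timber-value
  species (tanoak, as against redwood or Douglas-fir) face little harvest
  risk, undermining avoided-degradation claims.
* **H4 — post-project change in carbon accumulation.** Additional management
  should raise the accumulation rate relative to the pre-project rate and to
  controls; tested with a Chow structural-break F on equal windows around
  the start year.
* **H5 — post-project change in harvest.** Additional management should
  lower harvest relative to before and to controls; tested with a paired t
  on year-offset pairs across equal windows.

Each hypothesis maps to a three-way verdict: an effect in the additional
direction with `p < alpha` is `consistent-with-additionality`; a significant
effect in the opposite direction is `inconsistent`; anything else is
`inconclusive`. The package deliberately reports the five verdicts
separately — any combined "additionality score" would be a convention of the
analyst, not of the data.

Three control systems are built per project:

1. **buffer** — all private-forest pixels within 2 km of the project
   boundary, excluding urban/agricultural and public land and every other
   project's interior;
2. **region** — the pool of all private forest in the project's region
   (coastal vs interior), optionally including project pixels to reproduce
   region-wide curves;
3. **matched** — the `n` pixels of the project's region closest to the
   project's mean covariates (mean annual temperature, precipitation, site
   productivity class) in Mahalanobis distance, computed on a grid block-
   aggregated to the matching resolution (800 m by default), with `n`
   chosen to match the project's area.

Covariates are z-scored over the region's candidate pixels and the
Mahalanobis metric uses the covariance of those standardized covariates; the
interaction between standardization and the metric is underdetermined in
practice, and this choice makes matching invariant to affine rescaling of
any covariate (a property the test suite asserts). Ties in distance break
deterministically by pixel index. A singular covariance falls back to its
diagonal with a warning.

## Statistical choices

* **Percent growth rate** is `100 * slope / period-mean stock`. The
  alternative denominator (the fitted initial-year stock) is available via
  `percent_denominator = "initial"`; the period mean is the default because
  it reproduces the canonical coastal arithmetic (a 1.30 ton C/ha/yr trend
  on a 123.0 ton C/ha mean stock is 1.06 %/yr).
* **Chow test** uses the classic F with k = 2 (intercept and slope) and
  `(k, n1 + n2 - 2k)` degrees of freedom; heteroskedasticity-robust variants
  are out of scope. The test assumes serially independent residuals around
  piecewise-linear trends — see the generator notes below for what this
  implies.
* **Paired t across years** works on per-year differences (not ratios);
  relative differences are reported as percent of the control mean.
  Zero-variance differences are flagged degenerate rather than assigned
  `p = 0`: identical series yield `t = 0, p = 1`.
* **Equal windows**: a project starting in year `s` with carbon data to
  2017 and harvest data to 2021 gets a `w = 2017 - s` carbon window and
  `w = 2021 - s` harvest window (each also capped by the pre-start record),
  with at least 3 carbon and 7 harvest post-start years required; projects
  below the floor are excluded with an explicit reason, never silently.
* **Portfolio aggregation** weights per-year means by project area, but the
  cross-project standard error is the unweighted SE across the sample of
  projects, so that the reported uncertainty reflects the sample of
  projects rather than the area distribution.
* No multiple-testing correction is applied across the five hypotheses; a
  Benjamini–Hochberg adjustment would be an extension, not part of the core
  design.

## The synthetic landscape

`landscape_config()` describes a miniature two-region analogue of a
northern-California forest landscape on a 160 x 160 grid of 30 m pixels
(2 304 ha), simulated annually over 1986–2021:

* **Regions.** The western half is a "coastal" analogue (wet, productive,
  initial biomass 260 ton/ha ~ 122 ton C/ha, net carbon growth target
  +1.05 %/yr); the eastern half an "interior" analogue (drier, 110 ton/ha ~
  52 ton C/ha, target +0.1 %/yr). Covariates are smooth west–east gradients
  plus spatially correlated noise, so covariate matching is non-trivial.
* **Stand dynamics.** Per-pixel logistic growth toward a 700 ton/ha carrying
  capacity with multiplicative lognormal pixel noise (sd 1 %/yr) and a small
  shared region-year growth shock (sd 0.2 %/yr). Harvest multiplies biomass
  by a retention fraction (0.15); recovery follows the logistic with a rate
  set by a 25-year half-life while a stand is below half its regional
  initial biomass.
* **Calibration.** The configured growth rate is a *net* regional target.
  Logistic drag, spatial heterogeneity (the logistic is concave, so a
  lognormal spread of initial biomass lowers the mean rate) and harvest
  losses all pull the realized rate away from the intrinsic rate, so the
  intrinsic rate is calibrated by root-finding on a deterministic cohort
  model (lognormal quantile cohorts; expected harvest fraction pooled into
  one new cohort per year). Realized regional percent growth lands within
  ±0.3 %/yr of the target, and the coastal default realizes 1.0–1.1 %/yr.
* **Harvest.** Square 3 x 3-pixel patches with Poisson counts per region and
  year, expected area fraction 1.2 %/yr (coastal) and 1.8 %/yr (interior).
  The landscape is a scaled-down analogue — real projects average tens of
  km² — so patch and project areas are scaled together rather than using
  realistic absolute clearcut sizes. Year-to-year harvest variability is
  a consequence of the Poisson patch process; no additional variance
  parameter is asserted.
* **Measurement model.** Observed carbon equals true carbon below a 210
  ton C/ha onset and compresses increments by a factor 0.5 above it
  (piecewise linear, monotone), mimicking the high-density underestimation
  of Landsat-based biomass products. A shared region-year observation
  shock (sd 1 %) is applied to the observed stack only. This split matters:
  observation noise is serially independent, which is what the Chow
  framework assumes, whereas growth-process shocks integrate into the
  carbon level and would masquerade as structural breaks. Real
  remote-sensing series sit somewhere between those extremes, so the
  calibration demonstrated here is a best case; the observed stack is
  capped at the true value above the onset so the saturating sensor never
  reads high.
* **Projects.** Six rectangular projects (30–90 ha; four coastal, two
  interior; interior ones owned by the large-timber class) are placed on
  private forest via exact enumeration of feasible positions. Placement
  bias modes reproduce the strategic-selection patterns the audit is meant
  to catch: `recently_harvested` places large-timber projects on the most
  harvested candidate rectangles, `low_value_species` places projects on
  high-tanoak stands. Effect injection (`stop_harvest`, `growth_boost`)
  switches real management effects on inside project polygons after each
  start year.
* **Documents.** Reported stocks start from the measured (true zonal) AGL
  stock and accumulate at `reporting_inflation` times the measured rate;
  half the projects report total carbon (converted by the 0.806 AGL
  convention). Credits are issued in tCO2e via the 12.01/44.01 molar ratio:
  first the initial-above-baseline stocking (baseline defaults to 80 % of
  the initial stock), then annual incremental issuances.

What the generator does *not* emulate: fire and drought disturbance and
their attribution, spectral/radiometric detail, leakage and harvested-wood
products, landowner economics, and spatially autocorrelated measurement
error within a region-year. A passing audit on synthetic scenes therefore
shows the machinery is correct and calibrated under its stated assumptions,
not that real eMapR/LEMMA series satisfy those assumptions.

## Numerical conventions

* Grids are row-major with `(row, col)` indexing; the affine transform maps
  pixel centers, and a pixel belongs to a polygon iff its center is covered
  (even-odd rule). Masks are half-open on grid edges.
* 30 m to 800 m regridding uses the nearest integer factor (27, i.e.
  810 m cells) with block means; a coarse cell is missing when fewer than
  50 % of its fine cells are valid, and trailing partial blocks are
  dropped. Zonal statistics use valid pixels only; a region-year below 50 %
  valid is reported missing, never zero.
* Raster stacks are stored as one ESRI ASCII Grid per year plus a JSON
  sidecar (year range, CRS, units, nodata); polygons as GeoJSON; documents
  as CSV. Values round-trip exactly for integer data and within 1e-6 for
  floats.
* All randomness flows from `rng_seed`; identical config and seed reproduce
  a scene bit-for-bit, and `run_audit()` itself is deterministic.

## Scale of the shipped experiments

The test suite and the acceptance script exercise the pipeline at sizes a
reviewer can run on one CPU: 2 000 replicates for the type-I calibration of
the Chow and paired tests (empirical rejection 0.05 ± 0.02 at alpha = 0.05),
and 200 synthetic scenes per arm for effect recovery. In the recovery
scenario all six projects start in 2010, giving 7-point carbon windows and
11-point harvest windows; with a +0.5 ton C/ha/yr growth boost and harvest
cessation injected, the portfolio H4 and H5 verdicts flip to
consistent-with-additionality in well over 80 % of scenes, while without
injection they do so in under 10 %. Detection is defined at the portfolio
level: the pooled offset-aligned Chow (H4) or paired test (H5) must be
significant in the additional direction *and* exceed the controls' change,
mirroring the hypothesis definitions.

## Known limitations

* The audit's verdicts inherit the power of small windows: with only 3
  post-start carbon years (the 2014-start cohort), per-project Chow tests
  are weak, and lumpy harvest inside short windows inflates segment RSS.
  This is a property of the design being audited, not of the
  implementation.
* Matched controls on the default miniature landscape aggregate 160 pixels
  by factor 27, leaving a 5 x 5 coarse grid — usable, but matching is more
  meaningful at the scales of real data or with a smaller
  `match_resolution`.
* Buffer distances are Euclidean in the projected CRS; no geodesic
  correction is attempted.
* The spatial controls are approximations of a counterfactual; nothing in
  the statistics can rule out that project lands would have diverged from
  controls absent the program. The audit quantifies consistency with
  additionality, not additionality itself.
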