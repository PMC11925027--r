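---
title: "A patient-level model of bioprosthetic aortic valve failure and its transcatheter treatment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A patient-level model of bioprosthetic aortic valve failure and its transcatheter treatment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vivforecast)
```

## The question

Tissue (bioprosthetic) aortic valves degenerate structurally after roughly
a decade. As transcatheter aortic valve replacement (TAVR) displaces
surgical replacement (SAVR) and moves into younger, lower-risk patients,
a growing share of patients will outlive their first valve and present
for a second intervention — usually a transcatheter valve implanted
inside the failed one (valve-in-valve, ViV). `vivforecast` projects
annual US ViV volumes, split into TAVR-in-SAVR and TAVR-in-TAVR, through
2035.

## Model structure

The model is a cohort-seeded microsimulation. Every year's implant volume
of each procedure class seeds that many synthetic patients; each patient
is carried forward independently:

1. **Age at index** — discrete distribution on 60–95.
2. **Surgical-risk class** — Bernoulli draw with an era- and
   class-specific low-risk fraction. Risk class only selects the survival
   distribution.
3. **Valve durability** — mixture of normals truncated to strictly
   positive values. TAVR failure is bimodal: a 20% early-failure mode at
   4 ± 1.5 years and an 80% late mode at 11.5 ± 3.5 years. SAVR
   durability is age-stratified: 10 ± 5 years when implanted before age
   70, 17 ± 5 years at 70 or older (younger patients stress the valve
   more).
4. **Post-procedure survival** — normal, parameterised by its median
   (= mean, symmetric family), truncated positive, and capped so no
   patient exceeds attained age 100. Intermediate-to-high risk: median 6,
   SD 2.
5. **Competing risk** — the patient enters the ViV candidate pool only if
   durability < survival; otherwise they die with a functioning valve and
   leave the model. The failure calendar year is the index year plus the
   floored durability.
6. **Redo surgery** — annual counts of surgical re-replacement
   (SAVR-after-SAVR, SAVR-after-TAVR) are subtracted from the matching
   candidate pools before the transcatheter treatment decision, clamped
   at zero.
7. **Penetration** — each remaining candidate is treated with the year's
   penetration probability for its failure type, as an independent
   Bernoulli draw. Untreated candidates leave the model (no queueing),
   and treated ViV implants are not re-entered as new index TAVR (no
   third interventions).

A replicate ensemble (default 20) repeats the whole simulation with
independent streams; reported curves are per-year sample means with n−1
sample SDs. With one replicate the SD is reported as 0 by convention.

## Parameters and their provenance

| Parameter | Default | Status |
|---|---|---|
| TAVR durability mixture | 0.2·N(4, 1.5²) + 0.8·N(11.5, 3.5²) | published |
| SAVR durability (<70 / ≥70) | N(10, 5²) / N(17, 5²) | published |
| Intermediate-high survival | median 6, SD 2 | published |
| Low-risk survival | median 12, SD 4 | **assumption** |
| Age distribution | discretized N(77, 7²) on [60, 95] | **assumption** (support published) |
| SAVR risk mix | 85% low / 15% intermediate-high | published |
| TAVR risk mix eras | 0% low to 2019; 1/3 2019–2023; 50% from 2024 | published |
| Penetration, TAVR failures | 10% to 2022 → 60% in 2035, linear | published anchors |
| Penetration, SAVR failures | 60% to 2022 → 80% in 2035, linear | published anchors |
| SAVR volume 2021–2035 | constant 50,000/yr | published |
| TAVR volumes 2012–2022 | registry series (2020–2022 approximated) | fixture, cited in CSV header |
| SAVR volumes 1998–2011 | linear 16,000 → 42,000 | **assumption** |
| Total surgical AVR 2012–2020, ×0.8 bioprosthetic | fixture | approximation |
| Redo series | linear trends, see `inst/extdata/redo_series_us.csv` | **assumption** |
| Replicates | 20 | published |

Flagged assumptions fill quantities whose sources do not print usable
numbers; each lives in one configuration field and can be overridden from
YAML without code changes (`load_config()` merges any subset of keys over
the defaults). The low-risk survival default (median 12, SD 4) is the
single most consequential assumption: it controls how many of the large
low-risk TAVR cohorts of the 2020s survive to their late failure mode.

Era boundaries that share endpoint years (2019, 2024) are half-open
`[from, to)`, so each year is assigned exactly once; TAVR seeding years
before 2014 use 100% intermediate-to-high risk. "Progressive increase" of
penetration is read as linear interpolation between anchors, constant
outside them — the simplest monotone reading.

## Numerical choices

- **Truncation by rejection.** Durability and survival redraw the whole
  (component, variate) pair while non-positive, i.e. the *mixture* is
  truncated; the sampled CDF is `(G(x) − G(0))/(1 − G(0))` (`ptruncmix()`),
  which is also the closed form the tests check against. At the default
  parameters the truncated mass is below 2.5%, so printed means/medians are
  preserved to well under 0.3 years (the tests quantify this exactly).
- **Failure-year assignment** uses `floor(durability)` — the failure
  happens *within* that calendar year; `"round"` is available as a
  sensitivity switch (`failure_year_rule`).
- **Order of exclusions**: redo subtraction precedes penetration (redo
  patients are removed from the pool before the treatment decision);
  `redo_before_penetration = FALSE` exposes the alternative order.
- **Bernoulli thinning** (one uniform per candidate, consumed in year
  order) rather than rounding of expectations, so ensemble SDs are
  meaningful and, under common random numbers, raising the penetration
  schedule can never lower a treated count.
- **Random streams** are keyed: a 31-bit sub-seed is derived from the
  master seed and (replicate, seeding year, procedure class) — or
  (replicate, failure type) for thinning — by an iterated congruential
  mix that is exact in doubles. Adding years or replicates never perturbs
  the draws of existing units, and every run is bit-reproducible from
  (configuration, master seed).
- **Counts are integers**; fitted-line volumes round half-to-even and
  clamp at zero.
- **"All TAVR" denominator** for the ViV share is native index TAVR plus
  the ViV TAVR of that year; the seeded series is interpreted as
  native-only (avoiding double-seeding of ViV recipients). The
  alternative reading is available via `series_includes_viv = TRUE`.
- **"Nearly match"** is operationalised as the first year TAVR-in-TAVR
  reaches 90% of TAVR-in-SAVR in ensemble means; the strict (100%)
  crossover is reported alongside. Years where mean TAVR-in-TAVR is zero
  cannot qualify.

## The synthetic-data generator

`synthesize_scenario()` emits paired volume series so every stage is
testable without registry access: `tiny-deterministic` (hand-countable
cohorts used by the brute-force oracle tests), `linear-growth`
(configurable slope/intercept), and `paper-scale` (the packaged US
construction). The generator reproduces the *structure* of real volume
series — contiguous years, integer counts, linear trends, the 50,000
plateau — but none of the year-to-year irregularity of real registries
(approval shocks, COVID dips are present only insofar as the observed
fixture contains them). Passing tests therefore demonstrate correctness
of the machinery under the stated assumptions, not registry-grade
calibration of the inputs.

## Problem sizes and runtime

The default configuration seeds ~2.5M TAVR and ~1.6M SAVR patients per
replicate (~82M patient draws over 20 replicates), which runs in about
40 s on one core. The test suite exercises degenerate scenarios
(hundreds of patients), distribution checks at 10⁵ draws, and one full
default ensemble shared across the end-to-end checks.

## Limitations

- Headline reproduction is calibration-sensitive: the registry volume
  series behind the published model are not printed, so the packaged
  fixtures are documented approximations and the 2035 totals shift with
  them (roughly proportionally for TAVR-in-TAVR).
- No TAVR expansion below age 60, no third interventions
  (TAVR-in-TAVR-in-TAVR), no procedural mortality of the ViV itself, no
  queueing of untreated failures, no geographic or anatomic
  stratification — all outside the model's scope.
- Ensemble SD measures Monte Carlo dispersion under fixed parameters,
  not structural or parameter uncertainty; parameter sensitivity should
  be explored by editing the YAML configuration.
- The model crosses TAVR-in-TAVR over TAVR-in-SAVR in the
  mid-2020s under the default fixtures, a year or three before the
  published figure's "nearly match in 2028"; the crossover timing is
  sensitive to the assumed redo-surgery trend and the TAVR volume
  fixture, and the tests assert only the "by 2028" bound.
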