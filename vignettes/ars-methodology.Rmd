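---
title: "Scoring climate-induced downside risk with Annual Risk Scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring climate-induced downside risk with Annual Risk Scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Classical risk analysis of crop production looks at the distribution of
end-of-season outcomes — yields or gross margins — and summarises it with
means and variances. Farmers, however, perceive climatic risk *during* the
season: a thin canopy in March, a dry profile in May, a cold spell around
anthesis. `arscore` models this mid-season perception process for an
autumn-sown cereal (winter wheat is the reference crop) and aggregates it
into a single planning-relevant number per season, the **Annual Risk Score
(ARS)**.

The anchor of the whole construction is the **still-good yield (sgy)**: the
lowest yield a grower still considers economically acceptable, elicited by
survey together with the peak yield (py) and the farm's average yield
(avy). The band `wta = py - sgy` is the grower's willingness to accept
downside fluctuation. Everything below sgy is downside risk; everything at
or above it is acceptable. No prices enter anywhere — profitability is
expressed entirely in yield terms, which makes the method usable where
market prices are missing or distorted.

## From simulated experience to acceptance ranges

A modelled farmer needs experience before it can judge a season. The
package builds that experience by simulation:

1. **Weather.** `generate_weather()` produces daily series from a
   sinusoidal seasonal temperature with AR(1) anomalies, a two-state Markov
   precipitation occurrence chain with exponential wet-day amounts, and a
   clear-sky radiation curve attenuated on wet days. The defaults are tuned
   to a loess hill region of Southwest Germany: long-run annual mean
   temperature inside 9–10 °C and annual precipitation inside 730–830 mm.
   Years are fixed at 365 days; calendar leap-day edge cases add nothing to
   the method.
2. **Seasons.** `simulate_season()` grows the crop day by day: thermal time
   (base 0 °C) drives a piecewise-linear BBCH phenology; biomass grows as
   radiation-use efficiency × intercepted radiation × temperature, water
   and fertilization factors; soil water is a four-layer bucket (layers to
   30/60/90/120 cm) whose daily mass balance closes to 1e-9 mm; soil
   temperature at 5/10/50 cm is a depth-damped first-order lag of air
   temperature. Three fertilizations trigger at BBCH 25/30/39 and harvest
   at BBCH 92; grain yield is generative biomass at harvest (dt/ha).
3. **The what-if grid.** `build_grid()` crosses a sowing window (default
   DOY 283–328, 46 consecutive days) with every weather year (default 30),
   producing 1,380 simulated seasons.

Each season records end-of-day snapshots at eight **observation points
(OPs)**: OP0 the sowing day itself, OP1 thirty days after sowing, OP2/4/5
the three fertilizations, OP3/OP6 fourteen days after the first and third
fertilization, OP7 the harvest. Ten parameters are observed at OP1–7: LAI,
soil water at four depths, soil temperature at three depths, biomass
(above-ground until OP6, generative at OP7), and BBCH.

`build_pool()` turns the grid into a knowledge pool. Seasons whose yield
fell below sgy are discarded — they are the outcomes the farmer wants to
avoid, so they cannot define what "normal" looks like. On the surviving
seasons, each (OP, parameter) sample is summarised by its **Tukey boxplot
whiskers**: outliers are points beyond `q1 − 1.5·IQR` or `q3 + 1.5·IQR`,
and the acceptance range is the innermost data points inside the fences.
Quartiles use linear interpolation between order statistics (R type 7);
the convention is recorded in the pool's provenance because whisker
positions depend on it. OP0 is different: its "range" is the relative
frequency with which each sowing DOY led to a yield ≥ sgy across all
(unfiltered) years.

## Scoring a season

Scoring is deliberately binary. At OP *t*, parameter *i* of crop *c* earns
a utility score α\_{i,c} of 1 if the observed value lies outside its
acceptance range (boundaries inclusive — the whisker value itself came
from an acceptable season) and 0 otherwise. The OP sum and the annual
total are

    α_{t,c} = Σ_i α_{i,c}          (per observation point)
    ARS = α_{T,c} = Σ_t α_{t,c}    (per season)

plus the OP0 term: 1 if the sowing day's historical success frequency is
below 0.5, else 0 (exactly 0.5 scores 0: "less than" is strict). With 10
parameters, 7 OPs and OP0, the maximum is 71. There is no inter-temporal
weighting of the α values, and scoring never feeds back into the simulated
management — it only observes.

Failed seasons (maturity never reached before the weather series ends)
score the full parameter count at every unreached OP. The alternative —
skipping unreached OPs — would let a season that collapses in April
out-score a completed but risky one, which inverts the intended ordering.

## Comparative analysis and adaptation

`summarize_risk()` / `compare_scenarios()` produce the
mean–standard-deviation table used for scenario comparison: yield mean, SD
(n−1 denominator), moment skewness (`m3/m2^1.5`; the estimators are stated
because different software defaults disagree), coefficient of variation,
relative frequency of yields ≥ sgy, and the mean and SD of the ARS series.
The comparison also flags scenarios where the ranking by yield SD and the
ranking by mean ARS diverge — the constellation in which mid-season
perception carries information a yield-only mean-variance analysis cannot
see (calm yield statistics can hide seasons that repeatedly left the
acceptance corridor, and vice versa).

`update_pool()` adapts the pool year on year. Three situations: an
observation inside the range from a season with yield ≥ sgy joins the value
set without shifting the range beyond re-computation; an out-of-range
observation from a ≥ sgy season is collated as a non-downside-risk value and,
as such values accumulate, shifts the whisker; a season below sgy leaves the
ranges untouched — the loss was the expected consequence of the signal. The
package keeps the below-sgy case *strictly* immutable by default (the
serialized pool is byte-identical), and folds the season's outcome into the
OP0 frequencies only when `update_op0 = TRUE` is requested; updating OP0
unconditionally would make the no-consequence case impossible to verify
exactly, and the sowing-frequency bookkeeping is a separate concern from
range perception.

`expected_ars()` and `planning_constraint()` connect scores to planning:
the expected ARS of a crop is a weighted mean of past totals (uniform by
default; exponential-decay and fixed-window schemes are provided since how
farmers weight memory is an open modelling question), and the planning rule
compares the current year's per-crop ARS sum across fields against that
expectation. The comparison direction is ambiguous when a *higher* score
means *more* risk, so both readings ship behind `mode = "literal"` /
`"inverted"` rather than silently choosing one; the per-crop aggregate is a
sum over fields, following the literal double summation of the constraint.

## Sensitivity types

`classify_sensitivity()` places each surveyed farmer in one of four
quadrants from two strict inequalities: `sgy > avy_farm` (a demanding
threshold) and `avy_farm > avy_region` (an above-average farm). A farmer
demanding more than their own above-average mean is `high_sensitive`; the
tolerant above-average case is `low_sensitive`. The two below-region
quadrants have no established names; this package calls them
`underperforming_context` (demanding, below-region) and `standard`. Ties
fall to the less sensitive side, since the defining conditions are strict.

## Calibration of the synthetic defaults

The generator defaults were fixed once, before the test suite was written
around them, to the study conditions the package targets:

* climate envelope 9–10 °C and 730–830 mm (checked over 200 simulated
  years at 3 standard errors);
* sowing window DOY 283–328 × 30 years → 1,380 seasons;
* sgy 69.17 dt/ha, the regional survey mean;
* crop parameters (`rue = 1.85` g/MJ, thermal milestones
  150/550/800/1050/1400/2000 °C·d, late-sowing penalty 0.0048/day) chosen
  so that grid yields span roughly 54–91 dt/ha with the median near
  74 dt/ha and the per-DOY success frequency declines from ≈0.88 in the
  earliest third of the window to ≈0.33 at its end, crossing 0.5 around
  DOY 317 — so both OP0 outcomes actually occur.

What the synthetic stack does *not* emulate: nitrogen dynamics,
vernalization and photoperiod, pests, cultivar differences, real station
weather, or any specific published acceptance-range table. Green tests
demonstrate that the scoring machinery is correct and that the method's
qualitative behaviour (later sowing → lower success; filtering → tighter
ranges; perception ≠ mean-variance) emerges — not that any real region's
numeric ranges are reproduced.

## Numerical choices and degenerate inputs

* Whiskers need ≥ 4 values; an empty post-filter pool raises an error
  suggesting a lower sgy or a wider grid rather than returning vacuous
  ranges.
* A zero-IQR sample collapses the range to the repeated value — scoring
  then flags any deviation, which is the faithful reading of "no observed
  fluctuation was ever acceptable".
* All randomness flows through explicit integer seeds; repeated runs are
  byte-identical, and every writer/reader pair round-trips losslessly.
* Problem sizes in the shipped tests: the reference grid is built once per
  test run (46 × 30 seasons, ~25 s); module tests run on a 3 × 5 miniature
  grid.

## Worked example

```{r}
library(arscore)

weather <- generate_weather(climate_params(), n_years = 31, seed = 1)
traces  <- build_grid(weather, doys = 283:328)
pool    <- build_pool(traces, sgy = 69.17)

future  <- generate_weather(climate_params(), 21, seed = 1001)
seasons <- lapply(1:20, function(y) simulate_season(future, y, 290))
scores  <- score_seasons(seasons, pool)
summarize_risk(scores$yield, scores$total, sgy = 69.17, label = "future")
```
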