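---
title: "Methods: projecting cardiovascular DALY burden under demographic change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: projecting cardiovascular DALY burden under demographic change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvdproj)
```

## The question the package answers

Iran entered the 2000s with an unusually young population — a large
young-adult bulge born in the 1980s — and a fertility rate falling fast.
As that bulge ages into the 30+ range where cardiovascular disease (CVD)
dominates mortality, the national CVD burden must grow even if nothing
about the disease itself changes. `cvdproj` quantifies that purely
demographic effect: it projects disability-adjusted life years (DALYs)
lost to CVD over 2005–2025 holding age- and sex-specific DALY *rates*
frozen at their base-year level, so any growth in the projected burden
is attributable to population growth and aging alone.

The pipeline has four stages:

1. **Demography** — a base-year population pyramid by sex and 5-year age
   group, plus survivorship and fertility schedules. Because the original
   inputs (UN projections, a 2003 national burden-of-disease table) are
   not redistributable data files, the package generates statistically
   equivalent synthetic versions.
2. **Cohort-component projection** — the pyramid is stepped forward in
   5-year periods under one of five named fertility scenarios.
3. **Rate interpolation** — CVD DALY rates known only on coarse adult
   age groups (30–44, 45–59, 60–69, 70–79, 80+) are interpolated to
   5-year groups by an ordinary least-squares line of rate against
   age-group midpoint.
4. **Burden projection and uncertainty** — rates × projected populations
   give DALYs per year; a six-scenario sensitivity grid and Monte Carlo
   percentile intervals propagate population error and death
   undercounting.

## The rate model

Within each sex stratum (`both`, `male`, `female`) the DALY rate is
modelled as a straight line in the age-group midpoint $a$:

$$r(a) = \beta_0 + \beta_1 a,$$

fitted by OLS to the five coarse-group observations. The package ships
three reference lines for Iranian adults derived from the 2003 national
burden-of-disease data:

| stratum | $\beta_0$ | $\beta_1$ (per year of age) |
|---------|-----------:|------------:|
| both    | −5047.25 | 173.71 |
| male    | −4896.54 | 171.17 |
| female  | −5190.07 | 176.11 |

Three modelling choices deserve emphasis, because the source equations
are stated without units or coding conventions:

* **Rate denominator.** The coefficients are interpreted as DALYs **per
  100,000 population** at the group midpoint. Raw DALY counts are
  inconsistent with the magnitude of the reference projection table
  (e.g. a 30–34 rate of 511.47 per 100,000 applied to roughly 6 million
  persons gives ≈ 30,700 DALYs, matching the reference table's
  30,850.99 for 2005), whereas no count interpretation does. The
  denominator is configurable (`rate_denominator` in the run
  configuration) and is recorded in every run manifest.
* **Age coding.** "Age" is the interval midpoint in years, not a group
  index: a slope of ~174 per year over a 65-year adult span is only
  consistent with midpoint coding. Closed intervals use
  $(\mathrm{lo}+\mathrm{hi})/2$ with inclusive bounds (30–34 → 32;
  45–59 → 52); the open 80+ group is closed by convention 10 years above
  its lower bound (midpoint 85, configurable via `open_width`); the
  terminal 100+ group is pinned at 100.
* **Clamping and the terminal group.** Negative predictions are clamped
  to zero — irrelevant in practice, since all three reference lines
  cross zero near age 29, below every adult midpoint. The 100+ group is
  assigned zero burden outright, matching the all-zero 100+ row of the
  reference table: the linear extrapolation is not trusted that far and
  the affected population is negligible.

An open question the package resolves by decision: whether the original
interpolation applied the fitted line directly or rescaled the fine
rates so coarse-group totals were preserved. The package applies the
line directly (the simpler reading); nothing in the shipped reference
outputs discriminates between the two.

## Cohort-component projection

`project_step()` implements the standard discrete-time arithmetic on
5-year age groups. For each sex, survivors of group $[a, a+4]$ at time
$t$ populate $[a+5, a+9]$ at $t+5$ via the group's survivorship ratio;
the open 100+ group additionally retains its own survivors. Births over
the period are

$$B = 5 \sum_{g \in 15\ldots49} W_g \, f_g,$$

with $W_g$ the female count and $f_g$ the annual age-specific fertility
rate (ASFR); births are split by a sex ratio at birth of 1.05 and
survived into the 0–4 group. Start-of-period female counts are used as
the birth exposure by default — the simplest consistent convention; a
mid-period averaging alternative is available via `exposure = "mid"`.
Migration is zero throughout, consistent with a projection that isolates
fertility and aging.

Scenarios enter only through fertility: each 5-year period's schedule is
rescaled by a single scalar so its implied total fertility rate
(TFR $= 5\sum_g f_g$) equals the scenario's value for that period.
The five named paths (medium, high, low, constant, instant replacement
at 2.1) are shipped as an immutable fixture in `tfr_scenarios()`; any
other path must be passed explicitly, which prevents silent drift of the
study conditions. Because higher TFR adds births while every other flow
is identical, projected totals are pointwise weakly increasing in the
TFR path — a property the test suite checks by direct simulation.

A pyramid labelled year $Y$ describes mid-year $Y$; periods are labelled
`"Y-Y+5"`. Annual curves, when needed, come from cell-wise linear
interpolation between quinquennial pyramids (`interpolate_years()`),
since only 5-yearly values are produced natively.

## The synthetic demography generator

`make_base_population()` draws the age profile from a discretised
Gaussian in age (an optional flat floor is available but defaults to
zero: the pure Gaussian already meets every constraint the emulated 2005
pyramid must satisfy). The default configuration — 70,122,200 people,
peak age 22, spread 18 years, male excess of 889,000 at ages 30+ —
reproduces the documented features of the 2005 Iranian pyramid: modal
group 20–24 and an adults-30+ share of 37.8%, within 2 percentage
points of the recorded 38.01%. The grand total is normalised exactly and
the 30+ sex gap is enforced exactly by transferring mass between the
sexes within the 30+ groups (leaving the total untouched). A small
seeded lognormal jitter (sd 0.005) roughens the profile without ever
displacing the modal group.

What the generator does *not* emulate: the historical fertility troughs
and spikes that give the real pyramid its notches, old-age structure
heavier than a Gaussian tail (the synthetic 65+ share is ~1% against a
recorded 4.93%), and migration. Consequently synthetic runs reproduce
the *qualitative* conclusions (burden more than 1.5-folds by 2025;
scenario ordering; aging-driven growth) but not the published population
totals, which depended on external UN schedules; those totals serve only
as qualitative reference here.

`make_mortality_schedule()` uses a Gompertz hazard (log-hazard slopes
0.088/0.082 for males/females — females age more slowly), a childhood
dip, and a seeded 3% hazard jitter; hazards are made monotone beyond age
30 by a running maximum and anchored so the 30–34 five-year survivorship
equals `adult_level` × 0.995 to machine precision.
`make_fertility_schedule()` uses a Gaussian ASFR hump centred at age 27
(width 6 years) normalised exactly to the target TFR.
`make_coarse_daly_table()` evaluates a rate line at the coarse midpoints
and adds Gaussian noise truncated at zero — the model under which OLS
refitting is unbiased, which the tests verify over 500 replicates.

All generators are pure functions of their arguments including the
seed; seeding goes through an isolated RNG stream so package calls never
disturb the caller's random-number state.

## Burden projection and its summaries

`compute_burden()` forms cell DALYs = rate / 100,000 × group population.
The `both` stratum applies the both-sex line to the sex-summed pyramid
rather than adding male and female results: the three strata are
independent regressions, and the reference table itself is not
cross-stratum additive (male + female 2005 totals exceed the both-sex
total by ≈ 465 DALYs, about 0.05%). The package deliberately preserves
this independence rather than "fixing" it.

"Direct age standardization" is operationalised as constant base-year
age-specific rates applied to projected populations — i.e. the crude
total under frozen rates — because the reference totals are crude column
sums and no external standard population is named. An explicit
standardize-to-reference operation was considered and rejected as
unused by every shipped output.

The packaged fixture `reference_table2.csv` transcribes the published
projection of DALYs by sex and 5-year age group for 2005 and 2025. Its
printed column totals differ from recomputed cell sums by up to 0.02
(last-digit rounding); `burden_table` objects therefore carry the
recorded totals alongside the cells, `write_table2()` re-emits them, and
round-tripping the fixture is byte-exact. Values are formatted with two
decimals, rounded half-even.

```{r fixture}
verify_fixture()
```

## Uncertainty

The sensitivity grid crosses population-estimate error (2%, 5%) with
CVD-death undercounting (5%, 10%, 20%). Undercounting is one-sided:
recorded deaths are a $(1-u)$ fraction of the truth, so the correction
divides by $(1-u)$ and can only raise the estimate. Deterministic bounds
for a point $P$ are $[P(1-e),\; P(1+e)/(1-u)]$.

Monte Carlo intervals sample $e \sim U(-e_{max}, e_{max})$ and
$u \sim U(0, u_{max})$, form $P(1+e)/(1-u)$, and take empirical
percentiles (95% by default, 100,000 draws, seeded). Uniform sampling is
the maximum-entropy choice given that only ranges are stated for the
error sources; the published interval endpoints for these scenarios are
not exactly recoverable from any simple closed form, and their
generating distributions are unstated, so the package declares its own
distributions in the output metadata and documents the divergence
rather than reverse-engineering printed bounds. The qualitative
contracts that *are* enforced (and tested): Monte Carlo intervals are
always nested inside the deterministic bounds (their sampling support),
harsher scenarios give wider intervals, 95% intervals cover a truth
drawn from the stated distributions 95% ± 1.5% of the time, and equal
seeds give identical intervals.

```{r sensitivity}
point <- total_daly(reference_table2()$tables[["2025"]])
sensitivity_table(reference_table2(), year = 2025, draws = 2e4)[,
  c("scenario", "pop_error", "undercount", "lower", "upper",
    "mc_lower", "mc_upper")]
```

## Numerical and design notes

* Problem sizes: projections are exact linear algebra on 21 × 2
  matrices and run in milliseconds at any population size; tests use
  totals between 10^3 and 7 × 10^7 people. Monte Carlo defaults to
  100,000 draws; coverage experiments use 10,000 replications. The OLS
  fit has five points per stratum; its oracle (hand-written normal
  equations) agrees to 10⁻⁹ and exact-line recovery holds to 10⁻⁶.
* Degenerate inputs fail loudly: zero-total pyramids (undefined shares),
  fewer than two distinct midpoints (degenerate fit), undercount ≥ 1,
  TFR ≤ 0, horizons not a multiple of 5 years from the base.
* The first coarse adult group is taken as 30–44. One source passage
  lists it as "34–44", but every downstream use (the reference table's
  30–34 base row, the ≥30 framing of all totals) treats 30 as the base
  of adulthood; the package records the discrepancy and uses 30–44.
* `run_pipeline()` is deterministic given its configuration: rerunning
  an identical config writes byte-identical artifacts, and the manifest
  records the config, a stable hash, and the rate-denominator
  interpretation.

## Limitations

The projection isolates demography: rates frozen at base year mean no
risk-factor trends, no treatment effects, no cause interactions, and no
YLL/YLD decomposition. The synthetic demography supports testing every
pipeline property but is not a substitute for real schedules — runs
aimed at substantive conclusions should ingest externally validated
pyramids via `read_pyramid_csv()` and refit rate lines from real coarse
tables via `fit_rate_line()`.
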