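# polarland

Estimating terrestrial habitat use by satellite-collared polar bears and
relating it to sea-ice phenology.

## The problem

In regions where summer sea ice retreats toward the pole, collared female
polar bears face a choice: follow the pack ice north or come ashore. Collar
data answer where and for how long each bear used land — but the raw record
is hostile: Argos fixes with class-dependent errors of 0.15–10 km, GPS
fixes at 30 m, irregular sampling (every 3 days in older deployments, daily
or better recently), multi-week transmission outages, collars that drop and
keep transmitting from the ground, and den structures that attenuate
transmission exactly when denning behaviour is of interest. `polarland` is
for movement ecologists who need per-bear-year land-use metrics from such
data, comparisons of those metrics between collaring eras, and their
relationship to the timing of coastal sea-ice retreat.

## What it implements

**Movement model.** A continuous-time correlated random walk: velocity is
an Ornstein–Uhlenbeck process (decay β, 1/day; diffusion σ, km/day^1.5)
and position its integral,

    dv = −β v dt + σ dW,   dp = v dt,

fitted by exact Kalman-filter maximum likelihood over irregular fix times
with fixed class-specific measurement SDs (3: 150 m, 2: 350 m, 1: 1000 m,
0: 1500 m, A: 5 km, B: 10 km, GPS: 30 m), then smoothed to daily positions.
Days bracketed by observed fixes more than 14 days apart are excluded.

**Screening.** Standard Argos classes kept, class Z rejected, auxiliary
classes kept only when corroborated within 10 km by the adjacent kept fix
or moving < 10 km/h without an extremely acute turn; collar drops detected
from sustained zero activity and truncated.

**Land use.** A position is on land within 5 km of a labelled coastline
polygon (planar km projection). Per bear-year: days on land between 1 Aug
and 31 Oct, the >7-day and >21-day indicators, arrival/departure dates,
land-mass attribution, and the annual percent of positions on land (only
for bear-years with ≥ 300 usable days).

**Denning.** Events are runs of ≥ 35 days (Oct–May, ≤ 2-day interruptions
merged) where collar temperature exceeds a weekly non-denning baseline by
k·SD (default k = 2); substrate (land/ice/unknown) is judged from observed
fixes within ±3 days of the event.

**Ice phenology.** From daily 25-km concentration grids: weekly means,
pack ice as the largest contiguous ≥ 15% area (8-connected), per-coastal-
segment retreat/return dates against a 50-km distance rule with the
never-retreats sentinel (365, 1), and Aug–Oct shelf coverage fractions.

**Inference.** Two-group logistic regression from counts (slope = log odds
ratio with the classical closed-form SE), pooled-variance ANOVA from
summary statistics (F = t²), least-squares regression, conditional
logistic use–availability resource selection (stratified by bear-year,
with a period × retreat-date interaction), AIC ranking, and Pearson
chi-squared contingency tests.

**Synthetic study generator.** Seeded, deterministic telemetry + sensor +
ice-raster inputs with known ground truth, at the study's own rates and
effect sizes, so the whole pipeline is testable end to end.

## Worked example

```r
library(polarland)

# a full synthetic two-period study: simulate, screen, fit, classify,
# detect denning, compute ice phenology, compare periods
report <- run_study(sim_config(seed = 11))
print(report)
```

```
study_report (seed 11 )
  eligible bear-years: 22 + 14 (4 excluded for data gaps)
  >7-day land use: 6/22 (27.3%) vs 3/14 (21.4%)
  >21-day land use: 3/22 vs 3/14
  denning events: 14 ( 13 on land )
  logistic_gt7: Wald chi2 = 0.155 (p = 0.694)
  logistic_gt21: Wald chi2 = 0.369 (p = 0.544)
  anova_days_gt7: F = 11 (p = 0.0128)
  anova_arrival: F = 0.901 (p = 0.379)
  anova_departure: F = 0.00821 (p = 0.93)
  anova_pct_locations: F = 4.53 (p = 0.0423)
  regression_days_vs_ice: F = 0.978 (p = 0.368)
```

Reading this: of 40 simulated bear-years, 4 lost their August–October
window to > 14-day data gaps; of the rest, 27.3% vs 21.4% spent more than
a week ashore (at these cohort sizes the configured 20% vs 38.9% difference
is not significant — the logistic p = 0.69); bears that did come ashore
stayed markedly longer in the recent period (ANOVA on days ashore,
F = 11, p = 0.013), and a larger share of their annual positions was on
land (F = 4.5, p = 0.042). All 14 denning events planted by the generator
were recovered, 13 of them assigned to land.

The same inference functions work directly from published counts and
summary tables:

```r
f <- reproduce_printed_stats(system.file("extdata", "printed_summaries.csv",
                                         package = "polarland"))
print(f$logit_gt7)
print(f$days_gt7)
```

```
fit_result: two-group logistic (log odds ratio)
  slope = 0.9343 (SE 0.4416)
  Wald chi2(1) = 4.476, p = 0.03437
fit_result: two-group ANOVA from summaries
  diff = 30 (SE 7.571)
  F(1,28) = 15.7, p = 0.0004644
```

— the proportion of bear-years with > 7 land days rose with a log odds
ratio of 0.93 ± 0.44 (p = 0.034), and time ashore grew by 30.0 ± 7.6 days
(F₁,₂₈ = 15.7).

## Package layout

```
R/            simulation, screening, CTCRW fitting/smoothing, land use,
              denning, ice phenology, inference, pipeline, CSV/JSON IO
tests/        testthat suite: per-module unit + property tests,
              brute-force oracles, and the acceptance checks
vignettes/    methods vignette (model, assumptions, design choices)
inst/extdata/ printed-summary table used by reproduce_printed_stats()
scripts/      acceptance.R
```
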