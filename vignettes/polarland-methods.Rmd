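---
title: "Methods: estimating polar bear land use from telemetry and relating it to sea-ice phenology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating polar bear land use from telemetry and relating it to sea-ice phenology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Adult female polar bears carrying satellite radio collars produce irregular
location fixes of very uneven quality: Argos quality classes 3, 2, 1, 0, A
and B correspond to errors from about 150 m to about 10 km, GPS fixes are
accurate to tens of metres, and transmissions stop altogether for days to
weeks. From these data the analyst wants per-bear-year answers to
behavioural questions: did the bear spend more than 7 (or 21) days on land
between August and October, when did it come ashore and leave, which land
mass did it use, did it den over winter and on what substrate — and how do
these metrics differ between an early collaring period (fixes every ~3 days)
and a recent one (fixes daily or better)? Finally, land-use timing is
related to the phenology of sea-ice retreat along the coast.

`polarland` implements that pipeline end to end, together with a seeded
synthetic-data generator so that every stage can be validated against known
ground truth without access to restricted telemetry.

# Movement model

The core of the pipeline is a continuous-time correlated random walk:
velocity follows an Ornstein-Uhlenbeck process and position is its
integral. Per axis, with autocorrelation decay $\beta$ (1/day) and
diffusion $\sigma$ (km/day$^{1.5}$),

$$dv(t) = -\beta\, v(t)\,dt + \sigma\, dW(t), \qquad
  dp(t) = v(t)\, dt,$$

so the stationary velocity variance is $\sigma^2/2\beta$ and positions are
smooth at fine scales but diffusive over long horizons. Over a gap $\delta$
between fixes the state $(p, v)$ has the exact linear-Gaussian transition

$$T(\delta) = \begin{pmatrix} 1 & (1 - e^{-\beta\delta})/\beta \\
  0 & e^{-\beta\delta} \end{pmatrix},$$

with the standard closed-form innovation covariance of the integrated OU
process. Observed fixes are true positions plus isotropic Gaussian error
whose SD is fixed by the quality class (150/350/1000/1500 m for classes
3/2/1/0, 5000 and 10000 m for A and B, 30 m for GPS); these are treated as
known constants, not estimated. Both axes share $(\beta, \sigma)$ and are
conditionally independent.

`fit_ctcrw()` maximizes the exact Kalman-filter likelihood over
$(\log\beta, \log\sigma)$ with Nelder-Mead from three starting points
(moment-based $\sigma$ start, halved and doubled), a relative tolerance of
1e-10, and a diffuse initial state (first fix position, zero velocity,
1e6 km$^2$ covariance). Wald standard errors come from the numerical
Hessian via the delta method. `predict_daily()` runs a fixed-interval
(Rauch-Tung-Striebel) smoother on the union of fix times and daily 00:00
epochs: smoothing rather than filtering is used because daily positions
are estimated retrospectively with the full track in hand.

Two numerical contracts are enforced by tests rather than assumed: the
Kalman likelihood must agree with the log-density of the implied joint
Gaussian of the observations to 1e-8 on small tracks, and the smoother
must agree with direct Gaussian conditioning to 1e-6 km.

## Gap handling

Interpolation uncertainty grows with the gap between bracketing fixes.
Daily positions whose bracketing observed fixes are more than 14 days
apart are flagged `gap_excluded`: they stay in the path table (so coverage
can be reported) but never contribute land days. A bear-year with any
gap-excluded day inside the August-October window is ineligible for
between-period comparisons; one whose window is lost entirely is
indeterminate. Days outside the observed time range are flagged too, since
they are extrapolations.

Two resampling procedures audit the interpolation where it matters — the
land/ice call: `crossvalidate_withheld()` refits without five withheld
fixes and compares predicted and observed land status at the withheld
times, and `validate_gap_midpoints()` deletes a 14-day window around an
observed on-land fix that has neighbours at least 7 days away on both
sides, re-predicts the midpoint and reports the proportion still
classified on land. The midpoint procedure is defined over observed
*on-land* fixes; a `require_on_land = FALSE` switch audits all midpoints
instead (a bear always at sea otherwise yields the documented empty
result).

# Location screening

Before fitting, fixes are screened with the standard-class rules:
classes 3/2/1 and GPS are always kept, class Z always rejected, and
auxiliary classes 0/A/B kept only if corroborated by the temporally
adjacent kept fix within 10 km, or if implied speeds to both kept
neighbours are below 10 km/h and the angle at the fix is not extremely
acute. "Not extremely acute" has no canonical value, so it is an exposed
parameter (`min_turn_angle_deg`, default 30°) — the angle is measured at
the fix between the segments to its two neighbours, so near-0° means an
out-and-back spike. Neighbours are always *kept* fixes, which makes the
filter idempotent (screening a screened track is a no-op, a property the
tests check). Dropped collars keep transmitting from a fixed point; they
are detected from the activity sensor as the first run of at least 7
consecutive zero-activity days, and all later records removed.

# Land use

The coastline is a set of labelled polygons in a locally equal-distance
planar projection with km units; a position is on land when it lies inside
a polygon or within 5 km of its boundary (the buffer absorbs unresolved
barrier islands and residual location error). The summering window is
1 Aug-31 Oct inclusive (ordinal dates 213-304, 92 days); land days need
not be consecutive. Derived metrics follow from daily on-land indicators:

* `days_on_land`, with `used_gt7` / `used_gt21` thresholds;
* arrival = first day of the longest on-land bout *starting inside the
  window* (so a later denning bout cannot masquerade as summer arrival);
* departure = last day of the final bout that ends by 31 Dec; a bear still
  ashore on 31 Dec has no departure date and is flagged
  `stayed_into_winter` (such bears are excluded from departure
  comparisons, as is conventional);
* land-mass attribution by plurality of on-land window days, ties broken
  by earliest visit;
* the annual percent of positions on land, computed only for bear-years
  with at least 300 usable (non-gap) days.

# Denning

Denning bears read warmer than ambient for weeks because the den insulates
the collar. A weekly baseline (mean and SD per calendar week) is built
from non-denning bears' series; a day is *elevated* when its temperature
exceeds the week's mean by more than $k$ SDs (default $k = 2$), and a
denning event is a run of elevated days at least 35 days long after
merging interruptions of at most 2 days, clipped to the winter window
(1 Oct-31 May). The detector is deliberately transparent — a thresholded
run-length rule with every constant exposed — and is validated by
simulation: at a den offset of 4 baseline SDs it must recover at least
90% of simulated denning intervals with at most 5% false events.

In a real cohort the non-denning bears are not known in advance. The
pipeline therefore bootstraps in two stages: a provisional baseline over
*all* bears uses per-week medians and MADs (robust to the denning
minority) with a lowered threshold $k = 1$ — the mixture inflates the MAD,
and a sustained 35-day run of 2.3%-probability exceedances is essentially
impossible for a non-denner, so this stage is conservative in the right
direction — then the final mean/SD baseline is rebuilt from the bears
without provisional events and detection re-run at $k = 2$.

Because den structures attenuate transmissions, substrate is judged from
*observed* fixes only, within ±3 days of the event boundaries: land if any
such fix classifies on land, ice if fixes exist and none do, unknown
without fixes. Events are labelled "denning" without asserting maternity
versus shelter use.

# Ice phenology

Daily concentration grids (fractions in [0,1] on a 25-km planar grid with
land and shelf masks) are averaged over fixed 7-day blocks from 1 Jan (the
final 1-day block is kept); a week is dated by its first day. Pack ice is
the largest contiguous area of weekly-mean concentration ≥ 15%;
contiguity is 8-connected by default so diagonally touching ice is not
split (exposed as a parameter). For each coastal segment — a water cell
8-adjacent to land, one segment per 25-km cell — the retreat date is the
first week-start at which the minimum centre-to-centre distance from the
segment to any pack-ice cell exceeds 50 km, and the return date the first
later week-start at which it is back within 50 km. If the pack never
leaves, the sentinel pair (365, 1) is recorded; if it never returns, the
return date is 365. Centre-to-centre planar distance is used throughout;
with 25-km cells this differs from an edge-based rule by at most ~12.5 km.
Shelf coverage is the mean over window days of the fraction of shelf cells
at or above 15%.

# Statistical comparisons

All comparisons are Wald-type at the 0.05 level with no multiplicity
correction, and each works directly from counts or summary statistics so
that published tables can be re-analyzed exactly:

* **Two-group logistic regression from counts.** With $k_i$ of $n_i$
  bear-years using land, the slope is the log odds ratio
  $\ln\frac{k_2/(n_2-k_2)}{k_1/(n_1-k_1)}$ with the classical SE
  $\sqrt{\sum 1/\text{cell}}$; this is identical to IRLS logistic
  regression on the expanded 0/1 data (checked to 1e-8). A zero cell means
  quasi-separation: the estimate is reported as non-finite with a warning
  note, and a +0.5 continuity-corrected estimate is available behind a
  flag rather than silently substituted.
* **Two-group ANOVA from summaries.** Pooled variance, $F = t^2$ on
  $(1, n_1+n_2-2)$ df. When a source prints the mean difference at higher
  precision than the group means, the `diff` argument takes it — re-deriving
  the difference from rounded group means can shift the F statistic by a
  visible amount.
* **Linear regression** via ordinary least squares (`lm`).
* **Conditional logistic regression** for use-availability resource
  selection: one stratum per bear-year (its used coastal segment versus
  all segments available that year), covariates are the segment's ice
  retreat (or return) date and its interaction with period; the period
  main effect is absorbed by the strata. Fitting goes through the Cox
  partial-likelihood equivalence (`survival::coxph`, exact method); the
  tests independently maximize the exact conditional likelihood by grid
  search and require agreement to 1e-6. Covariates constant within every
  stratum are flagged unidentifiable instead of being estimated.
* **AIC ranking** with ties broken by parsimony, and **Pearson
  chi-squared** contingency tests without continuity correction.

# The synthetic study generator

The generator emulates the study conditions, not just the data formats.
Defaults: 25 + 15 bear-years (a deliberate down-scaling of the real 80 + 36
eligible bear-years so a full study runs in a few minutes; all rates and
effect sizes are kept at the study's values); land-use probabilities 0.20
and 0.389 per period; onshore durations 32.7 ± 21.1 and 62.6 ± 20.2 days;
arrivals around ordinal dates 261 and 241; denning probabilities 0.35 and
0.381 with 92.3% and 84% of dens on land; fixes every 3 days (early
period, Argos class mix including occasional class Z) or daily (recent
period, GPS); 10% per-fix dropout, a 25% chance of one 10-20-day outage
(to exercise the 14-day rule), and a 5% collar-drop rate. The den
temperature offset is 12 °C against 3 °C daily noise. The study area has
two southern mainland coasts and two northern islands; the ice edge is a
meridional logistic front whose 15%-contour crosses 50 km off a coast at
latitude $y$ exactly on the configured date profile (southern coasts near
day 150, the islands ~126 days later, with the recent period retreating up
to 30 days earlier in the north), plus a per-year date jitter (SD 6 days)
so across-year regressions see a spread of ice conditions.

Two design points deserve emphasis:

* **Two track simulators.** `simulate_ctcrw_track()` draws from the exact
  matrix-exponential discretization of the integrated OU process — the
  same model the fitter assumes — and is what the likelihood-oracle and
  parameter-recovery tests use. `generate_track()` builds *behavioural*
  tracks: a waypoint mean path (capture site, drift with the ice edge,
  onshore residence, denning) plus a stationary OU positional deviation
  (SD 3 km, timescale 1 day) plus class error. A pure integrated-OU path
  is a position-level random walk (SD ~70 km over a season at these
  parameters) and cannot hold a bear on a 100-km island for a configured
  number of days; the stationary deviation can. The movement model is
  thus deliberately misspecified for the behavioural tracks — exactly as
  it is for real bears — and the pipeline's recovery of the configured
  land-use proportions shows robustness to that, not a tautology.
* **What is not emulated.** No passive-microwave sensor artifacts (weather
  filter, pole hole, land spillover), no real coastline geometry, no
  geodesy (everything is planar km), no behavioural switching beyond the
  scripted waypoints, and no Argos class-frequency model fitted to real
  data (the class mix is a free parameter). Passing tests therefore
  demonstrate the pipeline's internal correctness and its robustness to
  realistic error/gap structure — not fidelity to any particular sensor.

Every object is a deterministic function of `(config, seed)`; per-bear and
per-year streams are derived from the master seed so regeneration is
bit-for-bit reproducible in any order.

# Numerical choices and degenerate inputs

* Optimization on log-parameters with three starts; non-finite likelihoods
  (e.g. non-positive innovation variances at extreme parameters) return
  -Inf rather than propagating NaN.
* Tracks with fewer than 10 fixes or spanning under 20 days are rejected;
  so are non-increasing timestamps and unknown quality classes.
* An all-constant axis makes $\sigma \to 0$ degenerate; the fitter reports
  non-convergence rather than a boundary estimate.
* Weekly blocks are fixed calendar blocks, not rolling windows; an empty
  week is an error, not an NA.
* The zero-cell logistic comparison is flagged, never silently corrected;
  the continuity-corrected value is clearly labelled as such.
* Ties in land-mass attribution go to the earliest-visited mass; ties in
  AIC ranking to the model with fewer parameters.

# Problem sizes used in the shipped checks

The test-suite simulation studies use 100 tracks of 300 fixes for movement
parameter recovery, 50 replicates of 200 strata for selection-coefficient
recovery, 200 simulated bear-winters for the denning detector, and the
default 25 + 15-bear cohort for the end-to-end study; these sizes give
stable pass/fail behaviour at conventional tolerances while keeping a full
run in the minutes range.

# Known limitations

* Per-bear-year movement fits: no pooling or hierarchy across bears, so
  short tracks carry wide parameter uncertainty.
* The 5-km buffer inevitably misclassifies bears swimming alongshore;
  the cross-validation procedures quantify, but cannot remove, this.
* The denning detector assumes approximately weekly-stationary ambient
  noise; a collar with drifting calibration would need a per-collar
  baseline.
* Retreat dates are quantized to week starts (±7 days) and to the 25-km
  grid (±12.5 km relative to an edge-based distance rule).
* The conditional-logistic availability set (all coastal segments of the
  year) is a design choice exposed in code; other availability designs
  change the coefficients' meaning.
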