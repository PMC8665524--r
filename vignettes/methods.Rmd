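---
title: "Methods: behavioural decoding, staging phenology and arrival-delay models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: behavioural decoding, staging phenology and arrival-delay models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`wigeontrack` implements a complete analysis chain for spring-migration
tracking data of Eurasian wigeons (*Mareca penelope*): from raw hourly GPS
fixes to a mixed-model estimate of how closely birds of different migration
distances track the onset of the thermal growing season. This vignette is
the package's own account of the science in each stage: the model and its
assumptions, the tunable parameters, what the synthetic generators emulate,
and the numerical choices made where the design was genuinely open.

## 1. Geometry

All distances are geodesics on the WGS84 ellipsoid (Vincenty's inverse
formula, implemented in the package because no geodesy package is available
in the supported dependency set and verified against the published
Flinders Peak–Buninyong benchmark to sub-millimetre agreement). A spherical
great-circle option (radius 6371.0088 km) exists because closed-form
expected values are possible there; it is used only in tests.

Positions along the flyway are summarised by a **two-point equidistant
projection** anchored at the two capture sites (Krommeniedijk, NL ≈
4.77°E/52.49°N and the Nemunas delta, LT ≈ 21.3°E/55.3°N; configurable).
The construction places anchor 1 at (0, 0) and anchor 2 at (d, 0) and maps
every point to the planar position whose distances to the two anchors equal
its geodesic distances to the two geographic anchors — the projection's
defining property, which the implementation satisfies exactly by
construction (tested to 0.1% over the corridor 0–80°E, 45–75°N). The x
coordinate ("longitude" of the projection, km) runs along the migration
corridor and is the distance proxy used by the arrival model.

Solar time is mean solar time — UTC plus 4 minutes per degree east — with
an optional equation-of-time correction (off by default; a ±15-minute shift
is immaterial for a cyclical daily covariate).

## 2. Trajectory preparation

Tags record 15-second 1 Hz bursts once per hour, transfer via GSM, and
degrade to coarser multiples of the hourly schedule at low battery. The
cleaning rules are: (i) remove the maximal *trailing* run of fixes with
ground speed exactly 0 m/s (a dead bird or dropped tag; interior zero-speed
fixes are real roosting and are kept); (ii) collapse each burst to its
first fix, where a burst is any run of consecutive fixes less than 20 s
apart (the recording bout is 15 s; 20 s gives margin without merging
distinct schedule points).

Regularisation snaps fixes within ±5 min of a whole hour to that hour,
drops off-schedule fixes, keeps the nearer fix when two snap to the same
hour, and inserts *missed fixes* — timestamps with unknown location — for
every absent hour. The ±5-minute tolerance is a package choice; at a
1-hour schedule it cleanly separates
on-schedule jitter from off-schedule recordings. Trajectories are split by
individual and calendar year of each fix (the spring season, February–July,
never crosses a year boundary, so this equals any February-anchored rule).

The observation stream for the behaviour model is, per hourly interval: the
square root of the step length in km (variance-stabilising for strongly
right-skewed waterfowl steps), the signed turning angle in radians (change
of initial geodesic bearing; `NA` at missing or zero-length flanking steps;
exact reversals take +π), and the solar hour at the interval start.

## 3. The four-state movement HMM

Behavioural states are *rest*, *non-flight activity*, *local flight* and
*migratory flight*, in increasing order of the mean sqrt-step. Emissions:

* **Steps**: a gamma distribution on the sqrt-km scale, parameterised by
  (mean, sd) per state, mixed with a point mass at exactly zero (stationary
  birds produce exact zeros, where a gamma density is undefined). The point
  mass is estimated only when the pooled data contain zeros.
* **Angles**: a Weibull density for |angle|, renormalised over (0, π], with
  a symmetric ½ factor for the sign. A Weibull on a circular variable is
  unusual; a density on the magnitude, truncated and renormalised to the
  supported range, is the one coherent reading, and directional persistence
  is then expressed through the shape/scale of the magnitude distribution.

State switching is multinomial-logit with the diagonal as reference and a
first-harmonic cosinor in solar hour (cos and sin of 2πh/24) on every
off-diagonal transition — the minimal model in which switching probability
varies over the day. Because the data are hourly, the covariate is
quantised to the integer hours 0–23 inside the likelihood; this makes the
transition matrix cacheable (24 per evaluation) at no modelling cost. The
initial distribution is a free simplex parameter: with time-varying
transitions there is no single stationary law to pin it to.

Missing observations contribute emission density 1 (exact marginalisation)
while the transition model keeps propagating — verified against exhaustive
path enumeration. The likelihood is the scaled forward algorithm (C++, as
movement-HMM packages do); all individual-year streams are pooled into one
shared parameter set, each stream restarting from the initial distribution.
Fitting maximises the likelihood on a working scale (log for positive
parameters, logit for the zero mass, multinomial logit for the initial
distribution) by BFGS from seeded random restarts around quantile-based
starting values; identical seed lists give bit-identical fits. Decoding is
global Viterbi with ties broken toward the lower state index; states are
labelled afterwards by increasing fitted step mean (ties, should they ever
arise, by decreasing mean |angle|).

On synthetic data from a well-separated four-state model (20 000 steps) the
fit recovers state-wise gamma means within 5% and decodes ≥ 90% of states
correctly; both are acceptance-tested at fixed seeds.

## 4. Staging sites and arrival events

The threshold distance `d_t = (v̄ₐ − 2σ) × 3600` m is the distance a slow
migratory wigeon flies in one hour in still air; with the airspeed
estimates reported for wigeons in the flight literature it is 50.184 km. It separates within-site movement from
relocation and defines departure/arrival at the migration endpoints.

The starting location is the "south-westernmost" February–April point and
the end location the "north-easternmost" May–July point, both
operationalised as extremes along the corridor axis of the projection
(lexicographic compass extremes are ill-defined; the corridor axis matches
the flyway geometry). Migration starts at the last instant within `d_t` of
the start before leaving for good — an excursion followed by a return
resets the clock — and ends at the first instant within `d_t` of the end.

After removing migratory-flight fixes (state 4 only by default; removal of
local flight as well is a configuration switch), staging sites are the
maximal runs of consecutive retained fixes with inter-fix geodesic gaps
≤ `d_t`; each gap beyond `d_t` opens a new site. A site's arrival event is
the UTC calendar date of its first member fix. Events within `d_t` of the
starting location are discarded (still "at home"), as are arrivals after
June 30 (inclusive cutoff: June 30 itself is kept) — late summer records
are no longer spring migration. Cumulative distance is accumulated along
the surviving events from the start location.

## 5. Thermal-growing-season phenology

Daily means are per-UTC-day arithmetic means of hourly 2-m temperature
(Kelvin auto-detected and converted); days with fewer than 20 of 24 hours
are flagged missing. Because no NetCDF reader is available in the
supported dependency set, gridded temperature travels as a long-format CSV
and lives in memory as a (time, lat, lon) array; everything else about the
contract is unchanged.

The TGS onset at a 5 °C reference uses, by default, the **degree-day-sum
minimum** criterion: the onset is the day after the within-year minimum of
the cumulative sum of (t̄ − 5 °C), with the empty pre-season sum as a
candidate so an always-warm year has onset 1. This criterion is robust to
single warm days and fully deterministic; a persistence alternative ("first
day of ≥ 5 consecutive days above the reference") is one switch away, and
both are tested against brute-force scans. A year whose daily mean never
exceeds the reference, or whose balance is still falling at year end, has
no onset; missing days within ±3 days of the candidate onset also undefine
it (the onset cannot be certified through a data hole).

The climatological mean onset (`tgs_mean`) averages the defined onsets over
a configurable window (a 20-year pre-study window such as 1998–2017 is the
intended use; undefined years are skipped). `tgs_deviation = onset − tgs_mean`: positive means a late spring.
Growing degree days over `[from, to)` sum `max(0, t̄ − 5)`; negative
exceedances are truncated to zero, and the accumulation is additive over
adjacent windows.

## 6. The arrival-delay model

Each arrival event is annotated with the onset and deviation of its year at
the nearest grid cell (great-circle nearest; deterministic lower-index tie
rule). The response is `Δarrival_d = arrival DOY − onset`, the signed
difference (wigeons overwhelmingly arrive after the onset, so the sign is
almost always positive anyway); an absolute-value switch exists but is off
by default. Events
over cells with undefined onset are dropped. Covariates: `max_longitude`
(largest projected corridor coordinate reached that spring, end location
included — one value per individual-year), `distance_traveled` (cumulative
km over prior events), and the year's `tgs_deviation`. Response and
covariates are z-scaled over the final modelling dataset, after all
exclusions, and the scaling constants are stored in the fit so predictions
can be returned in days.

The full model has cell-means capture-site intercepts, the scaled
deviation, the scaled maximum longitude, and one maximum-longitude ×
distance-traveled slope per capture site (one main longitude effect,
per-site interaction slopes — the identifiable reading of a three-way
interaction with cell-means site intercepts).
Random intercepts for individual and year-within-individual capture
repeated observations; within an individual-year, residuals carry an
**Ornstein–Uhlenbeck correlation** over arrival day — correlation
exp(−Δt/ρ) between events Δt days apart, equal to 1 at lag zero — plus an
independent residual nugget (the safer, more general default: ρ → 0 recovers the independent model exactly, which is
tested). The time variable is the unscaled arrival day of year.

Estimation is by direct maximum likelihood: per individual block the
marginal covariance is assembled from the four components, fixed effects
are profiled out by GLS, and the profiled multivariate-normal likelihood is
maximised over log-scale variance parameters (BFGS). Estimated variances
are clamped to [10⁻¹⁰, 10⁸] × var(y): when an exact fit drives components
toward zero the clamp keeps the covariance well-conditioned without
affecting interior optima. ML (not REML) is the default, matching the use
of Wald 95% CIs (estimate ± 1.96 SE) and z-values; the independent-route
check against `lme4` on the shared sub-model agrees to 10⁻⁴ in
log-likelihood. Marginal R² is var(Xβ̂) over the sum of var(Xβ̂), all
random-intercept variances, the OU variance and the residual variance.

The `last_arrival` variant keeps only the final event of each
individual-year, drops the site terms, the interaction and the OU
component, and uses a random intercept per individual. Scenario
predictions are population level (random effects at zero), computed on the
scaled scale and back-transformed to days with the stored constants.

## 7. Ring-recovery comparison

Ring recoveries from the Arnhem, London and Moscow schemes are summarised
in half-open 10° longitudinal bands [lo, lo+10), lo = 0…70°E, as the mean
and sd of the recovery day of year within a spring window (default
February 1 – June 30, DOY 32–181; configurable).
These bands use *geographic* longitude — the tracked corridor's ~4.5–80°
span matches geographic coordinates — unlike the projected corridor
"longitude" of the arrival model; both conventions are deliberate and
documented at their call sites. Spring-marked control birds enter only
behind a flag.

For each tracked individual-year, the first band crossing is the date of
the earliest arrival event whose longitude is at least the band's lower
edge (so crossing dates are monotone in the edge). `Δarrival_ring` is the
tracked crossing DOY minus the scheme's band mean; the delay model has
cell-means scheme intercepts, scheme-specific slopes in scaled band
longitude, and a random intercept per individual-year, fitted with the
same ML engine. Sex, capture site and TGS deviation can be appended as
fixed terms; the headline model omits them.

## 8. What the synthetic world does and does not establish

The generators produce every input the pipeline consumes, with ground
truth, at a realistic field scale (tens of individual-years, ~200 arrival
events, a handful of years):

* **Trajectories**: a planted itinerary of staging sites (≥ 2·d_t apart,
  enforced), within-site wander inside d_t/8, hourly migration legs of
  65 km toward the next site, behavioural states 1–3 drawn at configured
  dwell proportions, and missed fixes at 5%. Truth records per-fix states
  and per-site arrival dates (dated at the first *observed* non-migratory
  fix, so truth remains exact under missingness).
* **Temperature**: per cell and year, a sinusoidal daily-mean skeleton that
  first exceeds 5 °C exactly on a planted crossing day (later with
  latitude, shifted per year), a mean-zero diurnal cycle, and optional
  hourly noise.
* **Ring recoveries**: normal recovery dates around band-specific means,
  uniform longitudes within bands.
* **Arrival datasets**: the exact mixed-model data-generating process —
  fixed effects, nested intercepts, OU residuals (sampled through the
  Cholesky factor of the kernel), iid noise — with covariates generated
  directly on the standardised scale.

All generators are pure functions of (config, seed) via an isolated RNG
stream. What a green test establishes is *internal correctness*: the
pipeline recovers what its own assumed world plants. Real tracking data add
tag failure patterns, wind drift, GSM gaps correlated with location,
coastline-following movement and observation error — none of which are
emulated — so green tests here do not certify field performance, only that the
procedure itself is implemented faithfully.

## 9. Numerical choices and limitations

* Vincenty's inverse formula does not converge for near-antipodal pairs;
  such pairs (impossible within the corridor) fall back to the spherical
  distance with a warning.
* The HMM likelihood returns a large penalty (10¹⁰) outside the feasible
  region instead of erroring, so line searches can recover.
* Viterbi ties break toward the lower state index; `which.max`'s
  first-maximum rule implements this.
* The degree-day onset treats missing days as exactly the reference
  temperature while locating the minimum, then refuses to certify an onset
  within ±3 days of a hole.
* Variance components are reported as estimated (including boundary-level
  values); they are clamped for conditioning, not silently zeroed.
* Wald ± 1.96·SE intervals after (RE)ML undercover group-level coefficients
  when the number of groups is small (a few dozen individual-years, as
  here): the coverage acceptance test measures and reports this shortfall
  rather than hiding it. Kenward–Roger or Satterthwaite corrections would
  close the gap but are outside the package's CI convention of plain
  symmetric Wald intervals.
* The per-criterion time budgets drive two scale choices: the HMM recovery
  test uses two seeded restarts (the 20 000-step likelihood surface is
  effectively unimodal for well-separated states), and the coverage study
  caps the variance optimiser at 200 iterations per replicate.
* Single-stage CLI runs require their file inputs on disk; intermediate
  in-memory products (decoded states, arrival records) are rebuilt by
  `run all`, which is the supported end-to-end path.
* The pipeline decodes with supplied or default HMM parameters unless
  `hmm$fit = TRUE`: fitting inside the orchestrated run is supported but
  off by default to keep the end-to-end demonstration fast.
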