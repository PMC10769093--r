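---
title: "Quantifying busy ambulances and their delay: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying busy ambulances and their delay: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Emergency medical dispatch logs record which ambulance responded to each
incident and when every unit was occupied, but they do not record which
units *could* have responded. When the natural responder for an area is
already on a mission, a farther unit answers and the patient waits longer —
a concurrency conflict. This package estimates (a) how exposed each
incident was to busy ambulances and (b) how many minutes of response time
that exposure costs, using nothing beyond two operational tables: an
incident log (call time, coordinates, urgency, responding unit, scene
arrival) and a mission log (unit, start, end, primary/secondary).

## The busy-probability exposure

Because the counterfactual responder set is unobserved, it is estimated
empirically, one incident at a time:

1. **Neighbor set.** The up to 5,000 nearest eligible incidents within 15
   km (great-circle), excluding all incidents on the focal incident's
   calendar day. The same-day exclusion keeps the focal incident's own
   operational situation out of its model.
2. **Candidate units.** The at most five units with the highest responder
   frequency in the neighbor set (ties by unit id). Responder frequency is
   the only signal available for "could have responded"; neighbors served
   by other units are dropped from the training rows. The most frequent
   unit is the reference category.
3. **Local multinomial model.** The log-odds of each candidate unit
   responding, relative to the reference, are linear in hour-of-day (24
   levels) and day-of-week (7 levels) dummies:
   \[
   \log \frac{P(A_i \mid t, d)}{P(A_K \mid t, d)}
     = \beta_{0i} + \sum_j \beta_{t_j i}\, t_j + \sum_k \beta_{d_k i}\, d_k .
   \]
   The time covariates let the model express differing operating hours —
   a day car absorbs probability mass during its shift only.
4. **Exposure.** With predicted probabilities \(p_i\) at the focal
   incident's hour and weekday, and busy indicators \(b_i\) (unit occupied
   at call time),
   \[
   P(\text{busy ambulance} \mid t, d) = \sum_i p_i\, b_i ,
   \]
   a plain dot product, never re-normalized. The candidate count is the
   number of units with \(p_i > 0.10\) (strict).

A three-unit example: probabilities 0.6, 0.35, 0.05 with the first and
third units occupied give exposure 0.6 + 0.05 = 0.65, and two units clear
the 10% threshold.

### Numerical choices in the local model

The per-incident fit works on the (hour, weekday) × unit count table — the
sufficient statistic for a categorical-covariate multinomial — so the cost
is independent of the neighbor count. A damped Newton solver
(`src/multinom_newton.cpp`) maximizes the log-likelihood minus a ridge
penalty of `1e-4` per coefficient, starting from zero coefficients; the
fit is therefore deterministic given the data. The ridge tames the
separation that arises when a rare unit never responded in some hour; it
plays the same role as weight decay in neural-network training of the same
softmax-linear model, without changing the model class. Identical count
tables are memoized within a cohort; results are bit-identical with the
cache on or off.

Degenerate cases are explicit: a single-unit candidate set predicts
probability 1; an hour or weekday never seen in the neighbor rows falls
back to intercept-only prediction for that factor; incidents with fewer
than `min_neighbors` (default 50) neighbors, or a non-converged fit, are
excluded from the exposure table with a recorded reason rather than
imputed. Busy intervals are half-open `[start, end)` at minute resolution,
and the mission generated by the focal incident itself is excluded from
its own busy determination — otherwise every served incident would count
its own response as congestion. All missions, primary and secondary at
every urgency, count toward busy status. Whether "busy" should be read at
call time or dispatch time is not decidable from the data model; call time
is used, matching the exposure's conditioning on the incident time.

## Delay estimation

Response times vary enormously over space and time, so the delay is
identified only from contrasts *within* a neighbourhood and calendar year,
with month, day-of-week and hour-of-day absorbed as categorical adjusters:
an OLS regression of response time on the busy probability after iterated
weighted demeaning over all absorbed factors (alternating projections to a
supremum-norm tolerance of `1e-10`). This is numerically identical to
dummy-variable OLS — the test suite enforces agreement to `1e-8` — but
scales to many groups. Estimates are reported per 10-percentage-point
increase in busy probability (coefficient × 0.10).

The *mean additional response time* is the mean gap between actual
response time and the prediction with busy probability set to zero. With
absorbed effects this collapses algebraically to coefficient × mean
exposure; both the identity and the explicit counterfactual-prediction
route are implemented and agree to `1e-9`.

Uncertainty comes from the Bayesian bootstrap: per replicate, each
incident receives an independent standard-exponential weight normalized to
mean one, and the weighted estimator is re-run; the 95% interval is the
2.5th/97.5th percentile of replicates. Incidents, not neighbourhoods, are
the resampling unit — the within-group estimator already absorbs
group-level structure, and fractional weights keep every group populated.
The default is 1,000 replicates for production runs; the validation suite
uses 100–200.

Stratified estimates (rural/urban, 1/2/>2 candidate units, each weekday,
each hour) are separate refits on the stratum rows rather than interaction
terms — the direct reading of per-stratum reporting. Strata under 200 rows
keep their point estimate but are flagged without an interval. The balance
test regresses each of the six common incident-type indicators on the busy
probability by ridge-penalized logistic regression (ridge `1e-6`,
unpenalized intercept) with the fixed-effect and time dummies entered as
covariates, reporting odds ratios per 0.10 exposure; conditional-likelihood
matching would be an alternative reading, but plain within-area odds
ratios are what dummy absorption delivers. A sensitivity analysis re-runs
the main estimates without call years 2020–2021.

## The synthetic service

Real dispatch data of this kind cannot be shared, so the package carries a
discrete-event simulator whose output has the same shape and defects as a
regional service's logs, plus ground truth the real data can never give:
which unit was the *preferred* (overall nearest on-shift) responder, and
whether it was truly occupied at call time.

The generator lays out stations and neighbourhoods on a lat/lon plane
(urban neighbourhoods clustered and intense, rural dispersed), gives urban
stations extra day-shift cars and rural stations usually a single 24/7
unit, and drives arrivals with an inhomogeneous Poisson process (diurnal
peak in the afternoon, mild weekly cycle). Dispatch picks the nearest
on-shift free unit (ties by unit id); if none is free the incident waits
for the first unit to free up. Each response occupies its unit for the
drive plus a log-normal on-scene/transport/return block (median 55 min);
secondary missions arrive independently at 1.5 per unit-day. Travel time
is haversine distance at 80 km/h plus 2 minutes of mobilization — no road
network. Timestamps are floored to whole minutes, as in real logs.

The causal knob is `delay_effect_min`: when the preferred unit is occupied
at call time the response gains a truncated-normal draw centred on that
value (cv 0.25). The actual (farther or queued) responder determines the
mission log, but the emitted response time is built from the preferred
unit's travel plus the draw, so the injected effect *is* the ground-truth
estimand — recovery checks are not confounded by geometry. Defaults
(speeds, durations, rates, an overall busy fraction landing in the
15–35% range) were chosen once to resemble a mixed urban–rural regional
service and are not fitted to anything.

What the simulator does not emulate: road networks and travel-time
heterogeneity, re-routing of in-progress transports, helicopter/boat
units, triage behaviour under saturation, and seasonally varying demand.
Passing recovery tests therefore show that the estimator chain is correct
*when the availability process is schedule- and load-driven as modelled* —
not that real-world confounding is absent.

## Validation design and problem sizes

The test suite validates the chain at three scales, chosen as the smallest
sizes at which each property is informative:

- a reference cohort of 10 stations, 40 neighbourhoods and ~25,000
  incidents over 540 days with a 6-minute injected delay, on which the
  estimated delay per 10 pp must fall within 25% of 0.60 min and inside
  its own bootstrap interval, the exposure must be rank-calibrated against
  ground truth, and the planted balance-test association must be detected;
- 200 independent null runs (no injected delay, 2 stations, 60 days,
  ~350 analysed incidents each) whose bootstrap intervals must cover zero
  at close to the nominal 95% rate;
- small deterministic fixtures for every boundary (15.0 vs 15.01 km, 360
  vs 361 minutes, strict 10% threshold, population 10,000 vs 10,001) and
  for oracle agreement (dummy-variable OLS, an independent generic
  optimizer for the multinomial, `nnet::multinom` as an external
  cross-check).

On the reference cohort the recovered delay is moderately above the
injected value (about 0.72 per 10 pp against a true 0.60). This is the
expected behaviour of a regression on an *estimated* exposure: the
summed-probability statistic is a noisy, shrunken image of the true busy
indicator, and the within-regression rescales by the calibration slope.
Flipping busy flags at random moves the estimate monotonically toward
zero (tested), so prediction error of the candidate models pushes the
method toward *underestimation* in the field, where the candidate set is
genuinely uncertain.

## Limitations

- Units "busy" while effectively available (returning to base) inflate
  the busy indicator and dilute the exposure; the delay estimate is
  conservative in that respect.
- The candidate-selection rule (top-5 responder frequency) and the
  reference-unit choice are declared conventions, not estimated; the
  reference choice is inconsequential (softmax invariance) but the
  selection rule matters in dense areas with many overlapping units.
- Requiring an ambulance response induces potential collider bias in
  saturated situations where no unit was available.
- Per-incident exposures are not suitable for adjudicating single
  incidents; only area-time contrasts are interpretable.
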