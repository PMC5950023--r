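---
title: "An event-scheduling simulation model of AAA screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An event-scheduling simulation model of AAA screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`aaades` is an individual-level discrete event simulation (DES) of abdominal
aortic aneurysm (AAA) screening. It exists to answer questions a cohort
Markov model handles poorly: what happens to the cost-effectiveness of a
screening programme when surveillance intervals are rearranged, when the
diagnosis threshold moves, or when any other partition of the continuous
diameter scale is tried. This vignette describes the model, its
assumptions, the parameters that matter, and the design decisions taken
where the design was genuinely open.

## The model

### Disease process

Each simulated man enters at the invitation age (65 by default) with a
baseline aortic diameter drawn from a population distribution, and a latent
growth rate. Aortic size follows a log-linear individual trajectory

$$d(t) = d_0 \, e^{g t},$$

where the slope $g$ is drawn from a normal distribution whose mean and
standard deviation depend on the baseline band, and is fixed at zero below
a cutoff (2.0 cm by default): small aortas do not grow, sub-aneurysmal
aortas (2.0–2.9 cm) grow slowly, established AAAs faster. Keeping $g$
latent and individual-specific is what lets heterogeneity in progression —
impossible to express in a four-state cohort model — drive the economics.

Rupture is a continuous-time hazard that depends on current (true)
diameter,

$$h(d) = \exp\{\alpha + \beta (d - d_{\mathrm{ref}})\},$$

so the cumulative hazard along a growing trajectory is
$H(t) = \int_0^t h(d(s))\,ds$, which for this functional form has an
exponential-integral closed form. Rupture times are sampled by inverse
transform, $H(T) = -\log U$; in most men the sampled time is so far in the
future that the event can never occur, and a cap at age 150 maps those
draws to "never".

The functional forms are a design decision: the log-linear growth model
with random intercept and slope, and the log-linear diameter hazard, are
the standard choices in the surveillance meta-analysis literature on which
contemporary AAA models are parameterized, and they admit exact threshold
inversion. Both sit behind the `aorta_trajectory` /
`rupture_hazard_params` interfaces, so alternative forms can be
substituted without touching the engine.

### Scanning and detection

A scan never observes $d(t)$ directly: each measurement adds a fresh
modality-specific error (an *event-specific* parameter — errors are
independent across scans), and CT measurements additionally carry a
+0.24 cm systematic offset relative to ultrasound, reflecting
outer-to-outer versus inner-to-inner calliper placement. All screening and
surveillance decisions are made on measured diameters; this matters, since
measurement error near a band edge can discharge a true AAA or refer a
sub-threshold one.

Men not under surveillance can be detected *incidentally* (imaging done
for other reasons). Incidental detection is modelled as a constant-rate
exponential clock gated by the first time the true diameter crosses the
diagnosis threshold; the rate is a bundle parameter. It applies in both
arms to anyone currently undetected, which is what generates the
"resulting from incidental detection" rows of trial-style event tables.

### Policies

A surveillance policy is a declarative partition of the diameter axis:
an ordered list of band lower edges with a rescan interval per band, a
diagnosis threshold (the first edge) and a referral threshold. Bands are
half-open $[a, b)$ — published inclusive labels like "3.0 to 4.4 cm" sit on
a continuous scale, and half-open edges make the partition exhaustive and
disjoint. Three policies are built in: the current programme
(3.0–4.4 cm yearly, 4.5–5.4 cm quarterly, refer at 5.5 cm), a
lengthened-interval variant (2 y / 1 y / 3 mo), and a sub-aneurysmal
extension (diagnosis at 2.5 cm with 5-y rescans). Any other partition can
be expressed with `policy_spec()`.

### The event loop

Each individual owns a future event list (FEL) holding at most one pending
event per kind. The simulator pops the earliest event, records it, and
schedules, reschedules or cancels others: a surveillance scan classifies
the measurement into discharge / rescan / refer; referral schedules a
consultation 71 days later; a consultation CT at or above the referral
threshold schedules elective surgery after another 59 days (or exits the
contraindicated); repair cancels the pending rupture; rupture leads to
emergency surgery or immediate death. The loop terminates at non-AAA
death, AAA death, or censoring at the horizon. Ties are broken by a fixed
priority order with deaths first and censoring last — the paper-trail of a
simulated life is therefore deterministic given its random draws.

Three open points were resolved as follows:

* **Dropout.** Loss to recall follow-up is a per-scheduled-rescan
  Bernoulli; lost men revert to the undetected state with a fresh
  incidental-detection clock. The mechanism behind observed loss-to-recall
  counts is not described in the source literature; per-visit loss is the
  simplest mechanism that reproduces such counts.
* **Contraindication** is evaluated once, at the first consultation, using
  a pair-shared indicator.
* **Post-repair** men incur no further AAA events: no re-intervention or
  residual rupture risk is modelled (a stated non-goal).

### Twin pairs and common random numbers

Men are simulated in pairs — one invited, one not — sharing their latent
trajectory, non-AAA death time, rupture time, censoring time, and the
binary indicators for attendance, contraindication, elective and emergency
surgery survival, repair modality (EVAR vs open), *and* emergency-surgery
access upon rupture. Sharing the access indicator goes slightly beyond the
minimal twin description, but it is in the same spirit and markedly
reduces the Monte Carlo error of incremental estimates: without it,
matched pairs could diverge in whether a shared rupture is operated on.

Each pair derives three dedicated L'Ecuyer-CMRG substreams from the master
seed (shared latents, invited arm, non-invited arm), assigned by pair
index. Results are therefore bit-identical for any number of forked
workers, and the non-invited arm coincides exactly across policies
compared under one seed. Within an arm, event-specific randomness is
pre-generated in indexed blocks, so the $k$-th scan of a given individual
consumes the same error under every policy — two policies differ only
where they genuinely disagree.

### Economics

Costs attach to event occurrences (invitation, scans, consultations,
elective and emergency repair by modality) and are discounted with the
annually-compounded factor at the exact continuous event time,
$(1+r)^{-t}$. Person-time is discounted by exact integration,
$\int_{t_0}^{t_1} (1+r)^{-s} ds$, and QALYs weight each integer-age
segment by an age-banded population-norm utility. Because accrual happens
at event times there are no cycles and no half-cycle corrections — the
3-month averaging of the predecessor cohort model is intentionally not
replicated. No post-operative or post-rupture utility decrement is
applied; population norms only.

ICERs are classified on the cost-effectiveness plane (ratio / dominant /
dominated / south-west, with dominated reported as infinite in PSA
summaries), INMB is $\lambda \Delta E - \Delta C$, and the CEAC is the
fraction of PSA iterations with positive INMB per threshold.

### Oversampling

Model output is driven by the few percent of men with an aneurysmal
baseline, so those baselines are sampled at a multiplier $k$ times their
population rate and every mean is computed with Horvitz–Thompson ratio
weights (population stratum probability over sampling stratum
probability), which restores population proportions exactly in
expectation. The sampling fraction is capped at one half; the bundles set
$k$ so that the cap binds (an even split of aneurysmal and
non-aneurysmal pairs). A single uniform with a tail mapping drives the
stratified draw, so $k = 1$ reproduces plain sampling draw-for-draw.

### Parameter hierarchy and PSA

Parameters are layered exactly as the simulator consumes them: *global
fixed* values (waiting times, offsets, discount rates, unit costs, the
life table), *global uncertain* distribution specs realized once per PSA
iteration (`draw_global_uncertain()`), *pair-specific* latents,
*individual-specific* assignment (arm), and *event-specific* noise (scan
errors). Engine code receives realized draws read-only; only the PSA layer
creates them. `fix_bundle_at_means()` gives the deterministic base case.
PSA percentile intervals are the 2.5th/97.5th percentiles of the
iteration distribution, with infinite ICERs sorting above all finite
values; PSA draws are independent across parameters, as no correlation
structure is reported for them.

## Parameter bundles

Nothing epidemiological is hard-coded: every rate, cost, distribution and
table lives in a YAML bundle with per-value provenance notes. Two bundles
ship with the package.

**`mass-validation`** emulates the 4-y randomized-trial era: 4.9% AAA
prevalence, trial-era unit costs with open repair only, life-years
discounted at 1.5%/y and costs at 6%/y, and censoring at a
Uniform(3, 5.25)-year time shared within each pair (the "4-y" follow-up
had censoring times close to that distribution).

**`naaasp-basecase`** is the contemporary 30-y configuration: 1.6%
prevalence, both discount rates 3.5%/y, EVAR for 64% of elective repairs,
population-norm utilities, contemporary costs and national-statistics
mortality.

The exact values behind the original analysis are published only in
supplementary tables that are not part of this package's sources; bundle
values are therefore documented approximations chosen once at realistic,
literature-scale magnitudes. Choices worth flagging:

* **Baseline diameter** uses a mixture: a lognormal body below 3.0 cm and
  an explicit-prevalence gamma excess above it. A single lognormal cannot
  simultaneously match a screening prevalence of a few percent and the
  observed spread of detected AAAs across the 3.0–4.4 / 4.5–5.4 / ≥5.5 cm
  categories; the mixture makes prevalence an exact parameter. The gamma
  shape of 1.5 places the modal detected AAA slightly above 3.0 cm, as in
  screen-detected size distributions.
* **Growth** is band-dependent (≈1.5%/y below 3.0 cm, ≈5.5%/y above, zero
  below 2.0 cm, contemporary bundle). A single population slope applied to
  all baselines would send a third of the population to surgical size
  within the 30-y horizon, which is epidemiologically absurd.
* **Dropout** (contemporary bundle) is ≈0.1–0.2% per scheduled rescan:
  the contemporary programme recalls non-attenders and its reported
  surveillance attendance is close to complete. This parameter is
  economically load-bearing — per-visit loss couples the number of
  scheduled visits to long-run retention, so inflating it makes frequent
  scanning look *cheaper* via attrition, a mechanism the trial-era bundle
  (7% per visit, matching trial-scale loss to recall) does exhibit.
* **Measurement error** (contemporary bundle) is 0.1 cm SD for ultrasound
  under standardized protocols; at 0.2 cm, repeated rescans of men just
  above 3.0 cm churn a substantial fraction out of surveillance through
  lucky measurements, which distorts policy comparisons.

## What the simulator reproduces, and what passing tests show

With the shipped bundles and no tuning, the contemporary base case lands
at the published order of magnitude (incremental cost ≈ £50 per invitee,
incremental QALYs ≈ 0.01, ICER in the low thousands of pounds per QALY),
and the policy comparisons reproduce the published directions: lengthened
small-AAA intervals are mildly cost-saving with essentially no QALY
change; sub-aneurysmal surveillance buys QALYs at higher cost. The trial
emulation produces event tables of the observed shape and scale.

These are *structural* reproductions, not numeric ones: the generator
emulates the study conditions (prevalences, discount rates, waiting
times, censoring, policy bands), but real data differ in ways the
generator does not model — growth is not exactly exponential with a
frozen individual slope, incidental detection is not a constant-rate
clock, surgical outcomes vary with age and size, and repaired aortas
carry residual risk. Passing tests therefore certify the event-scheduling
machinery, the estimators and the economics; they do not certify the
fixture parameter values against the unavailable supplementary tables.

## Numerical choices

* Cumulative rupture hazard: exponential-integral closed form (internal
  `Ei` accurate to ~1e-15, cross-checked against `pracma`), with adaptive
  quadrature as fallback for negative hazard slopes; inversion by bracketed
  root-finding with time tolerance 1e-9 y (tested against a brute-force
  integrate-and-bisect oracle to 1e-6 y). "Never" cap at age 150.
* Life-table death times by inverse transform on the piecewise-constant
  hazard by integer age; the last tabulated rate extends beyond the table.
* Uniform draws feeding inverse transforms are clamped away from 0 and 1
  by 1e-12 to keep quantile functions finite.
* Tie-breaks: deaths before ruptures before pathway events before scans
  before censoring at equal times.
* Percent-of-observed ratios round halves away from zero. Published
  invited-arm percentage columns are internally inconsistent with their
  rounded counts (they appear computed from unrounded model output), so
  validation ratios are checked on no-invitation rows only.

## Problem sizes

The full-scale analyses behind the published numbers use millions of
pairs and 1,000-iteration PSAs. The packaged tests and the acceptance
script run the same code at reduced scale — 10^4–10^5 pairs per run,
chosen so the whole suite completes on a laptop-class single core in
minutes while keeping Monte Carlo error well inside the tested margins.
The reported quantities scale in the number of pairs only through
Monte Carlo noise; nothing in the model depends on cohort size.

## Known limitations

* No re-intervention, EVAR graft surveillance, or residual post-repair
  rupture risk; no women-specific parametrization; no targeted screening
  by risk markers.
* Growth/rupture parameters are consumed, not estimated: fitting the
  joint model to surveillance data is out of scope.
* The incidental-detection rate is diameter- and time-constant; dropout
  men re-enter only through incidental detection.
* Costs and utilities attach to events and person-time only — no
  long-term care costs or decrements after repair or rupture.
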