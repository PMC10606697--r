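---
title: "Modeling hospital mass-casualty response with mcisim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling hospital mass-casualty response with mcisim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcisim)
```

## The model

`mcisim` is a discrete-event simulator of a single acute hospital receiving
the casualty load of a mass-casualty incident. Patients are entities; staff,
rooms and machines are capacity-constrained resources; everything advances
on an event calendar with exact (not time-stepped) dynamics.

**Arrivals.** A scenario specifies counts per initial triage category
(red = severe, yellow = moderate, green = slight) and an arrival window $T$.
Within each category of size $n$, inter-arrival times are i.i.d.
exponential with mean $T/n$, so $T$ is the *expected* makespan rather than a
hard cutoff. This is the natural reading of "patients arrive within $T$
minutes under exponential arrival rates", and it keeps arrival processes
memoryless, which the M/M/c validation below exploits.

**Pathways.** Red: triage → stabilization in a resuscitation bay → imaging
if indicated → surgery if needed → transfer out. Yellow: triage →
examination in a treatment slot → imaging → surgery if needed → transfer
out. Green: triage → dining hall, discharged at the horizon. Whether a
patient needs surgery and which imaging they need are Bernoulli draws at
arrival with per-category probabilities. A CT-indicated patient who is
"eligible" (another Bernoulli draw) is sent to X-ray whenever all CT
machines are busy at request time — the capacity-saving switch radiology
departments apply in mass-casualty operations.

**Seizing rules.** Each task requires a staff multiset (with substitution
groups, e.g. the yellow examination accepts a medical assistant *or* a
rotation physician), a room type, and possibly a machine; a task starts only
when all of them are simultaneously free, holds them for the full drawn
service time (non-preemptive), and releases them together. Queues are
ordered red > yellow > green with FIFO inside a category, and a station is
head-of-line blocking: while its highest-priority patient cannot start, no
lower-priority patient overtakes at that station. Surgery draws its room
from the trauma operating rooms first, then from the usable central rooms,
which are shared with a time-of-day-modulated Poisson stream of routine
cases (warm-started 12 h before the incident so an ongoing night case can
straddle the incident time).

**Health dynamics and progressive re-triage.** Every patient carries a
score $h \in [0, 99]$ with death at 0. While a patient awaits their *first
clinical treatment* (stabilization or examination), $h$ falls at the current
category's rate $d$; during any treatment it rises at rate $r$; between
later stages it holds. Crossings of the thresholds
$\theta_{red} < \theta_{yellow}$ are solved exactly on the piecewise-linear
trajectory and scheduled as events — no ticking. A yellow patient whose
score falls below $\theta_{red}$ is re-queued on the red pathway at the
crossing time; a patient reaching 0 becomes black (absorbing), is removed
from all queues, and holds nothing.

Two scoping decisions here were genuinely open and are deliberate:

* *Deterioration stops at first treatment.* The alternative — deterioration
  during every later wait — makes stabilized patients die en masse while
  queueing for surgery under surge load, which contradicts the intended
  clinical reading (deterioration is tied to the time until treatment;
  stabilization is precisely what buys time). Consequently upward re-triage
  out of urgency never occurs before first treatment (scores only fall while
  waiting), and the category at first treatment is the category under which
  a patient's outcome is reported.
* *The triage crew is never stripped by supervision.* Green patients in the
  dining hall lock general nurses and rotation physicians at the plan's
  1:10 and 1:25 ratios. Locks claim idle staff with priority over new tasks,
  but never the last staffing of one triage slot: with three rotation
  physicians on shift and more than fifty slightly injured patients, a
  literal ratio would absorb all three and deadlock triage for everyone.
  The cap models what a hospital actually does — accept a worse supervision
  ratio rather than stop triaging casualties.

**Randomness.** Every stochastic purpose (each category's arrivals, each
service-time family, each Bernoulli decision, the routine load) draws from
its own substream derived from the replication seed. Two scenarios evaluated
with the same seeds therefore consume identical substreams for common
purposes — common random numbers (CRN) — so paired differences along a sweep
axis reflect the policy change, not noise. Replication $r$ of a scenario
uses seed $s + r$; sweeps, the optimizer and `evaluate_point` share $s$
across scenarios by default.

## Calibration: defaults and rationale

The hospital whose disaster plan motivated this model did not publish its
service-time data, so the shipped `calibration()` is a documented set of
design values — chosen once for clinical plausibility, exposed as data (not
code), and replaceable via JSON. Durations are lognormal (positive,
right-skewed, the standard choice for procedure times):

| Quantity | Default | Why |
|---|---|---|
| Triage | 2 min (cv 0.3) | tag-based color triage is fast |
| Red stabilization | 25 min (cv 0.3) | shock-room primary survey + stabilization |
| Yellow examination | 20 min (cv 0.4) | outpatient trauma workup |
| X-ray / CT | 8 / 15 min (cv 0.3) | room occupancy incl. positioning |
| Red / yellow surgery | 90 / 60 min (cv 0.35/0.4) | damage-control vs. scheduled trauma surgery |
| Transfer out | 20 min (cv 0.5) | hand-over and bed transfer |
| P(surgery) red / yellow | 0.9 / 0.5 | most severe casualties need hemostatic surgery |
| Imaging red | CT 0.9, X-ray 0.1 | polytrauma defaults to whole-body CT |
| Imaging yellow | CT 0.2, X-ray 0.7 | extremity injuries dominate |
| CT-downgrade eligibility | 0.5 | half of CT indications tolerate X-ray triage |
| $d$ red/yellow/green | 0.25 / 0.05 / 0 pts/min | red: death within ~100 min untreated |
| $r$ | 0.5 pts/min | treatment recovers faster than waiting decays |
| $\theta_{red}, \theta_{yellow}$ | 30, 70 | thirds of the score scale |
| Initial $h$ red/yellow/green | 25 / 55 / 85 | consistent with the thresholds |
| Routine OR load | 1 case per 2 h (day), 6 h (evening), 8 h (night) | an ongoing case at a 10 p.m. incident is occasional, not typical |

Task staffing matrices (also calibration data): triage = 1 rotation
physician + 1 general nurse; red stabilization = 1 medical specialist +
1 medical assistant + 1 general nurse; yellow examination = 1 medical
assistant *or* rotation physician + 1 general nurse; imaging = 1 radiology
assistant per machine; red surgery = 2 medical specialists + 1 surgical
nurse + 1 surgical assistant; yellow surgery = 1 medical specialist +
1 surgical nurse. Keeping the surgical assistant out of the stabilization
crew is deliberate: with a single surgical assistant on the night shift, a
shared assistant would serialize stabilization behind 90-minute surgeries
and kill most red patients before first treatment — the assistant's role
here is operating-room support.

Under these defaults the disaster-plan baseline (5/20/50 casualties over
90 min at 10 p.m.) reproduces the qualitative surge signature: the mean red
waiting time for critical treatment lands well above its 120-min benchmark
(the single surgical assistant and the red operating-room chain are the
binding constraints) while yellow waits stay far below 720 min. The
absolute numbers are properties of this calibration, not of the original
hospital's unpublished data.

## What the generator emulates — and what it does not

The synthetic scenarios emulate: surge arrivals with realistic category
mix, progressive re-triage and death, resource contention across staff,
rooms and machines, supervision load of uninjured-but-present patients, and
background routine utilization. They do **not** emulate: intra-hospital
transport times (not a bottleneck in the modeled hospital), downstream
ward/ICU hospitalization, sterile-goods logistics, off-duty staff recall,
inter-patient heterogeneity of service times beyond the lognormal cv, or
correlated injuries. Passing tests therefore demonstrate internal
correctness and directional realism of the mechanism, not calibration to
any specific hospital's data.

## Outcome metrics and replication control

The *waiting time for critical treatment* is surgery start minus arrival for
surgical patients, first-treatment start minus arrival otherwise; patients
who die before their defining event are excluded from the means and counted
as deaths (the alternative — scoring them at infinity — conflates mortality
and delay; both are reported). *Total system time* is exit minus arrival.
Summaries report mean, sample SD, median, min, max and range across
replications, and compliance is the share of eligible patients within their
category benchmark (120/720 min).

"Statistical accuracy of 95% (99%)" is implemented as a sequential stopping
rule: stop at the smallest $n \ge 10$ at which the t-based confidence
interval half-width of the running mean is at most 5% (1%) of its absolute
value. Fixed replication counts are supported alongside. On i.i.d. normal
streams the stopped $n$ agrees with the closed-form
$(z_{0.975}\sigma/(\gamma\mu))^2$ within 10%, and the stopped intervals
cover the true mean within a few points of nominal — optional stopping costs
a little coverage, which is why the pilot minimum exists.

## Sweeps, enumeration and optimization

`factorial_grid()` enumerates level combinations with the first category
varying slowest, so scenario #1 is the all-minimum and the last scenario
the all-maximum staffing; the index↔point mapping is an explicit mixed-radix
bijection. The published three-level grid over the seven staff categories
(shipped as `staff_grid_levels()`) yields $3^7 = 2187$ scenarios.

`optimize_staff()` minimizes total headcount subject to the mean red total
system time staying below a limit (default 200 min), with ties broken by the
smaller constrained metric. The search recombines elite lattice points
(rounding to admissible levels), mutates single coordinates, keeps a tabu
memory of visited points, and — when recombination stalls — scans unvisited
points in index order, so with a budget at least the lattice size it
degenerates gracefully to full enumeration. Acceptance is noise-aware: a
challenger at equal headcount must beat the incumbent by more than its own
confidence half-width, and candidate incumbents are re-evaluated at a larger
replication count. With a noise-free objective the optimizer provably
returns the enumeration optimum whenever its budget covers the space.

## Response-surface toolkit

`fit_ols()` wraps a least-squares fit with the full diagnostic suite used in
response-surface practice: unstandardized and standardized coefficients
($\beta_j = B_j \, s_{x_j}/s_y$), 95% confidence intervals, per-term VIF and
tolerance from auxiliary regressions (exactly 1 on the balanced orthogonal
grid), PRESS via the hat-matrix shortcut
$\sum_i (e_i/(1-h_{ii}))^2$ — identical to brute-force leave-one-out — and
the ANOVA $F$, which satisfies
$F = \frac{R^2}{1-R^2}\cdot\frac{n-p-1}{p}$ identically.
`pareto_standardized_effects()` ranks terms by $|t|$ (equivalent to $|\beta|$
on orthogonal designs) against the two-sided critical $t$;
`stepwise_build()` adds the candidate with the largest adjusted-$R^2$ gain
per step and stops when none improves, with non-hierarchical entry allowed
by default (so a strong quadratic may enter before weaker main effects) and
a hierarchy switch. The four normality tests are Anderson–Darling,
Lilliefors, Shapiro–Francia and Jarque–Bera — a moment-based, two EDF-based
and one correlation-based test; heteroscedasticity is checked by a
Breusch–Pagan auxiliary regression of squared residuals on fitted values.
`reference_surface()` ships a fixed main-effects surface over the staff grid
as a validation oracle: generating a response from it and refitting must
recover every coefficient to numerical precision, and at the noise level
matching its residual scale the dominant standardized effects are the
radiology assistants followed by the rotation physicians.

## Numerical choices and degenerate inputs

Threshold crossings are solved in closed form on the piecewise-linear score
trajectory; a downward crossing *at* a threshold classifies into the more
urgent category (the limit from below). Ties in the event calendar resolve
in insertion order, deterministically. `scale_load()` rounds half-up
per category, with explicit per-category overrides for published sweep rows
that do not follow a uniform rounding. Zero-probability branches (no
surgery, no imaging), empty categories, zero routine intensity and
effectively infinite resources are all exercised in the test suite; a
structurally starved scenario (a required staff category at zero) is
rejected at validation, and a dynamically starved run is stopped by an
event-cap guard rather than spinning.

## Problem sizes used in validation

The shipped checks run on one CPU in a few minutes: 200 CRN replications
per scenario for the directional analyses (arrival windows 45/90/120/200,
the six casualty-load rows, staffing extremes), 20 replications × 5000
arrivals for the Erlang-C comparison (the M/M/c reduction of the engine
matches the analytic mean wait within Monte-Carlo error), 1000 refits for
confidence-interval coverage, 50 random spaces for optimizer-vs-enumeration,
and a 3³ staff subgrid for the simulation-based optimization check. Larger
runs (e.g. thousands of replications per scenario or the full 2187-scenario
enumeration on the simulator) scale linearly and are a matter of patience,
not code.

## Known limitations

The calibration is illustrative, not fitted to data; absolute waiting times
should not be quoted against any real hospital. The score dynamics are
piecewise-linear with shared rates per category, which is a coarse proxy for
physiology. Staff do not fatigue, travel or hand over; service times are
independent across stages; the supervision-ratio cap described above departs
from a literal reading of the ratios when green patients outnumber what the
shift can supervise. The optimizer is a heuristic: outside the
budget-covers-space regime it carries no optimality guarantee, only the
noise-aware acceptance and the enumeration oracle to check against.
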