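---
title: "Methods: an offline engine for wearable-device trial management"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an offline engine for wearable-device trial management}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(weartrial)
```

## What the engine models

Behavioral intervention trials that instrument participants with consumer
wearables (an activity tracker, a connected scale, a diet-logging app)
need more than a data pipe: they screen thousands of applicants through a
multi-phase funnel, randomize the survivors with covariate balance,
synchronize device data daily under vendor API quotas, watch the incoming
streams for lapses in self-monitoring, and report trial flow in CONSORT
terms. `weartrial` implements that whole loop as a headless engine whose
every stage can run against synthetic data, so the behaviour of the
machinery — not any particular cohort — is what gets tested.

The package is organized around an **event-sourced registry**: every
consequential action (registration, questionnaire submission, an
eligibility decision, randomization, a withdrawal, an assessment, a
payment) appends an immutable `StudyEvent`, and `replay_events()` rebuilds
the participant registry from the log alone. CONSORT flows and retention
reports are pure functions of the log, which makes every report
replayable and auditable. Device-account tokens are deliberately kept out
of the event log and out of every report.

## Screening

Eligibility criteria are declarative: a named predicate over one answer
or over a derived quantity (the only built-in derivation is BMI from
self-reported height and weight, using exact unit conversions
1 lb = 0.45359237 kg and 1 in = 0.0254 m). Numeric bounds are inclusive
on both ends — an applicant aged exactly 18, or with BMI exactly 27 or
43 kg/m², is eligible — and the comparison carries a `1e-9` tolerance so
that float rounding in the unit conversion can never exclude a boundary
case. A criterion whose source answer is absent yields
`needs_manual_review` rather than a silent failure; phase-3 outcomes
(the short food-diary review) always require coordinator sign-off. The
phase-3 pass threshold defaults to all 5 days of a 5-day diary window
logged, with an optional entries-per-day minimum that is off by default,
since only the task — not the cut-off — is fixed by convention.

## Randomization by minimization

`allocate()` implements Pocock–Simon minimization: for each arm, the
engine hypothetically adds the incoming participant to that arm and sums,
over prognostic factors, the spread of the per-level arm counts
(`range`, the default, is max − min; `variance` is the population
variance), weighted per factor (default weight 1). With probability
`assignment_prob` (default 0.8, the common biased-coin choice) the arm
with the smallest score is chosen — ties broken by a fair draw, never by
arm order, to avoid allocation bias — otherwise a uniform draw among the
remaining arms. `assignment_prob = 1` gives deterministic minimization,
which with a single factor reduces to marginal balancing with
`|n_A − n_B| ≤ 1` inside every level. All draws come from R's seeded RNG
stream, so a seed plus an allocation order reproduces the identical arm
sequence; the per-allocation audit log records levels, per-arm scores,
the chosen arm and the coin draw. Prognostic factors are entirely
config-driven; the shipped fixtures minimize over sex and BMI category.

## Synchronization under an hourly quota

Vendor APIs meter calls per account per hour (quota 100 here), and the
study's look-back is bounded: `pull_window()` returns the half-open range
of the last 7 complete calendar days in the study timezone (calendar
arithmetic, so DST transitions still yield exactly 7 dates). The cost
model is one API call per (endpoint, day); endpoints are `activity`
(steps + heart rate), `sleep`, `food`, and `weight`. The quota is
enforced as a **rolling** 3600-second window — the conservative reading
of "per hour" — not calendar-hour buckets: `acquire()` grants up to the
remaining quota and defers the rest with a next-eligible time, and
re-planning the same day is idempotent. Ingestion is idempotent on exact
duplicates; records sharing a key (`participant, metric, timestamp,
source`) but disagreeing in value are conflicts resolved
last-writer-wins on retrieval time. Weight is stored internally in
kilograms; alert thresholds are stated in pounds, as trial protocols
write them. A push/subscription mode is defined only as an interface and
deliberately unimplemented.

## Adherence alerts

Four rules are scanned daily per randomized, non-withdrawn participant:
no food entries, no weight records, or no tracker data (steps, heart
rate, sleep jointly — a worn tracker produces all three) on the 7
calendar dates ending at the scan date; and a recorded weight change
strictly exceeding 5 lb between two records at most 7 consecutive days
apart. Design choices worth stating explicitly:

* the change rule compares **recorded** values (max pairwise difference),
  not a smoothed trajectory, fires in either direction, and reports the
  direction in the details;
* the strict `> 5 lb` comparison carries a `1e-9` lb tolerance so that a
  change of exactly 5.0 lb, stored in kg and converted back, never fires;
* only windows whose later record falls inside the current 7-day scan
  window are considered, so a point-in-time scan never re-reports ancient
  history and scanning any prefix of a stream agrees with the full-stream
  scan (no look-ahead);
* under daily scanning, a persisting gap re-raises on a 7-day cool-down
  (configurable) instead of every day.

The whole rule set is verified against an independent brute-force
sliding-window oracle on a thousand seeded random streams.

## Feedback messages and usage

Feedback-arm participants are scheduled exactly `messages_per_day`
(default 3) messages per day, each tagged with the self-monitoring
category that selected its template (cycling over the categories with
data present that day; a generic template when none). Message content is
a pluggable hook — tailoring logic is out of scope. Statuses move
`delivered → opened` only, `missed` is terminal, and per-day counts
partition: delivered + opened + missed = scheduled.

## Reporting conventions

The retention denominator for an assessment excludes participants who
officially withdrew before it: `denominator = randomized − withdrawn
before`. This rule is reverse-engineered from the published worked
example (502 randomized, 4 withdrawals before 6 months giving /498, 9
before 12 months giving /493). Rates are rounded **half-up** to two
decimals, which reproduces the published 12-month figure exactly
(100·394/493 = 79.9188… → 79.92). Note that the published 6-month figure
of 84.93% is not reproducible under any standard rounding — 100·423/498
= 84.9398… rounds to 84.94 — so the engine reports 84.94 and does not
force the printed value.

```{r retention}
retention(502, 9, 394, label = "12mo")
retention(502, 4, 423, label = "6mo")
```

## The synthetic cohort and streams

The generator's defaults are the study conditions the engine is exercised
under, chosen once:

* **cohort** (`cohort_params()`): 1741 registrants (the documented
  phase-1 volume); age ~ Normal(45, 12) truncated at 16 so minors occur;
  BMI ~ Normal(33, 6), straddling both the 27 and 43 boundaries (a
  Uniform(20, 50) option exists for measure-theoretic sanity checks);
  95% smartphone ownership; 3% pregnancy among female respondents;
  downstream pass probabilities 0.725 (phase-2 medical), 0.653 (phase-3
  diary), 0.849 (baseline attendance), matching the documented funnel
  ratios. Phase-1 eligibility is *not* a coin flip — it emerges from the
  generated demographics hitting the declared criteria.
* **streams** (`stream_params()`): steps negative-binomial (mean 7500,
  size 8); heart rate and sleep normal; food entries 1 + Poisson at meal
  hours; weight = baseline + linear trend + noise, in pounds, stored in
  kg. Adherence is an alternating renewal process per data source
  (adherent and missing runs with geometric lengths), which is what
  produces the multi-day gaps the alert rules exist to catch. Records
  surface at the vendor a day after measurement plus an optional
  geometric upload delay, emulating connectivity problems.
* **mock vendor server** (`mock_device_server()`): answers
  (account, endpoint, date) queries, refuses calls beyond the per-account
  rolling-hour quota with an explicit signal the scheduler honours, and
  hides records whose upload delay has not elapsed.

What the generator does **not** emulate: intraday waveforms, nutrient
composition, device firmware quirks, seasonal behaviour, or informative
missingness correlated with outcomes. Passing tests therefore certify the
machinery — funnel accounting, balance, quota safety, alert logic,
determinism — not any clinical property of real cohorts. The published
funnel counts (1741/1248/905/591/502) depend on a real population and are
used only as volume fixtures and worked-example arithmetic.

## Problem sizes and numerics

The shipped test suite and the acceptance script run the full pipeline at
1741 registrants with a 14-day stream horizon and a single
synchronization cycle for funnel checks, and at 150 registrants with two
cycles for the byte-determinism check; balance comparisons use 200 paired
replicates of 500 allocations. These sizes were chosen so the properties
under test (conservation, quota invariants, stochastic dominance of
minimization, determinism) are decidable with comfortable margins while a
complete run stays in the minutes range on one core. All randomness flows
from a single seed; two runs at the same seed produce byte-identical
report files.

## Known limitations

Live vendor OAuth, push notification transport, message-content
tailoring, e-signature capture, and geographic mapping are out of scope
by design. The one-call-per-(endpoint, day) cost model is an assumption
about how vendor quotas meter; if a vendor meters jointly across
endpoints the planner is conservative, if per sub-resource it is
optimistic. Coordinator authentication and encryption at rest are not
modelled. The registry intentionally does not reconcile the documented
discrepancy between 502 randomized and two arms of 250.
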