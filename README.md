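# weartrial

An offline, headless engine for running the data-acquisition and
trial-management loop of wearable-device behavioral trials: multi-phase
screening with adaptive questionnaires, covariate-adaptive randomization
by minimization, rate-limit-aware synchronization of wearable and smart-
scale data, rule-based adherence alerting, and CONSORT-style funnel and
retention reporting. A seeded synthetic-data module — cohorts,
questionnaire answers, observation streams with realistic missingness,
and a mock vendor server with an hourly API quota — stands in for live
device vendors, so the entire pipeline runs deterministically with no
network access.

It is aimed at trial methodologists and research-software engineers who
need the machinery of such a study (funnel accounting, allocation
balance, quota-safe scheduling, alert logic) to be testable apart from
any real cohort.

## The methods at the core

* **Event sourcing.** Every action appends an immutable `StudyEvent`;
  `replay_events()` rebuilds the registry from the log, and all reports
  are pure functions of it.
* **Pocock–Simon minimization.** Arriving participant with factor levels
  $(l_f)_f$ is assigned, with biased-coin probability $p = 0.8$, to the
  arm $a$ minimizing
  $\sum_f w_f \, \mathrm{spread}\big(n_{f,l_f,\cdot} + e_a\big)$,
  where the spread is max − min (or population variance) of the
  hypothetical per-arm counts at the participant's level; ties break by
  fair draw. With $p = 1$ and one factor, $|n_A - n_B| \le 1$ in every
  level.
* **Rolling-hour quota.** At most 100 granted API calls per account in
  any sliding 3600-s window, one call per (endpoint, day), pull window =
  the last 7 calendar days; excess calls defer, never drop.
* **Adherence rules.** Alerts for 7 consecutive days without food,
  weight, or tracker data, and for a recorded weight change strictly
  exceeding 5 lb within any ≤ 7-day span — checked against a brute-force
  sliding-window oracle in the tests.
* **Withdrawal-adjusted retention.** rate = 100 · completers /
  (randomized − withdrawn before), rounded half-up to 2 decimals.

## Worked example

```r
library(weartrial)
sim <- simulate_study(seed = 7, cohort = cohort_params(n = 200),
                      streams = stream_params(days = 21), sync_cycles = 3)
print(sim$flow)
#> CONSORT flow
#>          phase entered eligible ineligible pending
#>  phase1_screen     200      145         55       0
#>  phase2_screen     145       99         46       0
#>  phase3_screen      99       64         35       0
#>       baseline      64       54          0      10
#> randomized: 54
#>          arm randomized
#>           SM         27
#>  SM+feedback         27
```

Of 200 synthetic registrants, 145 pass the automatic phase-1 screen
(age ≥ 18, BMI 27–43 kg/m², smartphone), the funnel narrows through the
medical screen and the coordinator-reviewed 5-day food diary, 54 attend
baseline and are randomized — minimization keeps the arms at 27/27 and
balanced within each sex and BMI-category level. The pipeline then
generates device streams, syncs them through the quota-aware scheduler
against the mock vendor server, scans alerts, and simulates assessments:

```r
print(sim$retention)
#>   label randomized_n withdrawn_before completers denominator rate_percent
#> 1   6mo           54                4         45          50        90.00
#> 2  12mo           54                9         31          45        68.89

retention(502, 9, 394, label = "12mo")
#> retention [12mo]: 79.92% (394/493; randomized 502, withdrawn before 9)
```

The second call is the engine's retention arithmetic on a published
worked example: 502 randomized, 9 official withdrawals before the
12-month assessment, 394 completers — 79.92%.

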