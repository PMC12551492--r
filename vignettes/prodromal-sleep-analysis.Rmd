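---
title: "Detecting prodromal sleep disturbances in single-case bipolar time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting prodromal sleep disturbances in single-case bipolar time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prodromewatch)
```

## The scientific question

Sleep disturbance is a diagnostic criterion of both manic and depressive
episodes in bipolar disorder, and retrospective self-report suggests it is
among the most common early symptoms of an oncoming episode. `prodromewatch`
implements a replicated single-case pipeline for asking that question
prospectively: given 180 days of continuous wrist actigraphy, a morning
sleep diary, a daily mood EMA (a 0–100 Life Chart self-rating plus a set of
VAS mood items) and weekly symptom scales (ASRM for mania, IDS-SR for
depression), did any objectively scored sleep variable change during the
two weeks preceding a mood episode — and did sleep change before mood?

Each patient is analysed entirely against their own baseline. There is no
group model: the unit of analysis is one variable of one person's 180-day
record.

## Pipeline overview

1. **Sleep scoring** (`score_night`, `nights_to_daily_series`): epoch
   activity counts + diary → seven daily sleep variables.
2. **Episode detection** (`detect_manic_episodes`,
   `detect_depressive_episodes`): weekly scales + daily LC-self →
   episode intervals, each with a start week and a 14-day prodromal window.
3. **Stable period** (`select_stable_period`): the earliest 35-day
   symptom-quiet window ending at least two weeks before the episode.
4. **Extreme values** (`compute_limits`, `flag_extremes`): Shewhart
   individuals charts with limits at the stable-period mean ± 3 SD.
5. **Mean shifts** (`detect_mean_shifts`): least-squares changepoint
   segmentation with minimum segment size 7, BIC model selection, a supF
   existence test and bootstrap confidence intervals on break dates.
6. **Synthesis** (`run_pipeline`, `label_changes`, `temporal_order`,
   `rate_comparison`): per-variable change labels in the prodrome and start
   week, a sleep-versus-mood order verdict, and a prodromal-versus-stable
   event-rate comparison.

## Time conventions

All night times live on a *noon-anchored timeline*: hours since the noon
preceding the night (23:30 → 11.5, 07:30 → 19.5). Nights crossing midnight
are monotone, differences are plain subtraction, and a night's calendar
date is its morning. This is the standard chronobiology trick for avoiding
mod-24 wraparound; `compute_cpd` is invariant to shifting all times by a
constant, which the test suite checks.

Study weeks are aligned so week *w* covers days 7(w−1)+1…7w. Because the
weekly scales rate the *past* week, the first week with elevated scores is
the week the episode *started*; the prodrome is the 14 days before it, the
start week the 7 days from the start day. Day windows are closed; an event
on the start day belongs to the start week, not the prodrome.

## Sleep scoring

The rest period is taken from the diary (`lights_off` to `get_up`), snapped
outward to epoch boundaries. Within it each 1-minute epoch gets a weighted
activity score `S = Σ w_k c_{t+k}`, k ∈ [−2, 2], with weights
(0.04, 0.20, 1.00, 0.20, 0.04), and is scored wake when `S > 40` counts.
This is a Cole–Kripke-family rule; the weights and threshold are arguments
of `score_sleep_wake`, since count-scaled thresholds are device-dependent.
Sleep onset is the start of the first run of ≥ 10 consecutive sleep-scored
minutes, offset the end of the last such run (`onset_run_min`
configurable). Derived variables follow the usual actigraphy definitions:

* duration = minutes between onset and offset (WASO is counted *within*
  duration, not subtracted from it);
* SOL = minutes from lights-off to onset. The diary records both
  lights-off and try-to-sleep times and "bed time" is ambiguous between
  them, so the reference is a flag (`sol_reference`), defaulting to
  lights-off;
* WASO = wake-scored minutes strictly between onset and offset;
* efficiency = (duration − WASO) / minutes in bed (lights-off to get-up);
* midsleep = onset + (offset − onset)/2.

The composite phase deviation (CPD) combines mistiming (midsleep minus the
chronotype-ideal midsleep) and irregularity (midsleep minus yesterday's
midsleep) as `sqrt(mistiming² + irregularity²)`, in hours. When the
previous night is unscorable we use the mistiming term alone rather than
propagating a missing value; this keeps day 1 defined and is the one
deliberate departure from strict consecutive-night pairing (configurable by
simply recomputing from the midsleep series if strict pairing is wanted).

Nights with more than 20% missing epochs in the rest window
(`missing_tolerance`) or no qualifying sleep run are unscorable and become
missing days downstream.

## Episode rules and the stable period

Manic episodes require ASRM > 5 in ≥ 2 consecutive weeks with LC-self > 50
on ≥ 75% of days in those weeks; depressive episodes require IDS-SR > 25 in
≥ 3 consecutive weeks with LC-self < 50 on ≥ 75% of days. Inequalities are
strict (LC exactly 50 counts for neither side); the 75% denominator uses
non-missing days only, since EMA gaps are routine.

The stable period is the earliest week-aligned 35-day window that is
symptom-quiet, has lower LC-self SD than the full study, and ends ≥ 15 days
before the episode start day. "Symptom-quiet" is read as *containing no
week that belongs to a run of two consecutive elevated weeks* — the
episode-defining pattern — so a window adjacent to such a run is rejected
even when only one member of the pair falls inside it. A stricter reading
(no single elevated week at all) is available via `strict = TRUE`. SD is
used as the Life-Chart variability measure; it is the conventional default
and nothing downstream depends on the choice of dispersion statistic.
Patients with no qualifying window are excluded, mirroring clinical
practice for this design.

## Control charts

Limits are the stable-period sample mean ± 3 sample SDs (n − 1
denominator; with 35 observations the population-SD alternative differs by
< 1.5%). Flagging is strict (points exactly on a limit are inside), there
are no run rules, and charts whose stable-period SD is zero or which have
fewer than 10 non-missing stable days are suppressed with a warning rather
than emitting degenerate limits.

## Changepoints

The piecewise-constant fit with *m* breaks minimising the residual sum of
squares is computed exactly by dynamic programming over the non-missing
observations, with every segment required to span ≥ 7 observed days. Ties
are broken toward the earliest break. The test suite verifies the DP
against exhaustive enumeration of all admissible break placements on small
series.

Three choices are deliberately pragmatic where the field's conventions are
loose:

* **Model selection**: BIC with `m = 0` admissible, penalty
  `p = 2m + 2` (segment means, break positions, one variance). BIC-chosen
  `m` is affine-invariant in the data, which the tests check.
* **Existence test**: the supF statistic (max single-break F over
  admissible positions), with a permutation null (default 999 permutations)
  rather than the asymptotic supF distribution — exact level at these
  sample sizes (n ≈ 70–120 days) and trivially reproducible under a seed.
  Mean shifts are only reported when p < 0.05 (`supf_alpha`), and the gate
  is applied identically to sleep and mood series.
* **Break-date CIs**: residual bootstrap within the two flanking segments
  (rebuild from fitted means + resampled residuals, re-estimate the single
  break, take the quantile interval of re-estimated break days, clip to
  the flanking segments). Asymptotic argmax-distribution intervals behave
  poorly at n ≈ 70; the bootstrap interval's coverage is measured directly
  by simulation (≥ 85% nominal-95% coverage for a 2-SD shift) instead of
  assumed. Break days are reported as the first day of the new regime, and
  the CI always contains the point estimate.

Missing days are dropped before segmentation and indices mapped back to
study days, so a reported break day is always an observed day.

## Labels, order, rates

Every extreme value and gated mean shift in the stable-start → episode-end
window becomes an event tagged sleep/mood. Per variable × mechanism ×
window the label is *increase*, *decrease*, *unstable* (both directions
observed), or *none*. The temporal-order verdict is `indeterminate`
whenever any sleep-event CI overlaps any mood-event CI (extreme values
carry the degenerate CI [day, day]); `sleep_first`/`mood_first` require
strict separation of all CIs. The rate comparison (events per observed day,
prodrome vs stable, with an exact Poisson interval from
`stats::poisson.test`) is descriptive only — no verdict is attached, since
single-case event counts are tiny.

## What the synthetic cohort does and does not emulate

Because the clinical records this design targets cannot be shared, the
package ships a generator whose output carries exact ground truth:

* Daily sleep variables are Gaussian around fixed baselines (sleep onset
  23:30 ± 0.75 h, offset 07:30 ± 0.75 h, duration 450 ± 45 min, SOL 20 ±
  10 min, efficiency 0.88 ± 0.04, WASO 30 ± 15 min, CPD 1.0 ± 0.5 h) —
  plausible magnitudes for a euthymic adult, chosen once as free
  parameters, not claims about any dataset.
* Scripted episodes force the weekly scales over their thresholds in
  episode weeks and clip them below the thresholds elsewhere, and drive
  LC-self to the qualifying side of the midline on ~90% of episode days —
  a margin above the 75% rule so that self-consistency (every scripted
  episode is re-detected) is exact, not statistical. Mood items shift by
  1.5 baseline SDs in the polarity-appropriate direction for the length of
  the episode.
* Injections express magnitudes in stable-period SD units. A mean shift
  adds `magnitude × SD` from the injection day to the episode end; an
  extreme value *sets* its day to `baseline mean + magnitude × SD`, so the
  scripted magnitude is exactly the deviation the chart should see (adding
  the offset to a random draw instead would make a "+3.5 SD" injection
  exceed the +3 SD limit only ~69% of the time and the ground truth fuzzy).
* Epoch-level nights draw counts from negative binomial distributions
  (daytime and wake-bout mean 250 counts/epoch, rest mean 5, variance =
  2 × mean): enough contrast for scoring-recovery tests, with no attempt to
  model real actigraphy microstructure (sleep cycles, artefacts, naps,
  device formats).

Passing tests on this cohort therefore demonstrate that the *machinery*
recovers known structure at realistic noise levels — not that real
patients' sleep behaves like Gaussian baselines with step changes.

## Validation problem sizes

The shipped validation (test suite and `scripts/acceptance.R`) uses: 50
random series (n ≤ 24) for the DP-vs-enumeration oracle; 200 replicates of
a 2-SD shift at day 40 of n = 70 for changepoint error, CI coverage and
the pure-noise false-alarm rate; 10,000 i.i.d. Gaussian evaluation days
(100 independent 35-day stable samples × 100 days) for the chart's null
flag rate; 100 synthetic nights for sleep-scoring recovery; and a
20-patient scripted cohort for end-to-end label recovery. End-to-end runs
use 199 permutations and 150 bootstrap replicates per series; the package
defaults (999 / 500) are what an analysis of real data should use.

## Known limitations

* The epoch sleep/wake rule is a declared stand-in for the original
  device-specific scorer, which is not published as a formula; weights,
  threshold and run length are configurable for that reason.
* The supF gate tests for a *single* shift; series whose only structure is
  two opposite shifts of equal size can in principle defeat it, although
  the BIC stage can still represent them once the gate passes.
* Multiple episodes per patient are analysed independently against their
  own stable periods; the first detected episode is used by
  `run_pipeline`.
* Circadian variables that need ≥ 1-week windows (IS, IV, L5/M10) are out
  of scope by design; CPD is the only circadian marker because it is
  defined per day.
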