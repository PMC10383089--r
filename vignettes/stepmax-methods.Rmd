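---
title: "Methods: maximum free-living n-minute step counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: maximum free-living n-minute step counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stepmax)
```

## Why maximum free-living stepping?

Clinic-based walk tests (two-minute and six-minute walks, gait-speed
tests) measure what a person *can* do, but only under supervision, on a
good day, in a corridor. Event-format records from thigh-worn activity
monitors capture what a person actually does over a week of daily life.
The quantity this package computes — the largest number of steps
accumulated in any window of *n* minutes across a person's valid wear
days — is a free-living analogue of those capacity tests: it looks for
the person's best sustained stepping effort wherever in the week it
happened.

Two design choices follow from that framing:

* **The window slides over all placements.** A fixed grid (say, clock
  minutes) would miss efforts that straddle grid boundaries. The search
  here is exact over every real-valued window start.
* **An upright break ends the effort.** Sitting or lying down is a
  deliberate interruption; steps taken after a sedentary transfer inside
  the window belong to a different effort. Quiet standing, by contrast,
  is part of normal intermittent walking and does not stop the count.

## The data model

A stream is a contiguous, non-overlapping sequence of events for one
subject, each `sedentary`, `standing`, or `stride`, with a start time
and a duration. A stride is one gait cycle and always carries exactly
two steps. From the stream the package derives:

* **stepping bouts** — maximal runs of adjacent strides
  (`merge_strides_to_bouts()`), each with a duration, step count and
  cadence;
* **upright containers** — maximal non-sedentary runs
  (`build_upright_containers()`), the standing-plus-stepping envelopes
  within which bouts occur.

`validate_events()` enforces the invariants (known activity codes,
positive durations, two steps per stride, contiguity within a
millisecond tolerance) and can bridge sub-second recording gaps.

## The window search

For a window $[w, w + n)$:

1. a stride is counted when its **midpoint** lies in the window, so a
   partially covered bout contributes exactly the strides genuinely
   inside and counts stay integral;
2. if any sedentary event starts inside the window, counting stops at
   the first such onset (`truncated_by_break`);
3. alongside the count, the window reports its **stepping time** (summed
   stride time of the counted strides, clipped to the window) and
   **accumulation time** (first counted stride start to last counted
   stride end, clipped), so
   $0 \le \text{stepping} \le \text{accumulation} \le n$ always holds.

### Exactness of the anchored search

As $w$ varies, the count changes only when a stride midpoint or a break
crosses a window edge, so the count as a function of $w$ is piecewise
constant. For any window, let $m$ be the midpoint of its first counted
stride; the window anchored *at* $m$ counts a superset of the original
window's strides (it keeps every later midpoint up to the same break or
end, which can only move right). Hence the finite set of windows
anchored at stride midpoints always contains a maximum, and
`max_n_minute_step_count()` evaluates exactly that set. Ties are broken
toward the smallest accumulation time (the most concentrated effort),
then the earliest window, making results deterministic.

`brute_force_max()` is the deliberately naive reference: it evaluates
every window start on a dense fixed grid across the stream extent and
knows nothing about where counts change. For *arbitrary* real-valued
event timings a maximal count can in principle be achieved only on an
interval of window starts narrower than the grid step, so grid agreement
is not guaranteed in general. But when all event durations sit on a
lattice of spacing $2q$ (stride midpoints then sit on the $q$ lattice),
every breakpoint of the count function is on the $q$ lattice, every
achievable count is achieved on an interval at least $q$ wide, and a
grid of step $q/2$ or finer cannot miss it. Real monitors record at
finite resolution, so lattice timing is the realistic case; the
generator exposes it as `quantize_s`. The test suite exploits this:
thousands of monitor-resolution streams must match the brute-force
reference *exactly*, while an independent slow per-anchor implementation
covers continuous-time streams.

## From windows to cohort measures

* **Valid days** (`flag_valid_days()`): a day counts only with strictly
  more than 10 h of classified data *and* strictly more than 500 steps.
  A subject's measure at each duration is the maximum over valid days
  (`max_over_period()`), with the same tie-breaks.
* **Step accumulation rate**: the maximum count divided by the window
  length in minutes — comparable across durations (a rate that falls
  with duration is the expected fatigue/opportunity signature).
* **Availability** (`stepping_proportion_table()`): the proportion of
  subjects whose best window at duration $n$ was at least a given
  fraction stepping. By set inclusion this is monotone in the threshold;
  subjects with no valid days stay in the denominator.
* **Bout availability** (`bouts_per_day()`): mean daily count of single
  bouts at least as long as the window (duration $\ge n$, inclusive).
* **Distribution checks** (`distribution_stats()`): small-sample
  corrected skewness and excess kurtosis, with the conventional rule
  that a distribution is treated as normal when $|G_1| < 2$ and
  $G_2 < 7$.
* **Cohort tests** (`cohort_tests()`): Pearson correlation between
  per-subject maxima at two durations, a paired t test on the
  corresponding rates, and optional sex/month group comparisons.

## The synthetic generator

No public event-level dataset exists at the scale needed to exercise
this pipeline, so the package generates its own
(`generator_config()`, `generate_subject()`, `simulate_study()`), and —
crucially — records its own ground truth (every bout, every daily tally)
as it builds each stream, independently of the analysis code.

Each day is a 16 h waking window (07:00–23:00) filled by alternating
log-normal sedentary blocks (median 15 min) and upright containers; a
container holds a Poisson number (mean 1.7) of bouts separated by short
log-normal standing gaps; a bout is a run of uniform strides at a
truncated-normal cadence (mean 105, sd 12, floor 40 steps/min) with a
log-normal target duration (median 25 s, heavy right tail). 35% of
subjects are "low-opportunity": their bout durations are truncated below
300 s, which is what makes full 6-minute stepping rare at cohort level
while 2-minute stepping stays common — the qualitative pattern that
motivates using short windows for population work. Days are padded to
full calendar days so multi-day streams stay contiguous; cohorts rotate
start months so seasonal strata are populated.

What the generator does **not** emulate: circadian structure within the
waking day, day-to-day autocorrelation, cadence variation within a bout,
wear-time failure, and non-wear misclassification. It is a test harness
with known truth, not a population model; its defaults are fixed study
conditions, and the test suite treats them as such rather than tuning
them to outcomes.

## Problem sizes and budgets

The sizes used in the tests are the package's own choices, picked to
make the properties sharp while keeping a full run a few minutes on one
CPU: 1000 monitor-resolution streams (four durations each) for the
brute-force comparison, 200 streams for monotonicity and cover-bound
properties, 100 subjects for exact manifest recovery, and a 500-subject
simulated study for the cohort-level availability ordering. The
command-line front end (`inst/cli/stepmax.R`) and `run_simulate()` /
`run_compute()` / `run_report()` wire the same steps together on disk.
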