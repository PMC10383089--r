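# stepmax

Maximum free-living *n*-minute step counts from event-based
physical-behaviour data.

Thigh-worn activity monitors export a person's week as a stream of
timed events — sedentary, standing, or stride (one gait cycle, two
steps). `stepmax` searches that stream for the person's best sustained
stepping effort: the largest number of steps accumulated in **any**
window of *n* minutes across their valid wear days. This is a
free-living analogue of clinic walk tests (two- and six-minute walks),
measured where life actually happens.

The core rules:

* the window slides over **all** real-valued placements, not a clock
  grid, and the search is exact (windows anchored at stride midpoints
  provably contain a maximum);
* a stride is counted when its **midpoint** falls in the window, so
  counts stay integral for partially covered bouts;
* a sedentary transfer inside the window **truncates** the count —
  sitting down ends the effort, while quiet standing does not;
* ties break toward the most concentrated effort (shortest
  accumulation time), then the earliest window, so results are
  deterministic.

On top of the search sit the population measures: strict wear-day
validity (> 10 h of data **and** > 500 steps), per-subject maxima and
step accumulation rates across a grid of durations (30 s to 10 min),
stepping-proportion availability tables, daily bout availability,
distribution characterisation (corrected skewness/kurtosis with the
|skew| < 2, kurtosis < 7 normality rule), and cohort comparisons.
A configurable synthetic stream generator with recorded ground truth
makes every stage testable end to end; a brute-force grid search acts
as an independent oracle for the window search.

## Worked example

Simulate one subject's week, derive bouts, and find the best 2-minute
window:

```r
library(stepmax)

g <- generate_subject(generator_config(seed = 42), "S0001")
g$events
#> # A tibble: 17,727 × 5
#>   subject_id start               duration_s activity  steps
#>   <chr>      <dttm>                   <dbl> <chr>     <int>
#> 1 S0001      2023-01-02 00:00:00   29359.   sedentary     0
#> 2 S0001      2023-01-02 08:09:19      26.7  standing      0
#> 3 S0001      2023-01-02 08:09:45       1.07 stride        2
#> 4 S0001      2023-01-02 08:09:46       1.07 stride        2
#> 5 S0001      2023-01-02 08:09:48       1.07 stride        2
#> # ℹ 17,722 more rows

merge_strides_to_bouts(g$events)
#> # A tibble: 453 × 8
#>   subject_id bout_id start               end                 duration_s
#>   <chr>        <int> <dttm>              <dttm>                   <dbl>
#> 1 S0001            1 2023-01-02 08:09:45 2023-01-02 08:09:53       7.46
#> 2 S0001            2 2023-01-02 08:10:24 2023-01-02 08:12:35     132.
#> 3 S0001            3 2023-01-02 08:12:54 2023-01-02 08:13:01       6.50
#> # ℹ 450 more rows

max_n_minute_step_count(g$events, 120)
#> # A tibble: 1 × 6
#>     n_s window_start        step_count stepping_time_s accumulation_time_s
#>   <dbl> <dttm>                   <int>           <dbl>               <dbl>
#> 1   120 2023-01-04 16:39:18        270            120.                 120
#> # ℹ 1 more variable: truncated_by_break <lgl>
```

The subject's best 2-minute effort was 270 steps, stepping for the
full window. The per-subject summary applies day validity and compares
durations:

```r
subject_summary(g$events, durations = c(120, 360))$summary
#> # A tibble: 2 × 11
#>   subject_id   n_s step_count accumulation_rate stepping_time_s
#>   <chr>      <dbl>      <int>             <dbl>           <dbl>
#> 1 S0001        120        270               135            120.
#> 2 S0001        360        666               111            349.
```

The 2-minute rate (135 steps/min) exceeds the 6-minute rate (111), the
expected signature of sustained effort being harder to find. At cohort
scale the availability table shows why short windows suit population
work — almost everyone has a fully stepped 2-minute window somewhere in
their week, far fewer a 6-minute one:

```r
sim <- simulate_study(generator_config(seed = 42), 30,
                      durations = c(120, 360))
stepping_proportion_table(sim$summaries)
#> # A tibble: 8 × 4
#>     n_s threshold n_subjects proportion
#>   <dbl>     <dbl>      <int>      <dbl>
#> 1   120      1            30      0.5
#> 2   360      1            30      0.267
#> 3   120      0.95         30      0.967
#> 4   360      0.95         30      0.633
#> 5   120      0.9          30      1
#> 6   360      0.9          30      0.833
#> 7   120      0.8          30      1
#> 8   360      0.8          30      0.967

cohort_tests(sim$summaries)$rate_comparison
#> # A tibble: 1 × 10
#>     n_a   n_b mean_rate_a sd_rate_a mean_rate_b sd_rate_b     t    df          p
#>   <dbl> <dbl>       <dbl>     <dbl>       <dbl>     <dbl> <dbl> <dbl>      <dbl>
#> 1   120   360        129.      4.84        113.      10.2  8.13    29    5.82e-9
```

## Command line

`inst/cli/stepmax.R` wires the same steps together on disk:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "stepmax.R", package = "stepmax"))') \
    simulate --out raw/ --seed 7 --subjects 20
Rscript .../stepmax.R compute --input raw/ --out results/
Rscript .../stepmax.R report  --summaries results/subject_summaries.csv --out results/
```

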