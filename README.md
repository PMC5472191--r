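# antisaccade

Analysis of eye-movement recordings from the interleaved pro-/anti-saccade
gap task, the standard probe of voluntary saccade inhibition used to
characterize oculomotor deficits in basal-ganglia disorders such as
Huntington's disease.

On a **pro** trial the participant looks toward a suddenly appearing
peripheral stimulus; on an **anti** trial they must suppress that reflex
and look to the stimulus's mirror location. A 200 ms gap between fixation
offset and stimulus onset shortens latencies and raises the pressure on
inhibition. The package takes monocular gaze traces (500 Hz by default)
plus trial event logs and computes:

- **Saccade detection** — onset/offset where 2-D eye velocity crosses
  30 deg/s (Savitzky–Golay smoothed derivative), with merge/duration/
  amplitude filters and blink handling;
- **Trial scoring** — saccadic reaction time (SRT) of the first saccade
  after stimulus appearance; outcomes `correct`, `direction_error`
  (with corrective-saccade identification), `anticipatory` (SRT < 90 ms,
  direction at chance), `no_response`, `excluded`;
- **Latency epochs** — anticipatory [0, 90) ms, express [90, 140] ms,
  regular (140, 1000] ms, and a data-driven delimitation of the express
  epoch: per 10-ms bin, a one-sided exact binomial sign test of whether
  anti-trial direction errors outnumber correct anti-saccades
  (p0 = 0.5); the epoch is the longest contiguous run of significant
  bins;
- **Subject metrics** — mean SRT and CV (= SD/mean × 100%) over correct
  90–1000 ms trials, the anti-effect (mean SRT-anti − mean SRT-pro),
  epoch proportions, error rates by epoch, and the disease-burden score
  age × (CAG − 35.5);
- **Group statistics** — 2 (group) × 2 (task) mixed-design ANOVA with
  partial eta squared computed by explicit sums-of-squares decomposition,
  two-sample Kolmogorov–Smirnov comparison of SRT distributions
  (D, scaled K = D·√(nm/(n+m)), asymptotic p), two-tailed Pearson
  correlation, Shapiro–Wilk annotation;
- **A synthetic generator** — sessions and two-group cohorts with
  main-sequence kinematics, mixture latency structure, blinks, noise and
  full ground truth, so the entire pipeline runs and is testable with no
  access to patient recordings.

## Worked example

Simulate a small two-group cohort (8 subjects per group, 60 trials each,
a control-like and an inhibition-impaired profile), run the full pipeline,
and test the group × task interaction for direction errors:

```r
library(antisaccade)

cfg <- pipeline_config(
  simulate = list(n_subjects_per_group = 8),
  paradigm = paradigm_config(trials_per_block = 60, n_blocks = 1),
  seed = 42)
res <- run_pipeline(cfg)

aggregate(cbind(mean_srt_anti, anti_effect, pct_direction_error_anti,
                pct_error_regular_anti, pct_anticipatory_anti) ~ group,
          data = res$metrics, FUN = function(x) round(mean(x), 1))
#>     group mean_srt_anti anti_effect pct_direction_error_anti
#> 1 control         254.1        67.6                     20.8
#> 2 patient         289.3        80.9                     42.8
#>   pct_error_regular_anti pct_anticipatory_anti
#> 1                   22.1                  10.0
#> 2                   45.3                  16.7

res$stats$anova$pct_direction_error
#> group       F(1,14) = 22.897, p = 0.000, partial eta^2 = 0.621
#> task        F(1,14) = 165.457, p = 0.000, partial eta^2 = 0.922
#> group:task  F(1,14) = 22.859, p = 0.000, partial eta^2 = 0.620
```

The patient-like group doubles its anti-trial direction errors while pro
behavior stays comparable, which surfaces as the large group × task
interaction; mean anti-SRT and the anti-effect are elevated as well.

Delimiting the express epoch from a latency histogram in which direction
errors form an early narrow mode and correct anti-saccades a late broad
one:

```r
d <- simulate_anti_srt(4000, error_frac = 0.6, error_mean = 115,
                       error_sd = 12, correct_mean = 250, correct_sd = 60,
                       seed = 1)
w <- detect_express_window(srt_histogram(d, bin_width = 10))
c(w$start, w$end)
#> [1]  90 150
```

The run of bins in which errors significantly outnumber corrects starts
at the 90 ms anticipatory boundary and ends within one bin of 140 ms —
the conventional express-epoch bounds.

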