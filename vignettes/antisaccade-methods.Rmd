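---
title: "Quantifying voluntary saccade inhibition from pro-/anti-saccade gap-task recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying voluntary saccade inhibition from pro-/anti-saccade gap-task recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antisaccade)
```

## The task and what the package measures

In the interleaved pro-/anti-saccade gap task, a participant fixates a
central point whose color announces the instruction: look **toward** a
peripheral stimulus (pro-saccade) or **away** from it, to its mirror
location (anti-saccade). The fixation point is extinguished 200 ms before
the stimulus appears (the *gap*), which releases active fixation, shortens
latencies, and — on anti trials — makes the reflexive glance toward the
stimulus harder to suppress. Failures of that suppression appear as
**direction errors**: first saccades toward the stimulus on anti trials.
The default paradigm is 1000 ms fixation, a 200 ms gap, and a stimulus at
10 degrees horizontal eccentricity shown for 1000 ms, in two blocks of 120
pseudorandomly interleaved trials, recorded monocularly at 500 Hz.

The pipeline turns raw gaze traces into, per subject and condition: mean
saccadic reaction time (SRT) and its coefficient of variation
(CV = SD/mean x 100%), the anti-effect (mean anti-SRT minus mean pro-SRT),
the proportions of anticipatory, express and regular-latency responses,
and direction-error rates overall and within latency epochs. Group
inference uses 2 (group) x 2 (task) mixed-design ANOVAs with partial
eta squared, two-sample Kolmogorov–Smirnov comparisons of SRT
distributions, and two-tailed Pearson correlations.

## Saccade detection

Saccade onset and termination are defined operationally by eye velocity
crossing **30 deg/s**. Velocity is estimated with a Savitzky–Golay style
smoothing derivative (quadratic fit; default width 5 samples = 10 ms at
500 Hz). The kernel width trades onset-localization bias against noise:
width 5 localizes a noiseless onset within one sample while suppressing
sample-to-sample tracker noise; wider kernels are available through
`kernel_width`.

A single threshold is used for onset and offset. Because any real trace
crosses 30 deg/s spuriously now and then, maximal suprathreshold runs are
post-processed: runs closer than `merge_gap` (10 ms) are merged, and
events shorter than `min_duration` (6 ms) or smaller than `min_amplitude`
(0.5 degrees net horizontal displacement) are discarded. These three
values are declared defaults, not estimates from data; with them,
detection against synthetic ground truth achieves recall and precision
above 0.99 at default noise.

Blink handling: events whose suprathreshold run touches an invalid sample
— or comes within one kernel half-width of one, since velocity estimates
there are contaminated — are dropped and the trial flagged; windows with
more than 30% invalid samples are excluded outright. The 30% cut-off is
this package's choice of where a trial stops being interpretable.

Scoring uses the **first saccade with onset at or after stimulus
appearance**; earlier saccades (notably the inter-trial refixation that
returns the eye to center) are ignored rather than invalidating the
trial. A first saccade later than 1000 ms marks the trial excluded; no
saccade at all is a "no response". SRT below 90 ms classifies the trial
as anticipatory *regardless of direction*, because a saccade launched
before visual information reaches the oculomotor system is equally likely
to be correct or incorrect; anticipatory trials therefore never enter
correct/error denominators.

## Epoch boundaries and the binomial sign test

Latency epochs partition SRT: anticipatory [0, 90) ms, express
[90, 140] ms, regular (140, 1000] ms. Boundary closure (140 ms is
express, 141 ms regular) is a documented convention; the underlying
quantities are continuous and nothing in the pipeline is sensitive to it
beyond the labels of boundary trials.

The express epoch can also be *derived from the data*: direction errors on
anti trials concentrate in a narrow early mode, correct anti-saccades in a
later, broader one. `detect_express_window()` bins anti-trial SRTs in
10-ms bins and, in each bin with at least 5 trials, runs a one-sided exact
binomial test of errors versus corrects against p0 = 0.5 (a per-bin sign
test). The epoch is the longest contiguous run of at least 2 significant
bins with centers below 300 ms, its start clipped at the 90 ms
anticipatory boundary. Choices the procedure's name does not pin down —
alpha 0.05 per bin, no correction across bins, pooling across subjects,
the longest-run rule, the 300 ms search ceiling — are explicit arguments
with those defaults, and the no-correction choice is recorded in output
metadata. Per-bin p-values are exact binomial tail sums; the test suite
checks them against a brute-force enumeration and the run extraction
against an independent scan. On a 4,000-trial simulated mixture (errors
N(115, 12²) truncated at 90 ms, corrects N(250, 60²), 60/40) the
recovered window is [90, 140–150] ms depending on the draw: the
140–150 ms bin sits exactly at the decision boundary of the test, so both
outcomes are within one bin of the nominal 90–140 ms epoch. The fixed
90–140 ms bounds remain the pipeline default; window-based relabeling
(`epoch_mode = "detected"`) is opt-in, and both pooled and per-group
detection are possible by subsetting the scored trials fed to the
histogram.

## Subject metrics

Mean SRT and CV use **correct** saccades with SRT in [90, 1000] ms; SD is
the sample (n−1) standard deviation. Epoch percentages are taken over all
valid (non-excluded) trials of a condition, so anticipatory + express +
regular + no-response sums to 100. Error-by-epoch percentages are
**conditional** rates by default (errors in the epoch / responses in the
epoch), which keeps them interpretable as "the probability that a
response at this latency was an error"; `error_denominator = "responses"`
instead expresses them as shares of all non-anticipatory responses. The
disease-burden score is age x (CAG − 35.5), the standard age-by-expansion
progression covariate, computed whenever a CAG repeat length is present.

## Group statistics

The 2x2 mixed ANOVA is implemented by explicit sums-of-squares
decomposition — group tested against subjects-within-groups, task and
group x task against the subject-by-task residual — rather than through a
generic regression fit, so every number is checkable against a hand
decomposition (the tests compare it with `aov()`'s stratified output).
With a two-level within factor no sphericity correction is needed.
Unequal group sizes use the unweighted-means (Type III equivalent)
solution with the harmonic mean of group sizes; balanced designs reduce
to the classical formulas. Partial eta squared is
SS_effect / (SS_effect + SS_error-of-that-stratum).

The KS comparison reports D (maximal ECDF gap), the scaled statistic
K = D·sqrt(nm/(n+m)), and the asymptotic Kolmogorov p-value — the scaled
form is what latency studies conventionally print (K values around 2 with
p near 0.001); an exact small-sample variant is intentionally not the
default. Pearson correlations use the t transform with n−2 degrees of
freedom, two-tailed. Shapiro–Wilk normality checks annotate reports only;
the parametric battery is run regardless, matching standard practice for
these designs. No multiple-comparison correction is applied across the
behavioral ANOVAs; the report metadata says so.

## The synthetic generator

`generate_session()` exists so every stage can be tested against known
ground truth; it emulates the statistical structure the analysis assumes,
not any particular participant. Per trial it draws a latency component —
anticipatory (uniform [0, 90) ms, direction at chance, 50/50
toward/away), express (normal truncated to [90, 140] ms), or regular
(normal truncated to (140, stimulus offset]) — then an outcome: direction
errors on anti trials with per-epoch probabilities, corrective saccades
after errors with probability `correction_prob`, occasional omissions.
Truncating each latency component to its own epoch makes ground-truth
epoch proportions equal the mixture weights exactly, which is what the
recovery tests require; the alternative (letting components bleed across
the 140 ms line) would change only the bookkeeping, not the trace.

Saccades are rendered as minimum-jerk position profiles. Duration follows
a linear amplitude law (21 ms + 2.2 ms/deg) and the resulting analytic
peak velocity, 1.875·A/D, is capped by a saturating main-sequence curve
500·(1 − e^(−A/5)) deg/s — about 432 deg/s for a 10-degree saccade, far
above the 30 deg/s criterion. Ground-truth onsets and offsets are the
times at which the *analytic* velocity profile crosses 30 deg/s — the
same operational definition the detector applies — so detector error is
measured against a commensurable reference; the kinematic movement start
is a few milliseconds earlier and recoverable from the stored duration.

Realism choices, and their limits: white position noise of 0.05 degrees
RMS (typical of video eye trackers; real tracker noise is temporally
correlated and ours is not), slow random-walk drift of 0.1 degrees per
trial, blinks as 100–200 ms invalid runs placed in the fixation period at
a default rate of 0.05 per trial, endpoint noise of 0.5 degrees, and an
inter-trial refixation saccade back to center. The generator does not
model head movement, smooth pursuit, microsaccades, pupil dynamics,
fatigue or learning trends, main-sequence variability between saccades of
equal amplitude, or blinks colliding with response saccades. Passing
tests on this synthetic material therefore validates the *pipeline logic*
— detection thresholds, scoring rules, epoch arithmetic, statistics —
not robustness to every artifact of real recordings.

Group presets: `control_profile()` has low regular-latency anti-error
probability (0.18) and few anticipatory anti-saccades (0.08);
`patient_profile()` raises regular-latency anti errors to 0.48,
anticipatory anti-saccades to 0.16, and slows and broadens regular
latencies — the qualitative signature of impaired voluntary inhibition
with preserved reflexive behavior. These values are generator inputs
chosen to produce conditional error rates and anticipatory percentages in
the ranges such cohorts show; no published histogram was fit. Cohorts
jitter each subject's profile (latency means ±15 ms SD; probabilities on
the logit scale, SD 0.25) and draw patient CAG repeat lengths from the
clinically typical 40–52 range. All randomness derives from one master
seed through a single vector of per-subject sub-seeds, so cohorts are
reproducible as a whole and per subject.

## Numerical and degenerate-input choices

Velocity at window edges and around invalid samples is NA and can never
found an event. All-invalid or near-empty windows raise errors naming the
problem; trials outside the recording are reported by id. A session whose
gap duration is not an integer number of samples is allowed but noted.
Zero correct trials in a condition yield missing means with a flag rather
than an error; constant samples make Shapiro–Wilk and Pearson return
reason codes; a zero-variance ANOVA is reported as degenerate (NaN F)
rather than silently zero. Ties between equally long significant runs in
the epoch search go to the earlier run, express-window starts below 90 ms
are clipped with a warning, and the null window is represented as
start = end.

## Problem sizes used in the shipped checks

The test suite and the reproduction script run at desk scale: express-
epoch recovery on 4,000 simulated anti trials; detector fidelity on
noiseless 60-trial sessions; parameter recovery on one 2,000-trial
subject through the full trace pipeline; ANOVA type-I calibration on
1,000 replicates of 10-subject-per-group cohorts scored from ground
truth (60 trials per subject, the trace and detector stages being
exercised elsewhere). These sizes give the binomial/normal error bands
used in the assertions (3 SE) while keeping a full run in minutes on one
core.

## Known limitations

Pixel-to-degree conversion offers a linear and a tangent dialect because
recordings rarely document which mapping produced them; the two differ by
up to a quarter degree mid-screen at this geometry. The detector has no
adaptive threshold, so very slow (glissadic) movements are invisible by
construction. The express-window procedure assumes errors and corrects
were sampled under comparable conditions in each bin; strong latency
trends within a session would violate that silently. And the ANOVA's
partial eta squared shares the usual caveat that it does not aggregate
across studies.
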