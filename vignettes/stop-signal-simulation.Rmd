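---
title: "Simulating and scoring the web-based stop-signal task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and scoring the web-based stop-signal task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(sstsim)
library(dplyr)
```

## The task and the model

The stop-signal task (SST) measures response inhibition. On every trial a go
stimulus (the letter X or O) appears and the participant presses the matching
key as fast as possible. On a quarter of trials a stop signal (a box drawn
around the stimulus) follows the go stimulus after a stop-signal delay (SSD),
instructing the participant to withhold the response. The canonical session
simulated here is a practice block of 32 trials followed by 3 experimental
blocks of 64 trials, with stop signals on exactly 25% of each block's trials
and never on two consecutive trials within a block.

Performance on stop trials is interpreted through the independent horse-race
model: the go process and the stop process run in parallel, and the response
escapes inhibition iff the go process finishes first,

$$ \text{respond} \iff T_{go} < \mathrm{SSD} + T_{stop}. $$

The latency of the unobservable stop process, the stop-signal reaction time
(SSRT), is estimated by the mean method:

$$ \widehat{\mathrm{SSRT}} = \overline{RT}_{go} - \overline{\mathrm{SSD}}, $$

which is consistent at the 50% inhibition point the staircase targets. The
task adapts the SSD with a 1-up/1-down staircase: +50 ms after every
successful stop, −50 ms after every failed one, starting at 250 ms, so that
stop accuracy converges on 50%.

### Synthetic participants

The generator draws each participant-session as a parameterized racer:

* go finish times are ex-Gaussian, $T_{go} \sim \mu + \sigma Z + \tau E$
  (Gaussian plus exponential), the standard positive-skew model for simple
  RTs; the mean go RT is $\mu + \tau$;
* stop latency is Gaussian, $T_{stop} \sim N(\mu_{stop}, \sigma_{stop})$;
* lapse parameters add go omissions (`p_go_omission`: the go process never
  launches), wrong-key presses (`p_choice_error`), and stop-trigger failures
  (`p_trigger_failure`: the stop process never launches). Trigger failures
  default to 0 — the mean-method estimator ignores them, and the knob exists
  precisely so their bias can be studied.

Cohort-level defaults emulate a healthy young-adult sample on this task:
population mean go RT near 490 ms with positive skew (go $\mu$ 400 (SD 55),
$\sigma$ 50 (10), $\tau$ 90 (25) ms), stop latency 240 (33) ms with
within-subject SD 30 ms, omission and choice-error rates below ~2%, a latent
test-retest correlation of 0.6 between the two sessions' stop latencies, and
an independent-condition effect of +22 ms stop latency plus +0.8 percentage
points choice errors. These magnitudes sit where session-level estimates land
in published healthy cohorts for this design; they are configuration, not
constants, and the condition effect is encoded phenomenologically (an
additive shift), since no mechanism for it is established.

### Programmed versus meta SSD

Web deployment means the stop signal is scheduled at a programmed SSD but
actually rendered at a slightly different moment; the realised delay measured
by the machine's real-time clock is the *meta*-SSD. The clock model perturbs
each programmed SSD with a Gaussian offset and optional frame quantization.
The race runs against the realised (meta) delay, and scoring uses the
meta-SSD mean by default (`ssd_source = "meta"`), with `"programmed"` as an
option. Default study clocks put a 1 (SD 1) ms offset on the laboratory
machine and 4 (SD 2) ms on participants' own computers, giving
programmed/meta correlations above 0.99 within sessions — a few milliseconds
of mean shift, not decorrelation.

## A session end to end

```{r session}
cfg <- session_config()
sched <- generate_schedule(cfg, seed = 1)
log <- run_session(sched, participant_params(), config = cfg, seed = 1)
score_session(log) |> glimpse()
```

`feedback_events()` reconstructs the feedback stream the task would have
shown (per-trial messages during practice, the red warning at every third
consecutive go omission, and five end-of-block summary items, with the
"too slow" variant when the block's mean correct-go RT is at or
above 500 ms).

## Scoring decisions

The session battery is: go accuracy / omissions / errors (percent of go
trials — their sum is 100 by construction), mean correct-go RT, the
intraindividual SD, mean wrong-key go RT, stop accuracy (percent of stop
trials), mean programmed and meta SSD, failed-stop RT means split by key
accord, and the mean-method SSRT. Choices the task description leaves open
were fixed as follows:

* the main go RT mean uses **correct responses only**; wrong-key RTs are
  reported as their own variable (the battery carries a separate go-error RT
  entry, which implies the main mean excludes them). A flag
  (`include_error_rts`) pools them instead;
* omissions contribute no RT anywhere;
* the intraindividual SD is the sample SD (n−1) of the same RTs that enter
  the go RT mean;
* empty strata (e.g. no wrong-key failed stops) yield `NA`, "no such
  trials", never 0 — and skip the corresponding race-violation exclusion
  rule;
* the response window is the 1000 ms stimulus presentation; later
  keypresses are omissions (the deadline is not otherwise specified).

## Exclusion rules

A session is excluded when the mean RT of correct-key (or, separately,
incorrect-key) failed stops exceeds the mean go RT (a race-model violation),
when stop accuracy is below 25% or above 75%, when go errors exceed 10% of
go trials, or when SSRT is below 50 ms. All inequalities are strict, read
literally from the rule statements: boundary values retain. `pair_filter()`
then keeps only participants with both sessions present and unexcluded. The
rules are independent predicates, so their order never affects the retained
set.

## The statistics layer

Condition comparisons are dependent-samples t tests on
laboratory − independent differences, with a fixed criterion of p < .005 to
control the multiple comparisons across the battery (a flag per row, not an
FDR adjustment). The effect size is the paired-design
$d_z = |\bar d| / s_d = |t|/\sqrt{n}$ — the only convention consistent with
a (t, df, d) battery of this design. Correlation intervals use the Fisher-z
transform with SE $1/\sqrt{n-3}$; subgroup correlations are computed with
the subgroup's own n. Welch tests (Satterthwaite df) and the two-sided
Fisher exact test (p-summation convention, via `fisher.test`) cover the
between-group checks.

### The JZS Bayes factor

The default Bayes factor for the paired design places a Cauchy(0, 0.707)
prior on the standardized effect size $\delta$ and compares the marginal
likelihood of the observed t against the point null:

$$ \mathrm{BF}_{10} = \frac{\int f_{t,\nu}(t \mid \delta\sqrt{n})\,
  \pi(\delta)\, d\delta}{f_{t,\nu}(t \mid 0)}. $$

`jzs_bf10()` evaluates the equivalent one-dimensional integral over the
Cauchy prior's inverse-gamma mixing variable $g$, mapping the half-infinite
domain to $(0, \pi/2)$ by $g = r^2\tan^2\theta$ before adaptive quadrature
at relative tolerance $10^{-6}$; the integrand is assembled on the log scale
to avoid underflow at large $|t|$. The test suite cross-checks it against an
independent trapezoid integration of the $\delta$-space formulation on a
(t, n) grid to 0.1%. Evidence labels follow the conventional bands (1–3
anecdotal, 3–10 moderate, 10–30 strong, >30 very strong for H1; their
reciprocals for H0), with boundary values assigned to the stronger band and
BF = 1 labelled anecdotal-for-H1.

A practical caveat: at $|t| \approx 4$ the Bayes factor moves by roughly 2%
per 0.01 of t, so BF values recomputed from t statistics printed at two
decimals can differ from originally computed ones by 1–2%; the same rounding
limits how precisely $d_z$ can be recovered from a printed t.

## Numerical and design choices

* **SSD bounds 0–950 ms.** No bounds are stated for the task; observed SSD
  ranges stay far from both. The ceiling keeps the stop signal inside the
  1000 ms stimulus window with a 50 ms margin; clamping (not an error) is
  the staircase's defined behaviour at either bound.
* **Staircase reset.** Practice does not carry its SSD into the
  experimental blocks (sessions stay comparable); `carry_practice_ssd`
  reverses this, since the original behaviour is unstated.
* **Adjacency within blocks.** "No consecutive stop signals" is enforced
  within blocks; block boundaries break adjacency (feedback screens
  intervene). `stops_span_blocks` extends it across boundaries.
* **Exact stop counts.** Schedules place exactly `stop_fraction × length`
  stop trials per block by constrained shuffle with bounded rejection
  retries (and a gap-construction fallback near the feasibility boundary),
  rather than independent Bernoulli draws: the adaptive design implies exact
  balance.
* **X/O balance.** Go stimuli are independent uniform draws, not a forced
  50/50 — "random presentation" is all that is specified.
* **Seed derivation.** Every per-participant, per-session stream derives
  from the master seed by a counter-based rule
  (`master_seed * 1000 + participant_index * 2 + session`, mod $2^{31}-1$),
  so enlarging a cohort never perturbs streams already drawn.
* **Degenerate inputs.** Zero-variance paired differences, all-zero
  contingency tables, logs without a go or stop stratum, and non-finite
  t or SSRT inputs raise errors naming the offending stratum rather than
  returning conventional values.
* **Trial-log serialization.** Timing fields are written at microsecond
  (3-decimal) precision, far below meaningful resolution, keeping
  write/read/write cycles byte-stable.

## What the simulations do and do not establish

Simulated cohorts reproduce the *structure* of real data for this design —
positively skewed go RTs, staircase convergence to ~50% stop accuracy,
meta/programmed SSD divergence of a few milliseconds, attenuated
test-retest correlations of estimated SSRT, and a small independent-condition
decrement — under stationary, independent-race assumptions. Real
participants drift, fatigue, strategize (e.g. slow down in anticipation of
stop signals), and violate race independence; none of that is modelled, so
passing checks here validate the *pipeline* (scheduling, staircase, scoring,
exclusion, statistics), not claims about human performance. Group means from
any particular human sample are not reproducible targets: they depend on the
cohort.

The mean method itself is known to be biased for skewed go RT distributions:
with the default racer the recovered SSRT sits about 10 ms above the
configured mean stop latency (within the ±15 ms the recovery checks use).
The integration method is deliberately out of scope — this package mirrors
a mean-method pipeline; an integration estimator could be added alongside,
not instead.

Problem sizes used by the checks are the package's own choices: 200 seeded
sessions for the staircase-convergence property, 1,000 scored sessions for
the percentage-conservation sweep, 10 participants for stochastic SSRT
recovery, and cohorts of 40–120 for the null and effect-detection
properties. A normality check is available through `stats::shapiro.test`
on the user's side if desired; it is not part of the fidelity surface.
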