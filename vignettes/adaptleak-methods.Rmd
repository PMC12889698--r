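---
title: "Models and methods behind adaptleak"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind adaptleak}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adaptleak)
```

# The scientific problem

In dynamic environments, effective perceptual decisions require flexible
evidence accumulation: when the world is unstable, older evidence should be
discounted faster. Algorithmic models express this as an adaptive "leak" on
an accumulator, but the brain could implement the same flexibility at other
stages — in particular by adapting the sensory neurons that encode the
momentary evidence, or through arousal-linked neuromodulation indexed by
pupil diameter.

`adaptleak` implements, as a tested and reusable pipeline, the analyses
needed to study this question in a switching random-dot motion task:

* a two-epoch trial — a 2400 ms *adapting* stimulus whose motion direction
  reverses at a low (LSF; one switch, at 1200 ms) or high (HSF; five
  switches, every 400 ms) frequency, followed by a behaviorally reported
  *test* stimulus lasting 100–1200 ms (truncated exponential, mean
  parameter 500 ms). Each condition delivers exactly 1200 ms of each motion
  direction during adaptation, and the test direction differs from the
  final adapting direction with probability 0.5, so the adaptor is
  uninformative about the correct report;
* time-dependent lapse-logistic psychometric functions fit separately per
  condition, with trial-wise neural or pupil modulators;
* MT-like single-unit metrics: sliding-window rates, baseline subtraction
  and normalization, direction selectivity, adapting/facilitating
  classification, per-presentation effect sizes, exponential time
  constants, and ROC discriminability;
* a five-step pupillometry preprocessing pipeline with a sliding-window
  baseline-controlled context regression; and
* session-level contrasts, splits, correlations, and model comparison via
  Tjur's coefficient of discrimination against shuffled nulls.

Because in-vivo recordings cannot be reproduced at desk scale, the package
includes a first-class synthetic-data generator whose ground truth makes
every analysis stage testable end to end.

# The behavioral model

## The psychometric function

The probability of *reporting a switch* is modeled as

$$p(x) = \lambda + \frac{1 - 2\lambda}
  {1 + e^{-\beta_{slope}\,(x_1 - (\beta_{ss} x_2 + \beta_{rl} x_3))}}$$

where $x_1$ is the test-stimulus viewing time in ms, signed by trial type
(positive on switch trials, negative on non-switch trials); $x_2$ is the
switch indicator; $x_3$ the right/left indicator (right and left meaning
all directions right or left of vertical); $\lambda$ the lapse rate, which
compresses the response range to $[\lambda, 1-\lambda]$; and the bias terms
act on the x-intercept, because near-step psychometric functions make the
y-intercept hard to estimate. $\beta_{slope}$ is bounded above at 0.05/ms —
roughly the steepest slope resolvable given the sampling of viewing times —
and below at 0. We additionally bound $\lambda$ at 0.45 to keep the model
identifiable; the conditions are fit separately, each with its own lapse.

Fitting is by maximum likelihood (bounded L-BFGS-B) from ten starts: one
deterministic, nine random within bounds. Because the parameters span five
orders of magnitude (a 1/ms slope against ms-scale biases), the optimizer
uses explicit parameter scaling; without it, finite-difference gradient
steps of the default size are about 2% of the slope's entire range and fits
stall far from the optimum. With scaling, refits from different random
starts agree in log-likelihood to well below $10^{-6}$.

## The trial-wise modulated variant

To quantify how strongly a trial-wise signal $x_4$ (normalized MT firing
rate, or evoked-pupil residual) modulates behavioral sensitivity, the
package fits a variant in which the *effective slope* scales with the
signal:

$$p(x) = \lambda + \frac{1 - 2\lambda}
  {1 + e^{-\beta_{slope}\,(x_1 (1 + \beta_{tw} z(x_4)) -
  (\beta_{ss} x_2 + \beta_{rl} x_3))}}$$

with $z(\cdot)$ the within-fit z-score ($z \equiv 0$ when $x_4$ is
constant). This parameterization was a deliberate design choice. The
alternative — a single product
$\beta_{slope}\beta_{tw}(x_1 x_4 - \ldots)$ — ties the modulation strength
to the mean slope: with a standardized (mean-zero) $x_4$ the viewing-time
dependence is destroyed for *any* $\beta_{tw}$, so the variant can never
nest the base model and its pseudo-$R^2$ is catastrophically lower even
when $x_4$ carries real information. The slope-modulation form reduces
exactly to the base model at $\beta_{tw} = 0$, so the difference in Tjur's
pseudo-$R^2$ between the two fits honestly measures the trial-wise signal's
explanatory contribution — the quantity the session-level model comparison
needs. The product form remains available as
`predict_switch_prob_trialwise()` for direct evaluation.

Trials without a defined $x_4$ (for neural fits, trials whose test stimulus
moves in the unit's null direction, where MT responses are minimal) are
excluded before fitting. The evoked-pupil covariate is computed over all
trials rather than correct trials only: on a correct trial the reported
outcome is fully determined by the trial type, so a correct-only choice fit
would be degenerate; the correct-only convention applies to the pupil
time-course analyses instead.

## Fit quality and the shuffled null

Model fit is summarized by Tjur's coefficient of discrimination — the mean
predicted switch probability on switch-report trials minus that on
stay-report trials — averaged across the two per-condition fits to give one
value per session. Whether the *time-dependence* contributes beyond trial
type is assessed against a shuffled null: the pairing between duration
magnitudes and (trial type, sign) is permuted across the session's trials
100 times, the model refit each time, and the empirical value compared with
the null distribution. On zero-slope synthetic data the empirical value's
rank in its null is uniform, confirming calibration.

# The synthetic-data generator

The generator is ground truth for testing, not a biophysical model. Its
defaults define the study conditions emulated throughout the package's
tests; they were chosen once, as follows, and the test and acceptance
problem sizes below are the package's own choices of desk-scale study
design.

## Task schedules

Schedules follow the printed design exactly: 2400 ms adapting epoch; LSF
switch at 1200 ms; HSF switches every 400 ms; alternating directions
starting from a counterbalanced initial direction; a 0.5 epoch-switch
probability; and test durations drawn from the exponential with mean 500 ms
restricted to [100, 1200] ms. Sampling uses the inverse CDF of the doubly
truncated exponential — distributionally identical to resampling until
accepted, but vectorized and well-defined for collapsed bounds. We treat
the 500 ms figure as the pre-truncation mean parameter; the realized mean
of the truncated distribution is ~463 ms.

## Choices: a leaky accumulator with recovering sensory attenuation

Choices come from a linear leaky integrator (Euler step 1 ms),

$$dA = \left(-k\,A + g(t)\, \gamma\, c\, d(t)\right) dt + \sigma\, dW,$$

with $d(t) = \pm 1$ the motion direction, $c$ the coherence, drift gain
$\gamma = 0.01$/ms, diffusion $\sigma = 0.12/\sqrt{\rm ms}$, and the leak
$k$ set by condition ($k_{LSF} = 0.002$/ms, $k_{HSF} = 0.003$/ms). The
choice is the sign of $A$ at test offset, flipped with lapse probability
0.05. By default integration covers only the test epoch; a flag allows
adapting-epoch evidence to carry over, and no reset is imposed at test
onset in that case.

The factor $g(t) = 1 - a_0 e^{-t/\tau_{rec}}$ is an
adaptation-attenuated evidence gain that recovers during the test epoch
($\tau_{rec} = 800$ ms), with a much deeper initial attenuation after the
unstable adaptor ($a_0 = 0.85$ at HSF vs 0.1 at LSF). This term, not the
leak, is what produces the shallower fitted psychometric slope at HSF, and
deserves explanation because it was the design question of this generator.
For the linear leaky integrator, discriminability grows as
$d'(T) \propto \sqrt{\tanh(kT/2)/k}$: the leak affects only the asymptote
and the saturation time, not the early rise, and a *larger* leak makes the
normalized curve saturate *faster*. Worse, any static per-condition gain
scaling is absorbed by the per-condition lapse, leaving the fitted slope
unchanged (we verified this with expected-log-likelihood fits to the exact
Gaussian choice curves). A shallower fitted slope specifically requires the
approach to asymptote to be *slower*, which is exactly what deep,
recovering sensory attenuation produces — and it is the mechanism the
neural side of the pipeline measures in MT-like units. With these defaults
the asymptotic fitted slopes are ~0.0057 (LSF) vs ~0.0016 (HSF)/ms, overall
accuracy ~70%, and long-duration (600–1200 ms) accuracy higher at LSF —
the behavioral phenotype the analyses are designed to detect.

## Spike trains

Each unit is an inhomogeneous Poisson process: `base_rate` throughout,
plus `pref_gain` scaled by a presentation-dependent gain during
preferred-direction segments (latency 50 ms, matching the 50–500 ms
analysis offsets) and `null_gain` (typically suppressive) during null
segments. The gain starts at 1 and is multiplied by $(1 - s)$ after every
preferred presentation, with the step $s$ set by condition
(defaults $s_{LSF} = 0.05$, $s_{HSF} = 0.15$; negative steps give
facilitating units). Two forces therefore reduce HSF test responses: the
larger per-presentation step, and the larger number of preferred
presentations (three vs one) that the HSF schedule delivers before the
test. Because the presentation-count asymmetry is built into the task, the
natural null condition for "no context effect" is $s = 0$ in both
conditions, under which LSF−HSF response and ROC differences are centered
on zero. Negative instantaneous rates (deep suppression) are clipped at
zero and flagged.

## Pupil traces

Per-trial traces at 1000 Hz combine: a tonic baseline following an AR(1)
process across trials (coefficient 0.5); a stereotyped luminance
constriction at stimulus onset (gamma-shaped, peak 0.5 a.u.); a
context-dependent evoked component whose amplitude (0.6 LSF / 0.4 HSF
a.u.) ramps linearly over the adapting epoch and saturates at 1800 ms, so
the pre-test LSF−HSF contrast equals the injected amplitude difference; an
inverse baseline-to-evoked coupling (1.5), reproducing the known inverse
relation between baseline and evoked diameter; white measurement noise;
and blink gaps (Poisson onsets at 0.1/s, 100–300 ms, marked missing).
An optional per-trial latent arousal signal is expressed as an
*anticipatory* component with a Gaussian time course peaking at test onset
(SD 300 ms). The localization matters: a signal expressed uniformly across
the evoked ramp is nearly collinear with the whole-trace average and is
removed by the evoked-residual regression, whereas an anticipatory bump
survives residualization — which is what makes the pupil-based trial-wise
covariate informative when the generator couples arousal to behavior.

Fixation-acquisition times are generated to covary with the tonic baseline,
emulating the observed relation between baseline pupil and task engagement.

## What the generator does not emulate

Biophysical MT dynamics, spike-count correlations between units, eye
movements, gaze artifacts, reward and learning dynamics across sessions,
luminance effects beyond the onset constriction, and non-stationarities in
task engagement. Passing tests therefore demonstrate the *analysis code* is
correct and well-calibrated on data with the assumed statistical structure,
not that real recordings satisfy that structure.

# Neural analyses

Rates use a 100 ms sliding window advanced in 10 ms steps, indexed by
window center, with half-open `[start, end)` intervals; windows not fully
inside a trial's valid observation span are missing. Responses are baseline
subtracted per trial (the 100 ms window immediately preceding adapting
onset) and normalized by the maximum of the trial-averaged
baseline-subtracted trace over the 2400 ms adapting epoch; the maximum is
taken per condition and the cross-condition maximum applied to both, so
normalized responses stay comparable. Units whose normalization factor is
not positive are flagged and excluded from normalized analyses. Correct
trials only are used by default, switchable for error-trial controls.

Direction selectivity is the mean preferred-minus-null difference 100–500
ms after adapting onset (the stimulus period shared by the two conditions
allowing for response delay). Units are classified as adapting or
facilitating when their normalized response changes by more than 2.5%
between the first preferred presentation (200–400 ms after adapting onset)
and the test stimulus (50–500 ms after test onset) *in the same direction
under both conditions* — a deliberately liberal criterion; an alternative
slope-based method fits a line to per-presentation peak responses and
requires a significant (p < 0.05) slope of consistent sign in both
conditions. Effect sizes across presentations use the pooled-SD two-sample
Cohen's d against the first presentation. Test-epoch temporal dynamics are
summarized by an exact single-exponential interpolation
$v(t) = a + b e^{-t/\tau}$ through three response bins (200–330, 340–470,
480–600 ms); triples inconsistent with a positive $\tau$ (flat or
non-monotone) are flagged rather than extrapolated.

Discriminability is the ROC area — the probability that a random
preferred-trial response exceeds a random null-trial response, ties counted
one half — computed per time window (the series), then averaged over
epochs (50–500 ms for summaries, 200–400 ms for the behavior correlation),
so both the time course and the summary values are available.

# Pupil analyses

Preprocessing applies, in order: (1) linear interpolation of missing
samples; (2) a first-order 5 Hz low-pass Butterworth filter, applied
causally in a single forward pass (the first sample is subtracted before
filtering to avoid a startup transient; users wanting zero-phase filtering
can substitute a two-pass variant); (3) removal and interpolation of
samples beyond ±2 SDs of the session mean, computed once on the
concatenated post-filter samples (per-session rather than per-trial
statistics, single pass); (4) subtraction of the session-averaged time
course, computed per time point across all trials regardless of condition;
and (5) z-scoring against the concatenated session samples, with the scale
recorded so coefficients can be mapped back to input units. Entirely
missing and constant traces are excluded with a log message.

The context regression models each 100 ms window's mean pupil diameter
across trials as intercept + baseline (mean over the 100 ms before
stimulus onset) + condition indicator (1 = LSF), by OLS;
$\beta_{cxt}$ estimates the evoked LSF−HSF difference controlling for
baseline, with per-window two-sided p-values reported uncorrected, matching
the window-wise convention of the analyses it implements. Rank-deficient
windows (a single condition) are undefined. Baseline analyses use all
trials to preserve the session's temporal order; evoked analyses use
correct trials. Sessions with interleaved conditions should be excluded
from context-stability pupil analyses (the package generates them but the
pipeline defaults to blocked sessions).

The trial-wise evoked covariate residualizes each trial's pre-test pupil
(mean over the 500 ms before test onset) on the trial's whole-trace
average and baseline in one per-session OLS fit.

# Session-level analyses

Per-session summaries carry LSF−HSF contrasts throughout (psychometric
slope, accuracy for trials ending 375–600 ms after test onset, ROC area
200–400 ms, normalized test response 50–500 ms, and the mean
$\beta_{cxt}$ over −500–0 ms before test onset). Sessions split by the
sign of the slope difference, with the boundary (exactly zero) assigned to
the "HSF steeper or equal" group. Cross-session correlations are Pearson
or Spearman with two-sided p-values; pairs with missing values are dropped
and counted. Model comparison reports per-session differences in Tjur's
pseudo-$R^2$ with versus without the neural or pupil term (the
behavior-only baseline refit on the same trial subset as the modulated
model, so the comparison is like-for-like; per-session values average the
LSF and HSF fits, averaging before differencing), a one-sample sign test
per delta set, and a Wilcoxon signed-rank paired comparison of neural
versus pupil deltas (exact p-values below n = 25). No multiple-comparison
correction is applied anywhere, deliberately matching the window-wise
reporting convention; users needing corrected inference should adjust the
returned p-values.

`run_pipeline()` orchestrates simulate → fit → analyze → summarize,
writing `summaries.csv`, `fits.json`, and a plain-text report of the
headline contrasts; it is deterministic given its seed, with
session-to-session variability injected through a log-normal spread on the
HSF leak.

# Numerical choices and degenerate inputs

* Euler step 1 ms; halving it changes noise-free terminal states by <1%.
* Optimizer: L-BFGS-B, 10 starts, explicit parameter scaling; boundary
  solutions are flagged, and non-convergence returns the best point with
  an honest flag.
* Half-open windows and bins everywhere; rates indexed by window center.
* Ties in ROC count one half (midranks); zero-variance inputs yield `NA`
  with a warning rather than an error wherever a metric is undefined
  (Tjur's statistic with one outcome class, Cohen's d with zero pooled SD,
  correlations with zero variance).
* Exact-interpolation exponential fits refuse inconsistent triples instead
  of returning runaway time constants.
* Collapsed duration bounds return the degenerate value; single-class
  outcomes refuse to fit with an explanatory error.

# Study conditions used by the verification suite

The test suite exercises the stages at these desk-scale sizes: psychometric
recovery at 2000 trials per fit, 20 replicates; shuffled-null separation on
20 structured 800-trial sessions (100 null iterations each) plus 20
zero-slope sessions for rank calibration; ROC against brute force on 200
random small instances; context-adaptation mirrors on 50 simulated units
(120 trials each) with a 50-unit zero-step null; classification recovery
on 50 clearly separated units (steps ±0.2/±0.3, 100 trials each);
pupil-regression recovery over 50 sessions of 100 trials per condition; and
ground-truth dissociation on 20 sessions per direction (1000 trials each,
coupling 0.6). Null fits within the shuffled-null routine use 2 optimizer
starts (the permuted fits are many and forgiving); empirical fits use the
full 10.

# Known limitations

* The accumulator is a phenomenological stand-in: its recovering-gain
  mechanism reproduces the behavioral phenotype, but its parameters are
  not estimable from the behavioral fits and are not intended to be.
* The lapse-logistic is an approximation to the accumulator's true choice
  curve; near-flat psychometric functions leave the slope/lapse trade-off
  weakly identified in single sessions, which is why session-level claims
  in the verification suite are statistical (sign tests, rank tests)
  rather than per-session.
* Trial-wise model-comparison deltas are in-sample; with ~150 trials per
  fit the extra parameter inflates deltas by roughly +0.01, which cancels
  in the paired neural-vs-pupil comparison but should be kept in mind when
  reading absolute delta values.
* The pupil pipeline assumes blink gaps are marked missing upstream; it
  does not detect blinks from eye-openness signals.
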