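---
title: "Modelling physiological and behavioral responses to negative life events"
author: "pbstate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling physiological and behavioral responses to negative life events}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbstate)
```

# The problem

Consumer wearables record a person's daily resting heart rate (RHR, bpm),
moderate-to-vigorous physical activity (MVPA, minutes) and sleep duration
(hours) — together a daily *physiological and behavioral state* (PB-state).
After a significant negative life event (a death in the family, serious
illness, financial or marital problems), some people's PB-state visibly
deviates from their own routine and then drifts back over roughly two weeks,
while others barely move. `pbstate` implements a complete pipeline for
quantifying these deviations person-by-person, testing whether they exceed
what the same person's uneventful weeks produce, and relating their size and
shape to how the person copes.

The pipeline treats deviation detection as a *novelty detection* problem:
each participant's 60 pre-event days define their own normal, and each of the
15 post-event days (day 0 = the event day) is scored against that normal.
Nothing is pooled across participants until the very last inferential steps,
so between-person differences in baseline level, variability and weekly
rhythm never masquerade as event effects.

# Pipeline and assumptions

## Cohort selection

Participants qualify when they report a *negative* event (valence $\ge 5$ on
the 1 = extremely positive … 7 = extremely negative scale), of *at least
high* significance ($\ge 6$), dated with the *highest* confidence ($= 7$),
wore the device at least 19 of 24 h on at least 80% of the days in both
analysis windows ($\lceil 0.8 \cdot 60\rceil = 48$ pre days,
$\lceil 0.8\cdot 15\rceil = 12$ post days), and completed all 28 Brief COPE
items. The verbal anchors fix only the confidence cut exactly; the valence
and significance cuts ($\ge 5$, $\ge 6$) are this package's numeric reading
of "negative" (strictly past the midpoint) and "at least high significance",
and both are configurable (`eligibilityThresholds()`). The earliest eligible
event is the index event; two eligible events on the same date make a unique
index event impossible, so such participants are excluded with a warning
rather than resolved by an arbitrary tie-break. `filterCohort()` records a
consort-style count after every stage.

## Preprocessing

Within the 75-day window the order is: linear interpolation of missing
values (edge gaps take the nearest observed value, since linear
interpolation is undefined there; interpolation runs per window so
post-event days never influence the baseline), removal of day-of-week means,
an augmented Dickey–Fuller stationarity check per stream, and
z-normalisation. Weekday means and z-parameters are estimated on the
*pre-event window only* by default (`estimationSpan = "pre_only"`): the
event itself may shift the post-event distribution, and folding that shift
into the normalisation would shrink exactly the deviations the model is
meant to detect. The alternative (`"full_75"`) is provided for sensitivity
analysis. Whether imputation precedes or follows deseasonalisation is an
open choice; this package fixes imputation first so weekday means are
computed from gap-free series.

The ADF test (constant, no trend) selects its lag order by AIC up to
$\lfloor 12 (n/100)^{1/4} \rfloor$, with p-values interpolated from the
standard critical-value table for the constant-only statistic (clamped to
[0.01, 0.99], the table's resolution). No ADF implementation exists among
this package's dependencies, so the test is implemented here and its null
quantiles were verified by Monte Carlo before freezing. A non-stationary
flag is logged, not fatal: the downstream novelty model makes no
stationarity assumption of its own, and aborting a participant on a 5%-level
screen would discard data the test itself may have mis-flagged (at $n = 75$
and AIC lag selection the test rejects a true white-noise null about 97% of
the time, not 99%+ — a power limit of the test, shared by reference
implementations, that users should keep in mind when reading the flags).

## Baseline model and response curves

A one-class SVM with RBF kernel is fitted per participant on the 60
processed pre-event days. The decision function is the dual form

$$f(x) = \sum_i \alpha_i\, e^{-\gamma \lVert x_i - x\rVert^2} - \rho,$$

positive for days conforming to the baseline, negative for deviating days;
its magnitude is the degree of (non)conformity. The 15 post-event scores,
in day order, are the participant's *response curve*.

Two parameters matter and are deliberately held constant across all
participants, so that differences between response curves reflect only
differences between the participants' own baselines:

* $\nu = 0.01$ — the upper bound on the fraction of training errors, set
  small so the model learns from essentially every pre-event day. With
  $\nu n = 0.6 < 1$ no training point can sit strictly outside the boundary
  at the exact optimum; numerically, boundary support vectors score within
  solver tolerance of zero, which is why `trainingErrorFraction()` counts
  an error only below $-$tolerance.
* $\gamma$ — the RBF bandwidth, defaulting to the "scale" convention
  $1/(3\,\mathrm{Var}(X))$ (population variance over all entries of the
  $60\times3$ training matrix). On z-normalised data this is
  $\approx 1/3$.

The solver (libsvm via `e1071`) is an implementation detail: the package's
contract is the dual form above, and `scoreDays()` evaluates it directly
from the extracted support vectors, coefficients and offset. The test-suite
cross-checks this evaluation against the solver's own decision values.

For downstream modelling the curve is transformed two ways: *immediate
impact* truncates inliers to zero and flips outlier signs
($\max(0, -f)$, a non-negative right-skewed quantity), and the *short-term
trajectory* keeps outliers negative ($\min(0, f)$). The *cumulative
deviation* used by the internal validation is the raw signed 15-day sum by
default; an inlier-truncated variant is available
(`cumulativeDeviation(truncated = TRUE)`) because "sum of deviations" can
be read either way.

## Internal validation against a no-event null

To ask whether post-event deviations exceed the participant's ordinary
variability, the 75-day event window is removed from the full series and a
75-day window slides day-by-day over what remains. A block is valid when it
meets the same wear rule and contains no reported event *of any valence* —
the strictest reading of "no event present", configurable to
eligible-events-only. Each valid block yields a deterministic curve (train
on its first 60 days, score its last 15, full preprocessing recomputed
inside the block); blocks are then bootstrapped as whole units (10,000
draws by default) and the per-day median over draws is the participant's
*null curve*. Because block curves are deterministic, the implementation
computes each one once and resamples curves — algebraically identical to
re-fitting per draw, at a small fraction of the cost.

Two paired Wilcoxon signed-rank tests compare event and null responses
across participants: day-0 scores, and 15-day cumulative deviations. For
day 0 the null value is simply the null curve's first entry (the per-day
median *is* the median of day-0 scores over draws). For the cumulative
test the null value is the median over bootstrap draws of each curve's
15-day *sum* — aggregating after summing. The distinction matters: daily
decision scores are left-skewed (inliers bunch at small positive values,
outliers stretch far negative), so summing the per-day median curve
suppresses every day's outlier tail and yields a systematically
higher-than-typical sum. In null simulations that variant rejected in the
vast majority of no-effect cohorts, while the median-of-sums version is
calibrated (see the package's power/type-I study). Zero differences are
dropped
(the classical convention; the Pratt treatment would change p-values and is
deliberately not used), the exact distribution is used for $n \le 25$
without ties, and the normal approximation with continuity correction
otherwise.

## Relating responses to coping

Brief COPE items score 14 two-item strategies (sums, range 2–8). Each
strategy is analysed in its own regression — never jointly, so the strong
inter-strategy correlations cannot produce biased joint estimates — with an
identical adjustment set: standardised age, a gender indicator, and the
event's perceived valence and significance on their raw Likert scales
(standardising ordinal Likert covariates would only rescale coefficients
while making them harder to read; age in years is standardised because its
scale is arbitrary relative to the 2–8 coping scores).

*Immediate impact* (non-negative with exact zeros) uses a gamma-hurdle
model: an intercept-only Bernoulli hurdle for $P(y = 0)$ — the published
analysis reports a single coefficient per strategy, consistent with effects
on the positive part; a covariate-bearing hurdle is available behind a flag
— and $y > 0 \sim \mathrm{Gamma}(\alpha, \alpha/\mu)$ with
$\log \mu = X\beta$. *Trajectory* cluster membership uses Bayesian logistic
regression with the same conventions, summarised as odds ratios.

Sampling runs in JAGS: flat priors are realised as $N(0, 10^6)$ (JAGS has
no improper priors; at these sample sizes the likelihood dominates), and
the gamma shape gets a diffuse $\mathrm{Gamma}(0.01, 0.01)$ prior — a
genuinely flat shape prior can produce an improper posterior. The default
budget is 100,000 post-warmup draws over 4 chains targeting 10,000
effective samples; `inferenceConfig(testMode = TRUE)` scales this to 2,000
draws for simulation studies. Every fit reports effective sample size and
split R-hat and warns when ESS falls below target or R-hat exceeds 1.01.
Summaries are the posterior median multiplicative effect
($e^{\mathrm{median}(\beta)}$), the equal-tailed 90% credible interval
(the common posterior-summary default; HDIs would differ for skewed
posteriors), and the probability of direction
$pd = \max(P(\beta > 0), P(\beta < 0))$ — for a symmetric posterior,
$pd = 95\%$ corresponds to a two-sided p-value of about 0.1.

## Trajectory clustering

Signed trajectories are lowess-smoothed (tricube local linear fits, no
robustifying iterations, span 0.5 ≈ a 7-day local window on 15 points; the
span is unstated in the source analysis and exposed in the API) and
clustered with K-shape under the shape-based distance
$\mathrm{SBD}(a,b) = 1 - \max_s \mathrm{NCC}_c(a,b)(s)$, the
coefficient-normalised cross-correlation maximised over zero-padded shifts,
with curves z-scaled inside the metric as K-shape requires. Centroids come
from the standard shape-extraction eigenproblem; iteration stops when
labels stabilise or when an update would increase the within-cluster SBD
sum (the previous solution is kept, making the objective non-increasing by
construction). The best of 10 seeded restarts per candidate $K \in 2..6$ is
kept, and $K$ is chosen by mean silhouette on the SBD matrix (silhouette on
the Euclidean distances of smoothed curves is available behind a flag). A
chosen-$K$ silhouette below 0.25 sets an `unstable` flag.

Labels are canonicalised so cluster 0 is always the minimal-deviation
cluster (smallest mean $|$cumulative signed deviation$|$ of the raw
curves), making "cluster 1 membership" a stable outcome for the logistic
stage. Two degeneracies need policies: all-identical curves are an error,
and individual zero-variance curves (participants who never left baseline;
their truncated trajectories are exactly zero) cannot be z-scaled for shape
comparison — they are held out of the fit and assigned to cluster 0, which
is exactly what they are. Note the consequence: because SBD is
amplitude-blind, a "flat" cluster is identifiable either by this exact-zero
route or by a genuinely shared low-amplitude shape; constant-plus-noise
curves have no shape in common and will not co-cluster.

## Post-hoc changes in raw units

For each participant, medians of the *interpolated but unnormalised*
streams over the pre- and post-event windows (interpolated for consistency
with the modelling path; raw units so changes read as bpm, minutes, hours;
even-length medians are the midpoint of the central order statistics).
Per cluster and measure, the mean paired change and a Wilcoxon signed-rank
p-value; all-zero changes are reported as degenerate with $p = 1$ rather
than erroring. Per-strategy and per-measure tests are reported without
multiplicity correction, mirroring the source analysis's
exact-values-reported convention; the report footnotes the number of tests.

# The synthetic cohort generator

The study data this pipeline was designed for are access-restricted, so
`generateCohort()` produces cohorts with the structure the analysis
assumes, plus ground truth for recovery testing. Per stream and
participant:

$$x_d = \text{level} + \text{weekday}(d) + \varepsilon_d +
  \mathbb{1}[\text{responder}, d \ge E]\; m \cdot 2^{-(d-E)/h},$$

with $\varepsilon_d$ a stationary Gaussian AR(1) (independent across
streams by default — the measures' observed within-person correlations are
weak, max $|r| = 0.27$, and independence is the simplest compatible choice;
a cross-stream correlation parameter exists for stress tests), weekday
effects summing to zero per stream for identifiability, and an immediate
step + exponential decay response (half-life $h$, default 7 days, so
deviations essentially resolve within the two-week observation window).
`noiseSd` is the *marginal* sd of the AR(1) noise (innovation sd
$= \sigma\sqrt{1-\phi^2}$), so "a deviation of 2 pre-window sds" is
directly expressible. Sleep and MVPA are floored at 0 and clips counted.

Defaults mirror the observable study conditions: 45 participants, 365
days, RHR/MVPA/sleep around 65 bpm / 30 min / 7.5 h with noise sds
2.5 / 15 / 0.9, $\phi = 0.3$, 62% responders (28 of 45), deviations of
about two marginal sds per stream (+5 bpm, −25 min, −1.5 h), and 5% of
days effectively unworn (wear < 19 h, values absent) plus 2% worn only
part of the day (wear < 19 h, values present). COPE items are drawn with a
within-pair latent correlation of 0.6 so scale scoring is meaningful, and
the injected magnitude is scaled by $e^{c z}$ where $z$ is the
standardised designated scale score (default: active coping,
$c = -0.25$) — better copers deviate less. The standardisation constants
(mean 5, sd 1.957) are the analytic moments of the item model, estimated
once by large-sample Monte Carlo.

What the generator does *not* emulate: measurement error idiosyncrasies of
real devices, skewed or heavy-tailed stream distributions, seasonal trends
beyond the weekly cycle, informative (stress-related) missingness, and
event-date misreport. Passing recovery tests therefore demonstrates that
the pipeline's machinery is correct under its own assumptions, not that
those assumptions hold for any particular real cohort.

# Numerical choices and problem sizes

Determinism is end-to-end: a single pipeline seed derives per-stage,
per-participant and per-chain seeds through a rolling-hash
(`deriveSeed()`), so adding bootstrap draws to one participant never
perturbs another. The test suite and the acceptance script use scaled-down
problem sizes chosen to keep each study's Monte Carlo error well inside
the asserted margins: 200 baselines for the $\nu$-bound, 500 replicates
for the ADF error rates, 100 replicates at $n = 40$ participants with
100-draw bootstraps for the validation power/type-I study, 100 null
replicates at 2,000 posterior draws for credible-interval coverage, and
$n = 500$ for single-fit effect recovery. The full-scale settings (10,000
bootstrap draws, 100,000 posterior draws) remain the defaults of
`nullConfig()` and `inferenceConfig()`.

# Known limitations

* The day-0 validation test is mildly anticonservative: the Wilcoxon
  signed-rank test assumes symmetric differences under the null, but
  event-minus-null day-0 differences inherit the left skew of the decision
  scores. In the package's 100-replicate null study the day-0 test
  rejected 11% of no-effect cohorts at the 5% level (the cumulative test,
  which compares like-for-like medians of sums, rejected 3–4%). Day-0
  p-values near the threshold deserve corresponding caution.
* The ADF p-value comes from table interpolation; between tabulated
  points it is accurate to roughly ±0.01–0.02, and values outside
  [0.01, 0.99] are clamped.
* With $n = 45$ participants the per-strategy regressions are exploratory
  by construction; credible intervals are honest but wide, and the 14
  strategies are tested without multiplicity correction.
* K-shape with SBD cannot distinguish clusters by amplitude alone (see
  above); trajectory clusters are shape clusters.
* The bootstrap null treats blocks as exchangeable units; overlapping
  blocks share data, so the 10,000 draws do not represent 10,000
  independent no-event episodes — the median curve is robust to this, but
  tail quantiles of the null distribution would not be.
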