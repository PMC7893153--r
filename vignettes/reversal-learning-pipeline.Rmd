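---
title: "Quantifying reversal learning: from two-channel traces to statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying reversal learning: from two-channel traces to statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(revlearn)
```

## The experiment this package analyses

In olfactory reversal learning, a fly first learns that one odor (CS+)
predicts electric shock while a control odor (CS−) does not
(*acquisition*, five trials per odor here), and then the contingency flips:
the CS+ is presented without shock and the CS− with shock (*reversal*, two
trials per odor). Dopaminergic neurons (DANs) and mushroom-body output
neurons (MBONs) change their odor responses across these trials, and those
changes — not absolute response sizes — are the quantities of interest.

Neural activity is recorded ratiometrically: a calcium indicator (GCaMP) in
the activity channel and a calcium-insensitive fluorophore (tdTomato) in
the reference channel of the same neurons. Each 1-min trial is imaged only
during its first 20 s at 5 frames/s; the odor arrives 5 s after imaging
onset for 5 s, and on paired trials a 100-ms shock follows 4 s after odor
onset.

## The trace model and its processing

For each trial segment the pipeline computes, in order:

1. **Ratio** `R(t) = G(t) / T(t)`. A movement of the preparation scales
   both channels by the same factor, so it cancels here exactly. This is an
   identity of the arithmetic, and the suite asserts it against arbitrary
   positive artifact paths.
2. **Photobleaching correction.** The ratio is fitted with
   `f(t) = a1 e^{-t/τ1} + a2 e^{-t/τ2} + c` on the frames *outside* the
   stimulus interval, and detrended subtractively,
   `R'(t) = R(t) − f(t) + f(t0)`, which removes the trend while preserving
   the initial level. Subtractive (rather than divisive) detrending keeps
   ΔR/R₀ well defined and reduces to the identity on trend-free traces;
   both the masking of stimulus frames and the subtractive form are
   package choices the underlying protocol leaves open.
3. **Normalisation.** `ΔR/R₀ = (R' − R₀)/R₀` with `R₀` the mean over the
   half-open window `[0, 5)` s — exactly 25 frames at 5 fps, all before
   odor onset.
4. **Windowed metrics.** The *mean odor response* averages ΔR/R₀ over
   `[onset, onset + 4)` s (20 frames), stopping before the shock can
   contaminate it; the *mean shock response* averages over
   `[onset + 4, onset + 4.8)` s (4 frames), ending before odor offset at
   +5 s. Windows are half-open and a frame belongs to a window iff its
   timestamp does.

Each 20-s segment is processed independently, with `t = 0` at its imaging
onset: illumination (and therefore bleaching) is interrupted between
trials, and the baseline is defined per recording. Because a restriction of
a double exponential to a later time interval is again a double exponential
with the same time constants, per-segment fitting loses nothing.

### Numerical choices in the trend fit

The fit is deterministic: every ordered pair of time constants from the
grid {5, 30, 100, 300} s is tried with its linear coefficients solved
exactly (variable projection), and the best candidate is refined by bounded
Levenberg–Marquardt with an analytic Jacobian. The refined solution is
accepted only if it does not increase the residual sum of squares over its
own start, so degenerate profiles (a constant trace has `a1 = a2 = 0` and
arbitrary taus) cannot regress. If the nonlinear step fails outright the
trend falls back to a straight line and the segment is flagged
`fit_ok = FALSE`. Two time constants of order 10 s and 100–300 s are not
jointly identifiable from a single 20-s segment; parameter-recovery
checks therefore run on 120-s traces, while 20-s segments only require the
*trend*, not the parameters, to be right.

## Learning metrics

Per fly and odor, learning is summarised as trial differences: *last minus
first* trial of a phase (fifth minus first acquisition trial; second minus
first reversal trial; positive = response increased), and as a per-trial
trajectory relative to the first acquisition trial. These are plain
differences, hence shift-invariant and antisymmetric — properties the suite
checks explicitly.

## The statistical battery

* `paired_compare()` screens the paired differences with the
  D'Agostino–Pearson omnibus test (implemented from the standard skewness
  and kurtosis transformations; verified against an external reference
  implementation) at α = 0.05 and then applies either a two-tailed paired
  t-test or a Wilcoxon matched-pairs signed-rank test. The gate is applied
  to the differences — the quantity the subsequent test actually assumes
  normal — with zero differences dropped before ranking; both choices are
  package policy where the underlying protocol is silent, and both the
  gate α and the policy are visible in the code. Below n = 8 the omnibus
  statistic is undefined and Shapiro–Wilk gates instead.
* `rm_anova_dunnett()` runs a univariate repeated-measures ANOVA over
  trials (with two odors supplied, over the CS+ − CS− difference scores, so
  the omnibus test is the trial × odor interaction), optionally multiplying
  both df by the Greenhouse–Geisser epsilon, and compares each later trial
  with the first via Dunnett-style contrasts using the multivariate-t
  distribution with correlation 1/2 (quadrature tolerance 1e−6, internal
  RNG state fixed, so results are deterministic).

Calibration is asserted by simulation at the study's sample size (n = 9
flies, 5 trials): 2000-replicate null simulations must put the empirical
type-I error of both the paired battery and the omnibus F inside
[0.035, 0.065] at α = 0.05. The omnibus calibration runs without the GG
correction because the null generator draws i.i.d. noise, for which
sphericity holds and the uncorrected F is exact; on the same nulls the
GG-corrected test is conservative (its estimated ε < 1 even when sphericity
is true), and the suite asserts exactly that — it never rejects more often
than the uncorrected test — rather than forcing its rate into a two-sided
band it is known to sit below.

## What the synthetic generator emulates — and what it does not

`simulate_trace()` builds both channels from the generative model

```
G(t) = [baseline_G + Σ amp · k(t − onset)] · B_G(t) · M(t) + ε_G
T(t) =  baseline_T                        · B_T(t) · M(t) + ε_T
```

with `B` the double-exponential bleach evaluated in cumulative
illumination time, `M` a smoothed lognormal motion artifact identical on
both channels, `k` a difference-of-exponentials kernel (rise 0.2 s, decay
1.5 s, unit peak — any smooth causal kernel would do; none is prescribed by
the protocol), and white read noise. Key defaults: baselines 100 a.u.,
noise 1 a.u./frame (1%), motion log-sd 0.05, odor amplitude 40 a.u. (peak
ΔR/R₀ ≈ 0.4), shock amplitude 30 a.u., shared bleach
`(a1 = 0.3, τ1 = 30 s, a2 = 0.1, τ2 = 300 s, c = 0.6)` with per-channel
overrides available, and a per-fly lognormal response gain with CV 0.25 so
cohorts show realistic between-fly spread. Plasticity is declarative: a
table of per-trial amplitude multipliers per odor. The PAM-β′2a-style
preset halves the CS+ amplitude across the five acquisition trials and
raises it again across the two reversal trials (0.65 → 0.90 of naive),
with CS− flat — the sign structure the learning metrics must recover.

The generator deliberately does **not** model pixel-level movies, ROI
segmentation, odor plume dynamics, slow drifts other than bleaching,
channel cross-talk, or any mechanistic plasticity rule. Passing recovery
tests therefore shows the *analysis* is correct under the stated generative
assumptions — ratiometric cancellation, double-exponential bleaching,
additive transients — not that real recordings satisfy those assumptions.

## Behavior and connectome modules

The behavioral indices are count ratios: avoidance index
`(N_CS− − N_CS+)/N`, its reciprocally balanced average over swapped odor
assignments, the red-light preference index averaged over the two
alternating illumination configurations, and single-fly percent time per
quadrant class (frame counts as time proxy). Flies that cannot be assigned
to a quadrant class are excluded from both counts. Under the binomial
occupancy model the avoidance index estimates `2p − 1`, which the suite
verifies to within 0.01 over 10,000 draws.

The connectome module counts synaptic contacts between identified neurons
from a tabular export (one row per contact). Filters mirror standard
practice with a hemisphere-limited, partially traced volume: keep only
contacts whose two endpoints are fully traced, restrict to compartment ROIs
via an explicit whitelist (no geometric dendrite inference), and filter on
a side column when one exists. Type-pair means include zero-contact
candidate pairs only when an explicit member roster is supplied — "mean
contacts per candidate pair" is only defined against a roster. All
summaries are asserted equal to brute-force enumeration.

## Problem sizes used by the test suite

Simulation-based assertions use the study's own structure: 5 + 2 trials per
odor at 5 fps and 20-s segments, n = 9 flies for power, 200 single flies
for sign recovery, 2000 replicates for type-I calibration, 500 for power,
10,000 draws for the binomial consistency check, 20 parameter draws for
bleach recovery and 50 random fixtures for the connectome oracle.

## Known limitations

* The double-exponential taus from a single 20-s segment are reported but
  should not be interpreted; only the detrended trace is meaningful there.
* The Wilcoxon branch with many ties relies on the normal approximation
  with continuity correction, as exact distributions are unavailable under
  ties.
* The two-way repeated-measures analysis is the univariate
  difference-score approach; no mixed-model fallback is provided for
  unbalanced designs — they are rejected instead.
* Connectome counting trusts the export's tracing flags and ROI labels; it
  performs no geometric reasoning.
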