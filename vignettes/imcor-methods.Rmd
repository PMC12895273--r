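---
title: "Methods: models, calibration and design choices in imcor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, calibration and design choices in imcor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Movement imagery — mentally simulating an action without executing it —
engages the corticospinal system: motor-evoked potentials (MEPs) elicited by
transcranial magnetic stimulation (TMS) over primary motor cortex grow when
the stimulated muscle is the one being imagined, and short-interval
intracortical inhibition (SICI) weakens. Whether individuals who show
stronger neurophysiological signatures of imagery also score better on
behavioural imagery-ability instruments is an open validity question. imcor
implements the complete analysis pipeline for a study of this question: it
derives the individual-level neural measures (percentage MEP change and the
change in inhibition), scores three behavioural instruments (a kinaesthetic
imagery questionnaire, a chronometric Fitts reaching task, a hand-laterality
judgement task), and relates them with Bayesian correlations under a
sequential optional-stopping design. Because no human data exist yet, the
package ships a synthetic-cohort generator that reproduces the statistical
structure the analysis assumes, so every stage is testable end to end.

## Outcome measures

**Corticospinal facilitation.** For each muscle (FDI, ADM), the single-pulse
trial means in the two imagery conditions give
`%MEP change = 100 * active / non-active`, where "active" means the recorded
muscle is the imagined one. 100 means no muscle-specific facilitation. The
rest condition is derived and reported but deliberately not used for
normalization: normalizing by the non-active imagery condition removes
non-specific arousal effects and isolates muscle specificity.

**Disinhibition.** Per condition, `%INH = 100 * conditioned / unconditioned`
(paired-pulse over single-pulse means); the measure is
`delta INH = %INH_active - %INH_non-active`, positive under muscle-specific
disinhibition.

Neither source document specifies whether the confirmatory correlations use
FDI, ADM or a combination; imcor reports per-muscle values and uses the
arithmetic mean of the two muscles as the primary measure (both muscles are
measured in every trial and carry exchangeable information under the
generative model). Trial aggregation is the arithmetic mean by default
(median available via `aggregate = "median"`).

**Behavioural scores.** The questionnaire's kinaesthetic sum-score (7 items,
1-7 each) is normalized to `100 * (sum - 7) / 42`. The Fitts task is scored
by per-participant Gamma regressions of reach time on index of difficulty
(ID), one per condition; the ability measures are the absolute
execution-minus-imagery slope and intercept differences in ms. The
hand-laterality score is the mean reaction time over correct test trials;
accuracy is descriptive only (it sits near a ~90% ceiling). The
biomechanical-constraints effect is reported as lateral-minus-medial mean
correct RT — the sign convention is not pinned down by the protocol, so we
fix and record this one (positive = expected direction).

### Numerical choices in the Fitts regression

The protocol asks for a "Gamma link" with slopes "back-transformed (in ms)",
which is ambiguous: a Gamma *family* with identity link yields slopes
natively in ms/bit, while a log link needs a back-transformation. imcor uses
the identity link by default (`link = "identity"`), with the log link
available; under the log link the slope is reported as the average marginal
effect `mean(b1 * mu_i)`. Identity-link Gamma fits are started from the OLS
solution for stability. The five printed target IDs (6.34, 5.35, 4.3, 3.38,
2.47 bits for diameters 0.018-0.21) are treated as a canonical lookup: no
standard Fitts formulation reproduces them from the stated 0.4-unit
edge-to-edge distance, so `fitts_id()` exposes the lookup plus a clearly
flagged Shannon alternative.

## The Bayesian correlation engine

The population correlation `rho` receives a stretched symmetric beta prior:
`(rho + 1)/2 ~ Beta(1/kappa, 1/kappa)`. `kappa = 1` is the uniform prior on
(-1, 1); this is the family that common Bayes-factor software names
"rscale". The protocol text calls the prior a "Cauchy (rscale = 1)", but no
Cauchy density on (-1, 1) matches that software's correlation prior; we
treat "Cauchy" as a misnomer for the stretched beta family, which is what
the named implementation actually uses.

The likelihood is the exact sampling density of a Pearson correlation `r`
from `n` bivariate-normal pairs,

```
f(r | rho, n) proportional to (1 - rho^2)^((n-1)/2) (1 - rho r)^((3-2n)/2)
              * 2F1(1/2, 1/2; (2n-1)/2; (1 + rho r)/2),
```

evaluated in log space with a vectorized power-series Gauss hypergeometric.
The posterior is normalized by trapezoidal quadrature on a 4001-point
symmetric grid over (-0.99999, 0.99999) that contains 0 exactly, so the
Savage-Dickey ratio `BF01 = posterior(0) / prior(0)` needs no
interpolation. The test suite verifies (a) posterior normalization to
1 +- 1e-6, (b) agreement of the Savage-Dickey ratio with a direct
marginal-likelihood-ratio computed by adaptive quadrature using an
independent Euler-integral hypergeometric, within 0.5% over randomized
cases, and (c) agreement with external closed-form reference values.
Observed correlations of exactly +-1 (zero-noise data) are clamped to
+-(1 - 1e-8); the Bayes factor is then effectively infinite, which is the
correct qualitative answer.

Posterior indices: the probability of direction is the posterior mass
sharing the median's sign (50-100%); the equal-tailed 95% credible interval
comes from inverting the cumulative trapezoid; the 95% HDI is found by
density-threshold search on trapezoid point masses; and the ROPE percentage
is the share of HDI *mass* inside (-0.1, 0.1) — a mass-based reading of
"proportion of the HDI within the ROPE" (a length-based reading differs
only when the posterior is strongly skewed inside the interval). Spearman
inference rank-transforms both variables (average ranks for ties) and
applies the same machinery with the same `kappa` — whether the sensitivity
analysis should re-use the prior width is unstated; we default to yes and
record it.

## Sequential design and prior shrinkage

Looks occur at n = 70, 80, ..., 140. The run stops at the first look with
`BF10 >= 10` (decide H1) or `BF01 >= 3` (decide H0); reaching n = 140
without either gives "inconclusive". The protocol says priors are
"progressively shrunk" across looks but gives no formula; imcor's default
schedule is `kappa_k = kappa_1 / sqrt(k)` for look k — a simple,
monotone schedule under which the width-1 prior applies at the first look,
as specified — and any schedule can be injected as a function. Every result
object records the schedule actually used. Operating-characteristic
simulations (`sequential_operating_characteristics()`) verify the intended
direction: shrinkage cannot inflate the false-H1 rate relative to a
constant-width design.

## Sample-size calculations and the planning-figure reconstruction

The closed-form frequentist requirement
`ceiling(((z_{0.975} + z_{0.95}) / atanh(0.3))^2 + 3) = 139` is reproduced
exactly. The precision-based figure depends on convention: evaluating the
two-sided Fisher-z interval width at r = 0.3 gives n = 143 by direct scan,
a few participants above the published 140 (which other software computes
under slightly different width conventions); `precision_n()` documents its
convention and the acceptance check allows the [139, 143] band.

The published simulation-based planning figures state that at N = 140,
`BF10 > 10` is reached with 77% probability when the true r is 0.3, and
`BF01 > 3` with 68% probability under a true null. These two numbers are
**not reproducible with a width-1 prior**: exact quadrature over the
sampling distribution of r gives 72.3% and 87.2% for kappa = 1. They *are*
jointly reproduced by a prior width of 1/3 (exact values 77.9% and 70.8%),
which is precisely the default "medium" rscale of the Bayes-factor software
named as the planning tool — the plausible reconstruction is that the
planning simulation ran with package defaults while the analysis plan
states rscale = 1. imcor therefore computes the planning-reproduction
targets with `kappa = 1/3`, documents this here, and exposes `kappa` in
`bayesian_power()` so the width-1 reading is one call away. The H0-arm is
simulated under a true correlation of exactly 0, the only coherent reading.

## What the synthetic cohort emulates

One standard-normal latent ability `A` per participant drives every
measure:

- **MEPs**: trial amplitudes are lognormal around condition means
  (multiplicative CV 0.4 — MEP amplitude distributions are right-skewed;
  the protocol is silent on the value). The active-muscle mean is scaled by
  `exp(g_f (A + 1))` (default gain 0.2, giving a ~125% mean %MEP change,
  consistent with the pilot's muscle-specific facilitation direction);
  both imagery conditions carry a small non-specific factor 1.05,
  reflecting the pilot's weak non-active facilitation. Paired-pulse means
  multiply by a logit-normal inhibition ratio centred at 0.5, raised in the
  active condition by `g_d (A + 0.2)` (the pilot found near-zero
  muscle-specific disinhibition, hence the small shift).
- **HLJT**: trial RT is lognormal around
  `baseline * exp(-0.12 A) * angle and direction multipliers`, with RT
  rising ~0.08%/degree of rotation and 5% for lateral stimuli, and accuracy
  logistic in ability and angle near the 90% ceiling.
- **CRFT**: reach time is `(intercept + slope * ID) * Gamma(CV 0.2)`;
  execution slopes are N(43.9, 12) ms/bit (the pilot group estimate and
  spread), imagery slopes deviate by N(-5.9, 15 * exp(-0.5 A)) so the
  absolute difference shrinks with ability while the group imagery slope
  sits at the pilot's 38 ms/bit.
- **Questionnaire / vividness**: discretized linear-in-ability responses
  with ordinal noise, clamped to their scales.

**Calibration.** Exactly one cross-measure correlation is calibrated — the
primary one (%MEP change vs HLJT mean RT, default target -0.3). On the log
scale both measures are linear in `A` plus noise; writing R for their
common reliability, the raw-scale correlation of two lognormal measures
follows the bivariate-lognormal identity, and `solve_linking()` solves R by
`uniroot` so the raw-scale correlation equals the target after accounting
analytically for trial-sampling variance (cv^2 / 30 per cell, halved by
averaging muscles). The solved participant-level noise SDs are then
injected into the generator. A 5000-participant run in the test suite
confirms the realized correlation within +-0.03. All other pairwise
correlations are emergent from the shared latent factor, with only their
signs asserted.

**Reproducibility.** Each participant draws from an independent substream
seeded deterministically from the root seed, so extending a cohort from n
to n + m leaves the first n participants byte-identical — verified in the
suite.

**What a green test does not establish.** The generator's world is
idealized: no dropouts, no attention-check failures, no session or order
effects, no EMG waveforms (amplitudes are drawn directly), trial order is
systematic rather than scheduled, and the latent structure is
unidimensional. Recovery of the planning correlation in this world shows
the pipeline is correct, not that the real study will find r = -0.3.

## Quality control

Trials are retained when all three coil deviations (distance mm, tilt deg,
rotation deg) are strictly below 3 and the pre-stimulus RMS is strictly
below 10 uV. The coil rule follows the protocol text; the RMS ceiling
stands in for trial-rejection rules that live in an unavailable supplement
and is configurable (`qc_limits()`). The filter is monotone in its
thresholds (property-tested) and participants who lose a required cell
entirely are flagged and excluded from correlations rather than crashing
the run.

## Known limitations

- The exact shrinkage schedule intended by the protocol is unknown; results
  always record the schedule used.
- The precision-based n and the ROPE-percentage definition each admit
  convention variants (documented above).
- The hypergeometric series slows near |rho r| -> 1 with small n; the grid
  clamp and term cap keep it bounded, at negligible cost in accuracy for
  n >= 4.
- The pilot experiments' repeated-measures effect sizes require raw pilot
  data that do not exist publicly; reproducing them is out of scope.
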