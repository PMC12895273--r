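# imcor

Bayesian correlation pipeline for TMS movement-imagery ability studies.

## The problem

Movement imagery — mentally rehearsing an action without performing it —
leaves measurable traces in the corticospinal system. Transcranial magnetic
stimulation (TMS) over primary motor cortex elicits motor-evoked potentials
(MEPs) that grow when the stimulated muscle is the one being imagined, and
paired-pulse short-interval intracortical inhibition (SICI) weakens during
imagery. Behavioural batteries — imagery questionnaires, mental chronometry,
hand-laterality (mental rotation) judgements — claim to measure the same
underlying "imagery ability". Whether the neural and behavioural measures
actually correlate across individuals is the validity question this pipeline
addresses.

imcor is for researchers planning or analysing such studies. It provides:

- **Synthetic cohorts** (`cohort_config()`, `generate_cohort()`): all five
  trial-level data streams of the study (MEP trials for 2 muscles x 3
  conditions x 2 protocols x 30 trials, MIQ-RS items, Fitts-task reaches,
  hand-laterality trials, vividness ratings), linked through one latent
  ability factor with the %MEP-vs-reaction-time correlation calibrated to a
  target (default r = -0.3).
- **Session schedules** (`build_tms_schedule()`, `build_hljt_schedule()`)
  with exhaustive constraint validators.
- **Outcome derivation**: QC filtering (`qc_filter()`), per-participant
  `%MEP change = 100 * active/non-active`, `%INH = 100 *
  conditioned/unconditioned` and its active-minus-non-active difference
  (`derive_neuro_outcomes()`); questionnaire, Gamma-GLM Fitts-slope and
  laterality-RT scoring (`derive_ability_scores()`).
- **A from-scratch Bayesian correlation engine** (`correlate()`): stretched
  symmetric beta prior of width kappa on rho in (-1, 1), the exact sampling
  density of the Pearson r as likelihood, Savage-Dickey Bayes factors,
  probability of direction, ROPE percentage and credible intervals, with
  Spearman sensitivity analysis.
- **Sequential optional stopping** (`run_sequential()`): looks at
  n = 70, 80, ..., 140, stop at BF10 >= 10 (H1) or BF01 >= 3 (H0), prior
  width shrunk as `1/sqrt(look)`.
- **Design calculations** (`frequentist_n()`, `precision_n()`,
  `bayesian_power()`, `sequential_operating_characteristics()`).

## The statistics at the core

For observed correlation `r` from `n` bivariate-normal pairs, the posterior
over the population correlation is

    p(rho | r, n) ∝ pi(rho; kappa) (1-rho^2)^((n-1)/2) (1-rho r)^((3-2n)/2)
                    2F1(1/2, 1/2; (2n-1)/2; (1+rho r)/2)

with `pi` the stretched beta prior ((rho+1)/2 ~ Beta(1/kappa, 1/kappa);
kappa = 1 is uniform). The Bayes factor is the Savage-Dickey density ratio
`BF01 = p(rho = 0 | r, n) / pi(0)`, computed on a dense grid and verified in
the test suite against independent quadrature oracles to within 0.5%.

## Worked example

```r
library(imcor)

coh <- generate_cohort(cohort_config(n_participants = 140,
                                     target_r = -0.3, seed = 2026))
st <- run_study(coh)
print(st)
```

```
Study analysis: 140 complete participants
Primary correlation (%MEP change vs HLJT reaction time):
Bayesian pearson correlation (n = 140, prior width kappa = 1)
  r = -0.220 [weak], 95% CrI [-0.367, -0.054]
  BF10 = 3.06 (moderate), BF01 = 0.327
  pd = 99.5%, 5.5% of 95% HDI in ROPE [-0.10, 0.10]
```

Reading: in this simulated cohort the sample correlation between
muscle-specific corticospinal facilitation and hand-laterality reaction time
is -0.22 (the generating value is -0.3); the data favour an association by a
factor of about 3 (moderate evidence, below the study's stopping threshold of
10), the posterior is 99.5% negative, and only 5.5% of the credible mass sits
in the "practically zero" region.

The sequential design on a planning-style stream:

```r
xy <- generate_bivariate(140, 0.3, seed = 1)
run_sequential(xy[, 1], xy[, 2])
```

```
Sequential Bayesian correlation: decision H1 at n = 80
 look  n     kappa     r_obs      bf10       bf01
    1 70 1.0000000 0.3444560  9.711957 0.10296586
    2 80 0.7071068 0.3396617 17.315671 0.05775115
```

And the closed-form planning sample size:

```r
frequentist_n(0.3, 0.05, 0.95)
#> [1] 139
```

## Documentation

The methods vignette (`vignettes/imcor-methods.Rmd`) documents the models,
the noise-calibration algebra, every open design decision (prior family and
widths, shrinkage schedule, Gamma link, medial/lateral convention, QC
defaults) and the limits of what the synthetic world can establish.
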