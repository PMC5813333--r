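---
title: "Profiling hospitals with standardized ratios, an ordinal composite outcome, and rankability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling hospitals with standardized ratios, an ordinal composite outcome, and rankability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

In-hospital mortality, 30-day unplanned readmission and prolonged length of
stay (LOS) are the three outcomes most commonly used to compare hospitals on
quality of care.  They are interrelated in ways that complicate
interpretation: a patient who dies cannot be readmitted; a hospital that
keeps patients longer may "buy" lower readmission rates; and the sign of the
LOS-mortality association can differ between the patient level and the
hospital level.  `hospcomp` implements a full comparison pipeline for
admission-level administrative data:

1. **Case-mix adjustment.** Separate logistic regressions per
   diagnosis/procedure group and outcome, with backward elimination,
   produce an expected outcome probability per admission.
2. **Indirect standardization.** Summing expected probabilities per
   hospital gives the expected count E; the standardized ratio is
   $100 \cdot O/E$.
3. **Ordinal composite.** Each admission is graded 1 (alive, normal LOS,
   no readmission) to 5 (death), analysed with a proportional-odds model
   with hospital fixed effects; centred, exponentiated coefficients give a
   standardized composite rate.
4. **Rankability.** The fraction
   $100\cdot\tau^2/(\tau^2 + \mathrm{median}\,\sigma^2)$ of observed
   between-hospital variation attributable to true differences.

Because real multi-hospital administrative data cannot be redistributed,
the package ships a synthetic admission generator with *planted* hospital
effects and patient-level couplings, so that every stage of the pipeline
can be validated against a known truth.

# The synthetic cohort generator

## Generative model

For hospital $h$ a triple $(\eta^{mort}_h, \eta^{readm}_h, \eta^{los}_h)$
is drawn from a trivariate normal with variances
$(\tau^2_{mort}, \tau^2_{readm}, \tau^2_{los})$ and a configurable
correlation matrix, then centred to exact zero mean.  Volumes are uniform
on a configurable range, which creates the precision heterogeneity that
rankability is sensitive to.

Per admission, the generator draws a diagnosis group, a discharge year and
six case-mix covariates (five age bands; sex; unplanned admission;
transfer-in; urgent admission in the prior month; Elixhauser comorbidity
count).  Case-mix effects are log-odds ratios applied to *centred*
covariates, so switching them on does not move marginal outcome rates away
from the group baselines.  Outcomes follow logistic models:

$$\mathrm{logit}\,P(\text{death}) = \mathrm{logit}(p^{mort}_g) +
x^\top\beta_{cm} + \gamma_{year} + \eta^{mort}_h + \delta_{ml}\,L$$

where $L$ indicates a latent upper-quartile LOS (against the group's
baseline distribution) and $\delta_{ml}$ is the patient-level LOS-mortality
coupling; readmission (defined for survivors only, and stored as missing -
never 0 - for deaths) is analogous with coupling $\delta_{rl}$.

## LOS and the log-odds scale

LOS is log-normal per group.  We chose the log-normal because it is
right-skewed like real LOS and has closed-form quartiles, which makes
nearest-rank test oracles exact.  The hospital long-LOS effect
$\eta^{los}_h$ is specified on the *log-odds* scale (so that all three
$\tau^2$ are comparable and feed the same rankability machinery) and is
mapped onto the log-normal location: for $X \sim \log N(\mu, s)$,
$\partial\, \mathrm{logit} P(X > q_{75}) / \partial \mu \approx 1.695/s$,
so the generator shifts $\mu$ by $0.59 \, s \, \eta^{los}_h$, moving the
log-odds of exceeding a fixed upper-quartile cutoff by approximately
$\eta^{los}_h$.  The same conversion applies the (scaled) case-mix linear
predictor and calendar trend to LOS.

The coupling uses the *distributional* quartile at generation time while
the analysis re-estimates the *empirical* pooled quartile; the small
mismatch attenuates recovered couplings slightly and is accepted.

## The early-death mechanism

High-mortality conditions such as stroke kill early: patients who die have
*short* stays, while hospitals with high mortality also keep their
survivors longer.  With `early_death_short_los = TRUE`, deaths have their
LOS re-drawn from a short-stay distribution (location shifted by
`short_los_shift` = -1 log-days by default).  Together with a positive
correlation between $\eta^{mort}$ and $\eta^{los}$ this reproduces the
sign reversal between levels of analysis: the patient-level adjusted odds
ratio of long LOS on mortality is far below 1 while the hospital-level
correlation of standardized mortality and standardized long LOS (among
survivors) is strongly positive.  This is a Simpson-type pattern: the
within-hospital association and the between-hospital association involve
different groups of patients.

## Presets and defaults

Presets encode typical large-academic-hospital strata: overall mortality
3.1% and readmission (survivors) 7.8% with mean LOS 6.7 days
(`all_patients`, with planted couplings $e^{\delta_{ml}} = 1.45$,
$e^{\delta_{rl}} = 1.37$); stroke-like (13.6% mortality, early deaths);
colorectal-like (5.0% / 10.6%, longest LOS); heart-failure-like
(6.7% / 16.9%).  Between-hospital variances default to
$\tau^2 = 0.05/0.02/0.05$ (mortality/readmission/long LOS): on the odds
scale a hospital one standard deviation above average has about
$e^{0.22} \approx 1.25$ times the average odds, a realistic spread for
academic centres, with readmission deliberately tighter than the other
two outcomes.  The mortality-LOS hospital correlation defaults to 0.7
(0.9 in `coupled`), readmission independent.  All randomness flows from a
single seed through per-hospital sub-seeds, so cohorts are byte-identical
across reruns and hospital blocks are reproducible in isolation.

What the generator does *not* emulate: ICD-level coding (Elixhauser is
generated directly as a count), between-country structure, readmissions to
*other* hospitals, transfers-out, and within-year seasonality.  Passing
tests therefore demonstrate correctness of the estimators under a
plausible generative law, not performance on any particular real data set.

# Case-mix modelling choices

The full model contains the six case-mix variables, year (categorical -
no functional form is assumed), group (for pooled fits), and two a-priori
interaction candidates (age x Elixhauser, admission method x transfer).
Backward elimination removes one term per iteration - the eligible term
with the largest blockwise Wald chi-square p-value, if $p \ge 0.1$ - and
refits.  Specifics worth recording:

* **Blockwise tests.** A multi-level factor is one variable: it is kept or
  dropped as a block on a Wald chi-square over all its coefficients.
* **Hierarchy.** Interactions are eligible before their main effects; a
  main effect is eligible only when no retained interaction contains it.
  Consequently a shielded main effect can legitimately end with
  $p \ge 0.1$ in the final model.
* **Ties** are broken by reverse-alphabetical term name, making the
  procedure deterministic.
* **Sparse data.** Age bands with fewer than 10 events are merged into the
  immediately older band (the oldest merges downward) before fitting;
  groups with fewer than 25 admissions or 10 events get intercept-only
  models.  Zero-event intercepts use the empirical logit
  $(e + 0.5)/(n + 1)$ so predictions stay inside $(0,1)$.
* **Separation.** Non-converged fits are refitted with a small L2 penalty
  ($\lambda = 10^{-4}$) on non-intercept terms by a Newton solver and
  flagged; as a last resort the model is intercept-only.  A profiling run
  over hundreds of group models must degrade, never crash.
* Diagnosis group is treated as eliminable in pooled fits (the alternative
  - forcing it in - changes little because group baselines differ
  strongly and it is virtually always retained).

Maximum-likelihood logistic fits are perfectly calibrated in-sample
($\sum \hat p = \sum y$ per model), which is what forces the
all-hospitals standardized ratio to exactly 100 - a property the test
suite asserts at $10^{-6}$ relative tolerance.

# Long LOS, composite, and ordinal model

Long LOS uses the nearest-rank percentile (the
$\lceil p/100 \cdot n \rceil$-th order statistic) of the *pooled* within-
group LOS distribution (not per year), with strict exceedance, so ties at
the cutoff are never flagged.  Nearest-rank was chosen because it is
deterministic and oracle-checkable; pooling follows the definition of the
cutoff as a property of the group.  The 90th percentile serves as a
sensitivity definition; raising the percentile can only remove flags.

The composite grades survivors by (long LOS, readmission) as
$1\!=\!(F,F), 2\!=\!(T,F), 3\!=\!(F,T), 4\!=\!(T,T)$ and deaths as 5,
readmission ranking worse than long LOS.  The ordinal model is the
cumulative-logit proportional-odds model - the standard model behind "one
coefficient per hospital" - parameterized as
$\mathrm{logit}\,P(Y \le k) = \theta_k - \eta$, so a *positive* hospital
coefficient means higher odds of a *worse* level.  Readmission and
long-LOS standardized ratios, and the survivor flags entering the
composite, are computed over survivors; mortality over all admissions.

The standardized composite rate is
$100\exp(\beta_h - \bar\beta)$ with the unweighted mean over all
hospitals, the reference's 0 included; the geometric mean of rate/100 is
therefore exactly 1.  The reference hospital is the largest-volume one
(numerically convenient; the centring makes the choice immaterial, which a
test asserts).  One behaviour worth knowing: if a hospital is shifted by
$\delta$ on *all three component outcomes*, its composite coefficient
exceeds $\delta$ somewhat (intermediate cumulative splits compound several
shifted components), so the composite *amplifies* shared effects relative
to any single outcome.

Non-converged proportional-odds fits (e.g. monotone likelihood from an
all-best hospital) are retried by a BFGS optimizer on an unconstrained
parameterization (first threshold plus log-gaps) of the package's own
cumulative-logit likelihood with an L2 penalty of $10^{-4}$, with standard
errors from the numerical Hessian, and flagged.

# Rankability

$\tau^2$ for binary outcomes comes from a logistic random-intercept model.
Without covariates the data are aggregated to hospital-level binomial
counts and fitted with adaptive Gauss-Hermite quadrature (15 points);
with covariates a patient-level Laplace fit is used.  $\sigma^2$ comes from
the same model with hospital as a *fixed* effect; the reference hospital's
SE (identically zero by coding) is excluded from the median.

For the ordinal composite no random-intercept fitter is part of the
package's dependency set, and the estimation route is deliberately the
method-of-moments (DerSimonian-Laird) estimator applied to the centred
fixed-effect hospital coefficients with their squared SEs as
within-hospital variances, truncated at zero.  The two routes are
cross-validated in the test suite (agreement within 25% relative on a
planted-variance cohort).  Two caveats of the moments route are accepted
and documented: fixed-effect contrasts share the reference hospital's
estimation error (mitigated by choosing the largest hospital as
reference), and truncation makes small $\tau^2$ estimates sit exactly at
zero - which is also why, under a true null, the $\tau^2$ *estimate* is
the quantity that is near zero, while a single draw of the rankability
percentage is stochastic.

# The period comparison

The cohort is split at a calendar year; the proportions of admissions at
the best composite level are compared by a two-proportion chi-square test
*without* continuity correction - the uncorrected test is asymptotically
calibrated, and the test suite checks that its p-value is approximately
uniform under the null with type-I error near 5%.  Per-period $\tau^2$ of
the composite (moments route) quantifies whether hospitals converged over
time.

# Problem sizes

The test suite and the acceptance script run deliberately scaled-down
studies, chosen to keep the whole validation reproducible on a laptop
while leaving comfortable Monte-Carlo margins: cohorts of 26 hospitals
with 300-2,000 admissions each for recovery and correlation studies (8
replicates for ordinal-effect recovery, 200 for $\tau^2$ recovery, 100
for the correlation sign pattern, 40 for the early-death reversal, 25 for
the composite-rankability comparison), 1,000 fast replicates of 8 x 250
admissions for null calibration of the period comparison, and single
larger cohorts (26 x 5,000) where a point estimate rather than a
replicate distribution is assessed.  The acceptance script reports, for
scenarios at these scales, the quantities the pipeline computes: pooled
standardized ratios, patient-level odds ratios, hospital-level
correlations, standardized composite rates, rankability, and the period
comparison.

# Known limitations

* Expected counts come from in-sample fits; standardized ratios are not
  shrunken, and no funnel-plot control limits are provided.
* The proportional-odds assumption is not tested by default (the composite
  is *defined* through the ordinal fit); partial proportional odds is out
  of scope.
* The moments $\tau^2$ for the composite inherits the reference-contrast
  correlation noted above.
* Readmissions are same-hospital only, as in the data structure the
  generator emulates; cross-hospital linkage is out of scope.
* No explicit outcome weights: the composite's implicit weighting follows
  event frequencies, so the most frequent component (long LOS) dominates
  its variation.
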