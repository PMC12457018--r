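---
title: "Birth date, personality and metabolic rate: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Birth date, personality and metabolic rate: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paceline)
```

`paceline` implements, as a reusable and fully tested pipeline, an analysis
design common in field studies of pace-of-life syndromes in seasonally
breeding small mammals: repeated behavioural assays (starting-box and
open-field tests) and flow-through respirometry on the same free-living
individuals, combined into repeatability estimates, marginal
behaviour–metabolism associations, and a piecewise structural equation
model in which the date of birth within the breeding season drives both
personality and metabolic phenotypes. Because the motivating kind of
dataset is small and rarely deposited in full, the package ships a
synthetic-data generator that emulates the causal and noise structure of
such a study; every stage of the pipeline is exercised and validated
against it.

This vignette documents the models, the numerical choices, and the places
where a design decision was genuinely open.

## 1. Respirometry processing

Recordings come from a pull-mode (excurrent-flow) system: air is drawn at
roughly 700 ml min⁻¹ through a 1 l chamber and the downstream water-vapour
pressure, O₂ and CO₂ fractions are logged at 1 Hz, with a valve switching
between the animal chamber and an empty baseline channel.

**VO₂.** Whole-animal oxygen consumption is recovered by the classical
flow-through mass balance for an unscrubbed pull system with both gases
measured:

$$\dot V_{O_2} \;=\; FR_{dry}\,
  \frac{(F_iO_2 - F_eO_2) - F_eO_2\,(F_eCO_2 - F_iCO_2)}{1 - F_eO_2},
  \qquad FR_{dry} = FR\,\frac{BP - WVP}{BP}.$$

Water vapour is handled by dry-correcting the flow with the measured
water-vapour pressure; barometric pressure defaults to 101.325 kPa and is
configurable, since field stations rarely log it alongside the gas
channels. If the CO₂ channel is unavailable a fixed respiratory quotient
can be assumed instead (`use_co2 = FALSE`); the dilution terms cancel
exactly at RQ = 1.

**Baseline correction.** Analyser drift is removed by forcing each
baseline-channel segment's mean to the incurrent fractions; with two or
more segments the offset is interpolated linearly in time. This removes a
constant instrument offset exactly (tested by injection).

**RMR.** Resting metabolic rate is the lowest mean over all 30-s sliding
windows (stepping one sample) whose start falls in the last 10 min before
the first acoustic alarm, after discarding the first 10 min of the chamber
recording (airflow equilibration). Ties go to the earliest window. The
implementation is checked against an exhaustive brute-force window search
on a thousand random traces. RMR is mass-corrected by Kleiber allometry,
dividing by body mass^0.75.

**Acute-stress metrics.** The response to a 10-s acoustic alarm is
summarised by the maximum and the (trapezoidal) integral of VO₂ over the
minute following the alarm, each expressed relative to the resting rate
and reported as a percentage change (ratio − 1, in %). The percentage-change
convention is used because observed integral responses can be negative,
which a pure ratio cannot represent once offsets are added for
variance-stabilising transforms. The metric window is the closed interval
[alarm, alarm + 60 s]: the closed-form checks (flat response → (0%, 0%);
sustained +50% step → (50%, 50%); linear decay from twice resting →
(100%, 50%)) only hold when the onset sample is included. Sessions with
two alarms report the mean of the two; a session with no usable alarm
reports missing stress metrics but still yields an RMR.

## 2. Birth-date estimation

Age at first capture is estimated from body mass $M$ (g) by inverting a
juvenile Gompertz growth curve,

$$\text{age (days)} = \frac{\ln\!\big(\ln(88 / M)\big)}{-0.052} + 15,$$

with an asymptotic mass of 88 g. Only individuals captured at up to 65 g
are aged (≈ 38 days), where the mass–age relationship is still steep and
nearly linear; heavier first captures raise a distinct, catchable
eligibility error. Birth date is first-capture date minus estimated age;
calendar dates are rounded to whole days while analyses use the unrounded
numeric day-of-season (days since 1 July, the season origin — chosen
because parturition in the modelled system runs from mid-July to late
November).

Because growth-based ageing can convey false precision, the pipeline also
carries 14- and 28-day coarsened birth dates (bin midpoints, binned from
day 0 of the season) and re-runs the path models with them as a
robustness check. Bin midpoints rather than bin indices are used so the
coarsened variable stays on the day scale.

## 3. Mixed models

All analyses are random-intercept mixed models. The Gaussian
single-intercept case — the workhorse for the permutation tests — is fitted
by the package's own REML routine: the variance ratio
$\lambda = \sigma_u^2/\sigma_e^2$ is profiled out and optimised in one
dimension, with the inverse covariance applied through group sums, making
one fit cheap enough to repeat tens of thousands of times. On balanced
one-way designs the estimates coincide with the classical ANOVA
expected-mean-squares values (tested to 1e-6), and on general designs they
match `lme4::lmer` to optimizer precision (tested). Models with two
crossed random intercepts (individual identity and the count of previous
tests, as the path analysis uses) are fitted by `lme4::lmer`, and
binomial-logit models by `lme4::glmer` (Laplace), behind the same
interface.

**Standardization.** Continuous variables are centred and scaled so slopes
are standardized estimates; two-level factors (year, age class) are coded
−1/+1 and left unscaled. For binomial nodes slopes are standardized on the
latent scale: $\beta \,\mathrm{sd}(x) / \sqrt{\sigma^2_{fixed} +
\sum\sigma^2_{u} + \pi^2/3}$.

**Repeatability.** $R = \sigma^2_{ind} / (\sigma^2_{ind} + \sigma^2_{res})$
after adjusting for the number of previously experienced tests as a fixed
covariate; binary traits use the latent-scale version with the logit link
variance $\pi^2/3$. The permutation p-value shuffles individual-identity
labels across observations (the simplest scheme that destroys exactly the
grouping structure while preserving the response and the fixed design)
with $p = (\#\{R^* \ge R\} + 1)/(n_{perm}+1)$. The 95% CI is a parametric
bootstrap (simulate from the fitted model, refit); the CI method is a
package choice, made because variance-component CIs have no finite-sample
closed form in this setting.

**Fixed-effect permutation tests** permute the response vector across rows
with the design held fixed (two-sided on $|\hat\beta|$); residual
permutation is not offered because the exchangeable-rows scheme is exact
under the null of no fixed effect and matches the repeatability scheme in
spirit.

**The nine marginal association models** regress each metabolic response
(RMR, maximum stress, integral stress) on each behaviour separately, with
only an individual random intercept and deliberately no covariates: their
point is the *unadjusted* association that the path analysis later
decomposes. The stress responses are variance-stabilised first —
square-root after adding 9.76 (maximum) and natural log after adding 25.07
(integral). These fixed offsets are the default (`offsets = "paper"`)
rather than data-derived ones because the synthetic generator produces raw
stress values as exact inverses of these transforms, so the transform is
affine in the generating latent scale and standardized slopes survive the
round trip exactly; `offsets = "data"` (|min| + 0.01) is available for
ingested data with different ranges.

## 4. Piecewise structural equation model

The study DAG places the date of birth (and, for the metabolic node, year,
age class, ambient temperature, food abundance and body mass) upstream:
birth date → each of three behaviours; birth date + covariates +
behaviours → the metabolic response. The three behaviours form a
behavioural syndrome, modelled as *correlated errors* — undirected residual
associations estimated as residual correlations, excluded from the
independence tests. An inverted variant (metabolic response upstream of the
behaviours) is fitted for the direction-robustness check.

Each endogenous node is fitted by the matching mixed model (binomial-logit
for the binary entry trait) with individual identity and previous-test
count as random intercepts. Global fit uses directed separation: for every
non-adjacent pair without a correlated error and with at least one
endogenous member, the claim $x \perp y \mid pa(x) \cup pa(y)$ is tested by
adding $x$ to the regression of the topologically later variable $y$ on the
conditioning set, and the claim p-values combine into Fisher's
$C = -2\sum\ln p_i \sim \chi^2_{2k}$ (saturated model: $C = 0$, $p = 1$).
The union-of-parents conditioning set is used (rather than parents of the
dependent only) for consistency with mixed-model claim testing; the basis
set is verified in the test suite against a brute-force d-separation oracle
over the complete census of DAGs with up to five nodes. Pairs of two
exogenous variables carry no claim — there is no component model to test
them against. Claim p-values are model-based (Wald); simulation shows the
resulting Fisher's C rejects a correctly specified model at the nominal 5%
rate (200 replicates). Marginal R² is the fixed-effects variance over the
total (latent-theoretic for the binomial node).

Covariates without variation in a given dataset (e.g. age class when only
young adults were sampled) are dropped from component models and claims
with a warning, and the degrees of freedom count only testable claims.

## 5. The synthetic-data generator

The generator is first-class, tested code; it defines the study conditions
under which every downstream property is demonstrated.

* **Cohort structure.** 75 females by default, up to 4 test sessions
  (two at ~6–8 weeks, two at ~20–22 weeks), with independent Bernoulli
  survival (0.55 per later session) emulating field dropout; ~2% of
  sessions lose their behavioural or metabolic record independently, which
  exercises the both-data-present session filter.
* **Birth dates** are truncated-normal over the breeding window
  (days 14–147 from 1 July; mean day 80, SD 30). First-capture mass follows
  the forward Gompertz curve at a uniform 20–37.5-day capture age, so the
  ageing stage recovers the true birth dates to the half-day rounding of
  capture dates.
* **Causal structure.** Standardized latent variables receive the default
  generating slopes (birth → exploration 0.365, distance 0.267, entry
  0.448 on the latent scale, RMR 0.240, integral stress −0.316, maximum
  stress −0.274; temperature → RMR −0.234; year → RMR 0.723; all other
  edges, including every direct behaviour → metabolism path, zero). Each
  variable's residual variance is split between an individual random
  intercept and session noise according to its repeatability target
  (defaults follow the long-term design: entry 0.512 latent, distance
  0.323, exploration 0.378, RMR 0.393, maximum stress 0.097, integral
  stress 0.013), and the three behaviours' non-birth components share a
  0.4 residual correlation (the syndrome). The binary entry trait arises
  from a latent logit threshold whose unstandardized slope is back-computed
  so the configured latent-scale standardized coefficient holds exactly.
* **What the ICC targets mean.** They are conditional ICCs — the
  individual share of the variance *not* explained by fixed effects. When
  individual-constant fixed effects (year, birth date) are active, the
  raw unadjusted ICC of a variable exceeds its target; the fidelity checks
  therefore use configurations with the causal paths switched off.
* **Raw units.** Latent standardized values map to measurement units
  (distance in cm, exploration in % time, RMR in ml O₂ h⁻¹ g⁻⁰·⁷⁵); the
  stress variables map through the exact inverses of their
  variance-stabilising transforms, as discussed above.
* **Traces.** Each session's trace passes a piecewise animal-VO₂ profile
  (resting level from the session's RMR; alarm responses with
  instantaneous rise and fast + slow exponential decays, 20 s and 120 s;
  optional activity bouts) through a first-order chamber washout with time
  constant volume/flow = 1000/700 min ≈ 85.7 s, then adds a constant
  analyser offset (default 1e-4 fractional O₂, removed by the baseline
  stage) and Gaussian sensor noise (default SD 2e-5 fractional O₂ — a
  placeholder, as real instrument noise levels vary). Two alarms are
  spaced 900 s apart so the second response rides on a negligible tail of
  the first.
* **A physical limitation worth knowing.** A peak–decay response measured
  as a 1-min-window maximum downstream of an 85.7 s chamber lag can reach
  at most $(1 - e^{-60/\tau}) \approx 50\%$ of its instantaneous
  amplitude. The generator therefore works on the *observed* scale: the
  alarm amplitudes are solved (two-component least squares on the washed
  basis shapes) so that the processed trace reproduces the session's
  target stress metrics, rather than pretending instantaneous peaks
  survive the chamber. Sensor noise still inflates the observed 1-Hz
  maximum by a couple of percentage points — as it does on real hardware.

**What passing tests do and do not show.** The generator draws covariates
independently of birth date, uses Gaussian noise everywhere, has no
seasonal temperature–birth-date correlation, no within-day drift beyond a
constant offset, and no behavioural habituation trend across sessions.
Recovery of the generating coefficients therefore demonstrates the
correctness of the estimation machinery under the assumed causal
structure — not robustness to confounding structures the generator does
not contain.

## 6. Problem sizes and tolerances

The package's own validation runs at desk scale, chosen to make the Monte
Carlo error a small fraction of each tolerance: coefficient recovery uses
200 cohorts of 300 individuals × 2 sessions (tolerance ±0.05 standardized,
±0.10 for the latent binomial node); repeatability recovery uses 100
replicates at the short-term design size (56 individuals, ~82
measurements, tolerance ±0.08) with a 199-permutation null-uniformity
check; Fisher's C calibration uses 200 replicates of 100-individual
cohorts (nominal-rate band ±0.03). Permutation defaults are 10 000 in the
function signatures, as a full study would use, and smaller in the
pipeline configuration; every permutation and bootstrap count is reported
alongside its p-value or CI.

Numerical details: the REML profile is optimised on $\log\lambda \in
[-16, 12]$ with an explicit zero-variance boundary check; sliding-window
ties break to the earliest window; trapezoidal integration runs on the
native 1 Hz grid with endpoint interpolation; the washout is simulated by
the exact one-step exponential update, so steady states are reproduced to
machine precision rather than to an ODE-solver tolerance.

## 7. Known limitations

* Claim p-values in the d-separation tests are Wald-based; at much smaller
  sample sizes than validated here a permutation variant would be
  preferable.
* The correlated-error estimates between the binary entry trait and the
  Gaussian behaviours are response-scale residual correlations, an
  approximation to a latent tetrachoric/polyserial treatment.
* Only the model shapes this design needs are supported: at most two
  crossed random intercepts, Gaussian or binomial-logit families, no
  general formula interface.
* The generator does not simulate males, trapping logistics, or spatial
  lodge structure, and its noise defaults are plausible placeholders, not
  instrument calibrations.
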