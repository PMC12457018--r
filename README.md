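# paceline

Tools for asking whether "pace-of-life" correlations between animal
personality and energy metabolism are real or inherited from a shared
driver — the date of birth within the breeding season — in seasonally
breeding small mammals. The package was built around field studies of
free-living female bush Karoo rats (*Otomys unisulcatus*), where each
individual is repeatedly given a starting-box/open-field behavioural assay
(probability of entering the arena, distance travelled, % time exploring)
and a flow-through respirometry session (resting metabolic rate plus the
metabolic response to an acute acoustic stressor).

It implements the full analysis chain as reusable, tested components:

* **Respirometry** — pull-mode (excurrent-flow) trace processing:
  mass-balance VO₂ with dry-flow correction,
  `VO2 = FR_dry * [(FiO2 − FeO2) − FeO2 (FeCO2 − FiCO2)] / (1 − FeO2)`,
  baseline-channel drift correction, RMR as the lowest 30-s sliding-window
  mean in the last 10 min before the first alarm (Kleiber-corrected by
  mass^0.75), and maximum / integral metabolic stress responses over the
  minute after the alarm, as percentages of the resting rate.
* **Life history** — individual age from first-capture body mass by
  inverting the juvenile Gompertz growth curve
  `age = ln(ln(88/M)) / (−0.052) + 15`, hence date of birth; with 14- and
  28-day coarsened variants for robustness checks.
* **Mixed models** — random-intercept LMMs (own profiled-REML fitter for
  the single-intercept case, fast enough for 10⁴ permutation refits;
  lme4 for crossed intercepts and binomial-logit), GLMM-based
  repeatability `R = σ²_ind / (σ²_ind + σ²_res)` (latent scale with π²/3
  for binary traits) with parametric-bootstrap CIs and Monte Carlo
  permutation p-values, and the nine marginal behaviour × metabolism
  association models.
* **Path model** — piecewise structural equation modelling over a DAG with
  birth date upstream of three behaviours (correlated errors among them)
  and of the metabolic response; d-separation basis set, Fisher's
  `C = −2 Σ ln p ~ χ²(2k)`, standardized coefficients (latent-scale for
  the binomial node), marginal R², and an inverted-direction variant.
* **Synthetic data** — a generator that emulates the study's causal and
  noise structure end to end, including 1 Hz respirometry traces passed
  through a first-order chamber washout (τ = volume/flow ≈ 85.7 s), so the
  whole pipeline is testable without any field data.

## Worked example

Age and birth date from a first capture at 52 g on 15 September 2022:

```r
library(paceline)
estimate_birth_date("2022-09-15", mass = 52, individual_id = "F012")
#   estimated_age birth_date birth_date_numeric
# 1      27.35148 2022-08-19           48.64852
```

A synthetic respirometry session processed back into its summary
statistics:

```r
cfg <- generator_config(rng_seed = 42)
tr  <- generate_trace(list(v_rest = 1.4,           # ml O2 / min resting
                           alarm_amp_fast = -1.7,  # alarm response shape
                           alarm_amp_slow = 1.4), cfg)
tr
# <resp_trace> 2701 samples over 45 min; 300 baseline samples; 2 alarm event(s)
summarize_session(tr, mass = 98)
# <metabolic_summary> RMR 83.51 ml O2/h (2.681 ml/h/g^0.75 at 98.0 g);
#   max stress +31.8%, integral +13.2% (2 alarm(s))
```

The resting level is recovered within the sensor-noise tolerance (the
generating value is 1.4 ml/min = 84 ml/h), and the stress metrics are the
washed-out responses a real analyser would see.

The full study, simulated at the published design size (75 females, up to
4 sessions) and analysed end to end:

```r
report <- run_pipeline(pipeline_config(
  generator = generator_config(n_individuals = 75, rng_seed = 42),
  n_perm = 1000, rng_seed = 42))
report$paths$rmr
# <path_model_result> 4 component model(s)
#                  from          to   beta    se        p   family
# 1  birth_date_numeric       entry  0.454 0.116 8.69e-05 binomial
# 2  birth_date_numeric    distance  0.313 0.096 1.12e-03 gaussian
# 3  birth_date_numeric exploration  0.385 0.095 4.68e-05 gaussian
# 4  birth_date_numeric         rmr  0.258 0.065 7.68e-05 gaussian
# 5               entry         rmr -0.002 0.112 9.85e-01 gaussian
# 6            distance         rmr -0.045 0.059 4.47e-01 gaussian
# 7         exploration         rmr  0.037 0.062 5.49e-01 gaussian
# 8           year_code         rmr  0.684 0.058 1.39e-31 gaussian
# 9            age_code         rmr -0.098 0.054 7.15e-02 gaussian
# 10        temperature         rmr -0.226 0.049 3.35e-06 gaussian
# 11               food         rmr -0.084 0.048 8.15e-02 gaussian
# 12          body_mass         rmr  0.033 0.049 5.06e-01 gaussian
# Fisher's C = 21.00, df = 30, p = 0.888
# marginal R2: entry=0.206, distance=0.097, exploration=0.146, rmr=0.634
```

Reading this: later-born individuals are more likely to enter the arena
(β = 0.45 on the latent scale), travel further (0.31), explore more
(0.39) and have a higher RMR (0.26), while every *direct*
behaviour → RMR path is indistinguishable from zero — the
personality–metabolism correlation is carried by the shared birth-date
driver. Fisher's C (p = 0.89) does not reject the graph. The same report
contains the repeatability tables (e.g. long-term RMR R = 0.64,
95% CI 0.49–0.76, permutation p < 0.001 on this simulation) and the nine
marginal association models; `robustness_suite(report)` refits the path
models with 14-/28-day-binned birth dates and the inverted causal
direction.

Command-line wrappers live in `inst/cli/`:
`Rscript inst/cli/paceline.R run --out results --seed 1` and
`Rscript inst/cli/respiro.R --trace trace.csv --mass 98 --out summary.json`.

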