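# ivcoxsim

Calibrated Monte-Carlo evaluation of instrumental-variable (IV)
estimators for treatment effects on survival outcomes, for
biostatisticians and pharmacoepidemiologists who need to know when a Cox
proportional-hazards second stage can be trusted under unmeasured
confounding.

## The problem

Observational survival comparisons are biased when a confounder `U`
affecting both treatment `X` and outcome is unmeasured. A valid
instrument `Z` — associated with `X`, affecting the outcome only through
`X`, independent of `U` — promises a way out, but IV theory was built
for linear models and the hazard ratio (HR) is *non-collapsible*: the
marginal HR differs from the conditional HR even without confounding.
`ivcoxsim` quantifies the resulting bias by simulation. Each cohort is
generated as

- confounders: `(C1, L) ~ BVN(0, I, rho)`, measured `C1`, unmeasured
  `C2 = 1(L > 0.4)`;
- instrument: `Z ~ Bern(0.40)`, independent of `(C1, C2)`;
- treatment: `X ~ Bern(expit(a0 + az Z + s1 C1 + s2 C2))`;
- outcome: event time `T ~ Exp(lambda0 * exp(bx X + s1 C1 + s2 C2))`
  with `bx = log(true HR)`, censoring `D ~ Exp(c)`, administrative
  cut-off at `tau = 5`; observed `(min(T, D, tau), 1(T <= min(D, tau)))`.

`a0`, `az`, `lambda0` are calibrated by root-finding so each scenario
hits its target treatment prevalence (20–25%), instrument–treatment
odds ratio (~4–4.6) and outcome incidence (9–13%). Five estimators are
fitted per cohort — conventional adjusted Cox, two-stage IV (linear
first stage, Cox second stage on predicted treatment) and two-stage
residual inclusion (2SRI), the IV estimators with and without the
measured confounder in both stages — and HRs are pooled over replicates
(mean, with 2.5/97.5-percentile intervals).

## Worked example

Moderate confounding (strengths 1.5 measured / 2.0 unmeasured), true
HR = 3, 200 replicates of n = 10,000 (the full study uses 1000):

```r
library(ivcoxsim)
cfg <- scenario_preset("moderate")[[3]]   # true HR = 3
cfg$n_reps <- 200
par <- calibrate_scenario(cfg)
par
#> Calibrated scenario parameters
#>   treatment model: alpha0 = -3.5660, alpha_z = 2.2960, alpha_c1 = 1.500, alpha_c2 = 2.000
#>   hazard model: lambda0 = 0.002719, beta_x = 1.0986 (HR 3.000), gamma_c1 = 1.500, gamma_c2 = 2.000
#>   achieved: treat prev 0.2401, outcome incidence 0.1298, IV OR 4.576
#>   calibration: n = 1e+06, seed = 272559854

s <- run_scenario(cfg, params = par)
s
#> Scenario 'moderate', true HR = 3: 200 replicates used, 0 failed
#>   mean treat prev 0.240, outcome incidence 0.130, IV OR 4.57
#>   pooled hazard ratios (mean [2.5-97.5 percentile]):
#>     conventional_adj  adj    5.13 [4.53-5.84]
#>     two_stage_unadj   unadj  3.20 [2.17-4.45]
#>     two_stage_adj     adj    3.80 [2.57-5.40]
#>     tsri_unadj        unadj  1.55 [0.98-2.19]
#>     tsri_adj          adj    2.01 [1.31-2.83]
```

Reading the output: the conventional Cox model, blind to the unmeasured
confounder, overestimates the true HR of 3 badly (5.13). The
*unadjusted* two-stage IV estimate (3.20) brackets the truth; adding the
measured confounder to the IV model pushes the estimate away from the
truth (3.80) — the non-collapsibility effect, not a coding error. 2SRI
underestimates (2.01 adjusted). Single fits are available too:

```r
coh <- simulate_cohort(cfg, par, rep_index = 1)
summary(iv_coxph(coh, method = "two_stage", adjusted = FALSE))
```

A command-line interface with `calibrate`, `run` and `table` subcommands
ships at `inst/cli/ivsim.R`; scenario presets (`weak`, `moderate`,
`strong`) live in `inst/presets/` as editable YAML. See the vignette in
`vignettes/iv-cox-simulation.Rmd` for the model, calibration and design
choices in full.

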