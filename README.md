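# txmsm — multi-state comparison of transplant and non-transplant registries

`txmsm` is an R package for the survival comparison of two *separately
collected* cohorts: a transplant registry, whose patients exist in the data
only from the day of transplant, and a non-transplant (supportive-care)
registry. Such comparisons — typical for haematological registries, e.g.
transplant versus best supportive care in elderly patients with advanced
myelodysplastic syndrome — are structurally biased when done naively:

* measured from diagnosis, transplanted patients carry *immortal*
  pre-transplant person-time (left truncation / immortal-time bias);
* diagnosis-to-transplant waiting times are observed only when the
  transplant happened before the registry window closed (right truncation);
* nobody who died while waiting is in the transplant registry, so the
  transplant rate and the pre-transplant death rate are not estimable from
  it at all.

The package casts the problem as an illness-death model
Diagnosis → Transplant → Death (no recovery, death absorbing), with
transition intensities α₁₂(t), α₁₃(t), α₂₃(t) on the days-since-diagnosis
scale, and provides:

* **Estimators** — Kaplan-Meier and Nelson-Aalen with delayed entry, the
  reverse-time product-limit estimator F̂(t | T ≤ τ) for right-truncated
  waiting times, competing-risks cumulative incidence, and the
  Aalen-Johansen product integral P(s, t] = ∏ (I + dA(u)).
* **Reconstruction** — the from-diagnosis survival curve of the transplant
  *strategy*, 1 − P₁₃(0, t), built from the three estimable pieces under
  the Markov assumption (patients awaiting transplant die at the
  non-transplant registry's rate), next to the plain Kaplan-Meier of the
  non-transplant cohort.
* **Regression** — Cox partial likelihood (Breslow ties, Newton-Raphson)
  on counting-process data with transplant as a time-dependent state,
  piecewise and kernel-smoothed time-varying treatment effects, and a
  proportional-hazards score test on scaled Schoenfeld residuals.
* **A simulation engine** — piecewise-exponential illness-death cohorts
  with covariates, shared frailty, selection-on-risk and administrative
  censoring, plus the two registry sampling mechanisms and a replicated
  bias study quantifying each method's error against the latent truth.

## Worked example

Simulate the two-registry study under the `tv-effect` preset — transplant
confers a hazard ratio of 5.8 during the first three months after
diagnosis, an interpolated 2.4 up to one year, and exactly 1.0 afterwards —
then analyse it as one would analyse the real registries:

```r
library(txmsm)

ps   <- scenario_presets(n = 2000, seed = 42)
regs <- simulate_registries(ps[["tv-effect"]])
ds   <- assemble_multistate_dataset(
  validate_records(regs$non_tx_registry)$records,
  validate_records(regs$tx_registry)$records)

curves <- reconstruct_strategy_survival(ds)
print(curves)
#> From-diagnosis survival by treatment strategy
#>   transplant strategy : 4387 knots, median 688.8628 days
#>   non-transplant      : 1608 knots, median 869.8608 days
#>   identified up to tau = 2920.71 days (8.0 years)

fit_treatment_comparison(ds)
#> Cox model (Breslow ties), n = 3530, events = 2857, iter = 4
#>           coef    HR      se lower upper         p
#> tx_state 0.338 1.402 0.03879   1.3 1.513 2.929e-18

test_proportional_hazards(fit_treatment_comparison(ds))
#> Proportional-hazards score test (transform: km)
#>  covariate chisq df         p
#>   tx_state 61.55  1 4.319e-15
#>     GLOBAL 61.55  1 4.319e-15

fit_time_varying_effect(ds)
#> Time-varying treatment effect (piecewise log HR)
#>   start_y end_y  loghr     se   hr lower upper
#> 1    0.00  0.25 1.7523 0.1454 5.77 4.338  7.67
#> 2    0.25  1.00 0.8343 0.0801 2.30 1.969  2.69
#> 3    1.00   Inf 0.0832 0.0451 1.09 0.995  1.19
```

Read together: the pooled model reports a single "significant" hazard ratio
of 1.40 — but that number is an average over follow-up time. The
proportional-hazards test rejects constancy outright, and the piecewise fit
recovers the generating shape: severe early harm (HR 5.77, truth 5.8),
equivalence after the first year (HR 1.09, truth 1.0). A single average
hazard ratio would mischaracterise a treatment whose entire detriment is
concentrated in the early treatment-related-mortality window.

The reconstructed strategy curve (`curves$tx`) is the from-diagnosis
survival a cohort *intending* transplant would experience; in the
simulation it can be compared against the latent truth, which is what the
replication engine does:

```r
tab <- run_bias_study(scenario_presets(n = 2000)["s1-markov"],
                      n_reps = 100, seed = 1)
```

yielding, per method and horizon, the truth, bias, Monte-Carlo standard
error and interval coverage — the naive from-diagnosis Kaplan-Meier
overstates one-year survival by about +0.12 under these conditions, while
the multi-state reconstruction is unbiased to within Monte-Carlo error.

A thin command-line wrapper (`exec/txmsm`) exposes the same pipeline as
subcommands `simulate`, `sample-registries`, `fit`, `bias-study` and
`figures`, reading scenario YAML files and writing CSV/JSON.

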