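# akisem

Latent-variable modelling of cardiac surgery-associated acute kidney
injury (AKI) in infants.

After cardiopulmonary bypass (CPB) surgery, infant AKI emerges from
entangled processes — the bypass run itself, post-operative low cardiac
output syndrome (LCOS), age-related renal immaturity — and no single
measurement captures it: creatinine reacts late, urine output is
confounded by fluid management, and urinary NGAL marks tubular injury
specifically.  `akisem` treats AKI as a latent construct in a structural
equation model (SEM) with four constructs and thirteen observed
indicators:

```
CPB  ──0.596──▶ AKI ──0.684──▶ Outcome
  └──0.451──▶ LCOS ──0.347──────┘(▶ AKI)
```

* **CPB** measured by bypass duration, cross-clamp duration,
  ultrafiltration;
* **LCOS** by age (negative), systolic-pressure deficit, lactacidemia,
  day-0 transfusions;
* **AKI** by creatinine-normalized uNGAL, a >50 % creatinine rise and
  oliguria (each a duration-adjusted AUC);
* **Outcome** by ventilation duration, ICU stay and in-hospital mortality;

plus two residual covariance arcs (bypass duration ↔ uNGAL,
mortality ↔ ΔsCr>50 %).  Compound effects follow Wright's tracing rules —
the value of a compound path is the product of its constituent arrows, and
an association is the sum over all connecting traces — so the total
CPB → AKI effect is

```
0.596 + 0.451×0.347 + 0.997×0.137×0.508 = 0.822  (67.5 % shared variance)
```

The package is aimed at biostatisticians studying perioperative organ
injury who want the full pipeline as tested code: per-patient derived
metrics from raw trajectories (trapezoidal and threshold-deficit AUCs,
vasoactive-inotropic score, AKIN staging, fluid balance), exploratory
factor analysis with varimax rotation and the published refinement rules,
a maximum-likelihood SEM engine in RAM parameterisation (fit indices,
Lagrange-multiplier modification indices, BIC-guided respecification),
Wright trace enumeration, percentile bootstrap intervals, and a synthetic
cohort generator with the reference model as its default truth.

## Worked example

```r
library(akisem)

## the four published compound decompositions, from the coefficient table
aki_worked_effects()
#>           effect n_traces      total shared_variance_pct
#> 1     CPB -> AKI        3  0.8218842           67.549366
#> 2   AKI -> ungal        3  0.6107828           37.305564
#> 3 AKI -> Outcome        2  0.7409007           54.893384
#> 4     age -> AKI        1 -0.2293670            5.260922

## simulate a 200-infant cohort from the reference model and refit it
cfg <- cohort_config(n_patients = 200, seed = 42)
ind <- simulate_indicators(simulate_latents(cfg), cfg)
fit <- sem_fit(aki_model_spec(), ind)
fit$chisq; fit$df
#> 62.92 on 59 df
unlist(fit$fit_indices[c("rmsea", "nfi", "gfi", "bic")])
#>  rmsea    nfi    gfi      bic
#>  0.018  0.950  0.954 -249.686

subset(fit$standardized, label %in% c("CPB -> AKI", "CPB -> LCOS",
                                      "LCOS -> AKI", "AKI -> Outcome"))
#>           label       std
#>      CPB -> AKI 0.4744172
#>     CPB -> LCOS 0.4129085
#>     LCOS -> AKI 0.3834601
#>  AKI -> Outcome 0.7278077

## percentile bootstrap (200 case resamples) of the structural paths
sem_bootstrap(ind, fit$spec,
              list(`CPB -> AKI` = stat_path("CPB", "AKI"),
                   `LCOS -> AKI` = stat_path("LCOS", "AKI"),
                   `AKI -> Outcome` = stat_path("AKI", "Outcome")),
              B = 200, seed = 42)
#> Percentile bootstrap, B = 200 (0 failed), 95% CIs
#>       statistic estimate lower upper
#>      CPB -> AKI    0.474 0.314 0.622
#>     LCOS -> AKI    0.383 0.220 0.542
#>  AKI -> Outcome    0.728 0.631 0.830
```

The fitted paths at n = 200 scatter around their generating values (0.596,
0.347, 0.684) with the sampling error the bootstrap intervals quantify; at
n = 5000 the engine recovers every standardized path coefficient with mean
absolute error below 0.02 (see the test suite).  `run_pipeline()` chains
every stage — simulation (or your own CSV inputs), derived metrics, EFA
refinement, SEM fit, effect decomposition, bootstrap — and writes each
stage's artifact (CSV/JSON/DOT) plus a text report.  A thin command-line
front end lives at `inst/cli/akisem.R`.

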