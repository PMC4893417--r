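---
title: "Latent-variable modelling of cardiac surgery-associated AKI: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent-variable modelling of cardiac surgery-associated AKI: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(akisem)
```

## The scientific problem

Acute kidney injury (AKI) is a frequent and prognostically important
complication of cardiopulmonary bypass (CPB) surgery in infants.  Its
drivers are entangled: long bypass runs, post-operative low cardiac output
syndrome (LCOS), and age-related renal immaturity all plausibly contribute,
and no single measured variable captures "AKI" itself — serum creatinine
reacts late and is diluted by bypass priming, urine output is confounded by
fluid management, and urinary NGAL reflects tubular injury specifically.

This package implements a latent-variable treatment of that problem.  Four
constructs — **CPB exposure**, **LCOS**, **AKI** and post-operative
**Outcome** — are each measured by several observed indicators (bypass and
cross-clamp durations, ultrafiltration; age, arterial-pressure deficit,
lactacidemia, transfusions; creatinine-normalized uNGAL, a >50 % creatinine
rise, oliguria; ventilation duration, ICU stay, in-hospital mortality).
Structural paths connect the constructs
(CPB → AKI, CPB → LCOS, LCOS → AKI, AKI → Outcome), and two residual
covariance arcs (bypass duration with uNGAL; mortality with the creatinine
metric) absorb association not carried by the constructs.  The package
covers the full workflow: derived metrics from raw trajectories,
exploratory factor analysis (EFA) with refinement, maximum-likelihood
structural equation modelling (SEM), Wright path tracing, and bootstrap
inference — plus a synthetic cohort generator used to exercise and validate
every stage.

## Derived perioperative metrics

Repeated measurements are summarised as areas under the curve (AUC) by the
trapezoidal rule, integrating both the magnitude and the duration of a
deviation, and divided by the monitoring duration where a time-average is
the natural unit (`trapezoid_auc()`).  Threshold-type metrics integrate the
excursion beyond a clinical threshold with exact linear-interpolation
crossing points (`threshold_deficit_auc()`): oliguria as the area of urine
output below 0.5, 1 and 2 ml/kg/h over 24 h, and arterial-pressure deficits
below the cohort's age-stratum first quintile (ages ≤ 2 days, 3–28 days,
> 28 days; `pressure_quintile_thresholds()`).  The stratum boundary closes
the gap in the conventional "<2 days / 3–28 days" phrasing at ≤ 2 days.
Creatinine is summarised relative to its pre-operative baseline
(`delta_scr_metrics()`): the duration-adjusted AUC of `sCr/baseline − 1`,
and the integral of the excess above 1.5 × baseline — a magnitude-times-
duration reading of "> 50 % increase", not merely time above threshold.
AKIN staging uses the creatinine and renal-replacement criteria only
(`akin_stage()`); oliguria enters the analysis as its own metric, so the
urine-output staging criterion is deliberately not applied.  The
vasoactive-inotropic score uses the conventional weights (dopamine +
dobutamine + 100·epinephrine + 100·norepinephrine + 10·milrinone +
10000·vasopressin, µg/kg/min except vasopressin in U/kg/min).  Creatinine
is handled in µmol/L with a configurable mg/dl conversion (88.4).  AUC
normalisation uses each patient's actual monitoring duration rather than a
nominal 48 h.

## The synthetic cohort generator

There are two generators, reflecting two distinct uses.

**The structural generator** (`cohort_config()`, `simulate_latents()`,
`simulate_indicators()`) inverts the fitted measurement model, which is the
standard way to generate data for SEM parameter-recovery studies: latent
scores are drawn recursively along the structural DAG with residual
variances chosen so every construct has unit variance; indicators are
loading × latent + unique noise of variance 1 − loading²  (floored at
10⁻⁶); the two covariance arcs are imposed on the unique terms.  Defaults
are the reference standardized solution: cohort of 200, mortality rate 4 %,
CPB → AKI 0.596, CPB → LCOS 0.451, LCOS → AKI 0.347, AKI → Outcome 0.684,
and the thirteen loadings (age on LCOS negative, −0.661).  Covariance arcs
are parameterised as **residual correlations**.  That is a deliberate
reading: the bypass-duration loading of 0.997 leaves a residual variance of
0.006, so a residual *covariance* of 0.137 with the uNGAL indicator would
make the residual block non-positive-definite; as a residual correlation
the arc is generable and the generator's sampled residual correlations
converge to 0.137 and 0.197 as n grows.

Mortality deserves a note.  The indicator is produced by thresholding a
continuous propensity at the 96th percentile and is analysed as a numeric
0/1 column, as is conventional for in-hospital death.  Dichotomising at a
4 % rate mathematically caps the column's correlation with any normal
variable at `dnorm(qnorm(.96))/sqrt(.04*.96) ≈ 0.44`, so a binary mortality
column can never exhibit its generating loading of 0.652.  Cohort-level
realism (≈ 8 deaths in 200) uses the binary default; quantitative
parameter-recovery studies use `mortality = "propensity"`, because on the
binary scale exact recovery is impossible for any estimator — a
measurement-scale fact, not an engine limitation.

**The EFA-structure generator** (`simulate_efa_cohort()`) draws from the
orthogonal four-factor varimax solution instead.  The two references are
not interchangeable: the structural model implies strongly correlated
constructs (the CPB–AKI latent correlation is 0.596 + 0.451·0.347 ≈ 0.75),
and an orthogonal varimax solution of data generated that way spreads the
weak AKI loadings (0.44–0.51) across factors, landing near 0.3 — below any
reasonable significance bar.  Structure-recovery studies of the EFA
machinery therefore simulate from the orthogonal factor pattern, which is
the EFA's own model.

**The raw-trajectory generator** (`simulate_timeseries()`) emulates the
perioperative record: creatinine ramping to a patient-specific peak, hourly
urine output and arterial pressures, 6-hourly lactate, and uNGAL peaking
around 6 h, each anchored to a standardized target drawn from the
measurement model and mapped to clinical scale (e.g. bypass duration
118.2 ± 63.0 min, urine output 4.1 ± 2.7 ml/kg/h).  Curve shapes are
package inventions; only the induced correlation structure is contractual.
Two design points matter.  First, the renal anchors (creatinine, oliguria,
uNGAL) share a patient-level severity component (mixing weight 0.75) on
top of the AKI construct: one injured kidney drives all three trajectories,
and without that shared component the zero-inflated threshold metrics
correlate too weakly for any renal factor to survive refinement — no choice
of curve shapes avoids this, because the attenuation is a property of the
deficit transform.  Second, the 23-variable derived-metric set is refined
starting from the latent-root factor count (typically 7): families of
near-collinear metrics (three uNGAL readings, three oliguria thresholds,
creatinine metrics plus AKIN stage, systolic/mean pressure) first claim
factors of their own, and surrogate collapse plus the scree-style reduction
bring the solution down to four.  Forcing four factors up front starves the
weaker constructs instead.

## EFA and the refinement rules

Extraction is principal-axis factoring with iterated communalities started
at squared multiple correlations (maximum-likelihood extraction via
`factanal` is available behind `method = "ml"`), followed by
Kaiser-normalized varimax rotation with a sign convention (each factor's
largest loading positive).  The communality iteration caps estimates at
[0, 1] and switches to a half-step (averaged) update after 50 iterations:
the plain fixed-point map can enter a period-2 oscillation near degenerate
eigenvalues of the reduced matrix, and the damped map converges to the same
fixed point.  The default stopping rule is a maximum communality change
below 10⁻⁵.

Adequacy diagnostics are the Bartlett sphericity test
(χ² = −(n − 1 − (2p + 5)/6)·ln det R on p(p−1)/2 degrees of freedom) and
the Kaiser–Meyer–Olkin measure from the anti-image correlation matrix.

`efa_refine()` iterates: extract and rotate; drop the worst offender (one
variable per iteration); collapse one metric family to its best-loading
surrogate; repeat until stable.  Offences, in order of precedence: maximum
absolute loading below 0.400 (the significance bar for a sample of 200);
cross-loading (≥ 0.400 on two factors, the largest secondary loading goes
first); communality below 0.50.  The communality rule carries a deliberate
qualification: it applies only to variables *without* a significant loading
on exactly one factor.  Read literally, a communality-0.50 cutoff would
remove weak-but-clean construct markers (an oliguria burden loading 0.42
has communality ≈ 0.2), leaving the AKI construct unmeasurable — whereas
the rule's purpose is to remove variables the solution represents poorly
overall.  The number of factors is re-assessed by the latent-root criterion
each iteration (or fixed via `n_factors`), factors holding fewer than two
significant loadings are removed (the scree-style reduction), and
reductions persist for the remainder of the refinement.

A caution on the latent-root criterion: on data simulated from the
*structural* model, the population correlation matrix has only three
eigenvalues above 1 (5.06, 1.65, 1.32, 0.85, …) because the constructs are
strongly correlated — the classic situation in which the Kaiser rule
undercounts.  Structure-recovery exercises on the 13-indicator set
therefore pass the published dimensionality `n_factors = 4` explicitly.

## The SEM engine

Models are specified in RAM form (`sem_spec()`): a directed-coefficient
matrix `A`, a symmetric residual/exogenous covariance matrix `S`, and an
observed-variable selector `F`, with implied covariance
`F (I−A)⁻¹ S (I−A)⁻ᵀ Fᵀ`.  Estimation minimises the ML discrepancy
`F_ML = ln|Σ| + tr(SΣ⁻¹) − ln|S| − p` by quasi-Newton iteration with an
analytic gradient: with `B = (I−A)⁻¹`, `E = B S Bᵀ` and
`C = Σ⁻¹(Σ − S_obs)Σ⁻¹`, every element of the gradient is read off two
matrix products (`dF/dA[r,c] = 2(E C B)[c,r]`,
`dF/dS[r,c] = (2 − δ)(Bᵀ C B)[r,c]`), which keeps a 13-indicator fit under
20 ms and makes the 10 000-fit bootstrap studies practical.  Start values
are 0.5 for every free parameter; the convergence tolerance is 10⁻¹⁰ on
the relative change of the discrepancy; trial points with non-positive-
definite implied covariance are rejected by a penalty value.

Identification and scaling: exogenous latent variances are fixed at 1 and
endogenous latent *residual* variances are fixed at 1 (`"unit_variance"`,
the default; `"marker"` mode fixes the first loading instead).  Fixing
endogenous residuals is required, not cosmetic — leaving them free creates
an exact rescaling ridge (loadings down, paths and residual variance up)
along which the likelihood is flat and the information matrix singular.
The reported standardized solution rescales every coefficient to
unit-variance variables, so the reported numbers are invariant to the
scaling mode and to any rescaling of the observed variables.  By default
the correlation matrix of the data is analysed, so all output is
standardized; covariance arcs are reported as residual correlations,
matching the generator's convention.

Standard errors come from the inverse expected information
(I = (n−1)·½tr(Σ⁻¹dΣᵢΣ⁻¹dΣⱼ)); the test statistic is `(n−1)·F_min`.  Fit
indices follow the classical definitions: RMSEA
`sqrt(max(χ²−df, 0)/(df(n−1)))` (returned as 0 with a flag when df = 0);
NFI against the independence model; the ML-based GFI
`1 − tr[(Σ̂⁻¹S − I)²]/tr[(Σ̂⁻¹S)²]`; and BIC in the `χ² − df·ln(n)` form,
which is the variant that yields negative values for well-fitting
over-identified models.  Heywood cases (negative residual variance
estimates) produce a warning and are otherwise left alone by default —
with a bypass-duration loading of 0.997 the true residual variance is
0.006, and its estimate dips negative routinely in resamples of 200;
`bound_variances = TRUE` optionally constrains variances to be
non-negative.

Modification indices (`modification_indices()`) are score tests: the
expected chi-square drop from freeing an omitted parameter, computed from
the gradient and partitioned expected information at the restricted
optimum.  `sem_respecify()` runs the greedy Lagrange-multiplier loop —
free the top candidate, refit, keep if and only if BIC improves, stop
otherwise.  A structural caveat, demonstrated in the package's own tests:
under the residual-correlation reading of the arcs (the only generable
one), the population chi-square gain of the bypass-duration/uNGAL arc at
n = 2000 is 0.88, far below the BIC acceptance bar ln(2000) ≈ 7.6, so that
arc is rarely re-discovered from synthetic data even though the
mortality/creatinine arc (population gain ≈ 74) is found essentially
always.  The near-unity bypass loading leaves almost no residual variance
for the arc to live in; its detection in the original cohort reflects
covariance structure beyond what the published coefficients encode.

## Path tracing and compound effects

`enumerate_traces()` enumerates connecting routes by depth-first search
under Wright's rules: no variable twice, at most one two-headed arc, and
movement backward along arrows, then across at most one arc, then forward
(move strings matching `B* A? F*`).  The published compound arithmetic for
this model additionally uses traces that *bridge* a residual covariance arc
through the loading edges of its two indicators (pattern `B* F+ A B*`) —
for example CPB → durCPB ↔ uNGAL ← AKI, whose product 0.997·0.137·0.508
enters the CPB → AKI total.  Such traces violate the canonical collider
rule at both indicator endpoints; they are admitted by default because the
published decompositions require them, and `strict = TRUE` excludes them.
On canonical models (DAG plus exogenous covariances) the strict total
reproduces the model-implied correlation to 10⁻⁸, which the test suite
verifies against the RAM engine on random graphs.

`total_effect()` sums trace products; shared variance is `100 × total²`.
The four published worked decompositions are reproduced by
`aki_worked_effects()`: CPB → AKI 0.8219 over three traces, AKI → uNGAL
0.6108 over three, AKI → Outcome 0.7409 over two, and age → AKI −0.2294 as
the single compound through LCOS.  Two honest footnotes.  The age → AKI
figure is one route, not a total: full enumeration also admits the backdoor
age ← LCOS ← CPB → AKI (−0.661·0.451·0.596 ≈ −0.178), which the published
arithmetic omits; the function isolates the published route with
`exclude_nodes = "CPB"` and a plain `total_effect()` call reports the rest.
And shared-variance percentages quoted alongside 3-decimal totals square
the *rounded* totals (0.820² → 67.2 %); `report_effects()` prints both the
unrounded and the rounded-input percentage.

## Bootstrap inference

`sem_bootstrap()` draws case resamples of patients (not residuals), refits
the full model per resample, and forms percentile intervals by
linear-interpolation quantiles (type 7) of the stored per-resample values
— with B = 200 the quantile rule is visible at the 2.5 %/97.5 % points, so
it is fixed and documented.  Non-convergent resamples are redrawn up to
`max_retries` times, then counted; more than 20 % failures aborts.  The
percentile method (not BCa) is used, matching the era's standard practice
for SEM coefficient intervals; the model specification is held fixed
across resamples (respecification is not re-run inside the bootstrap).
Coverage under the default cohort conditions (n = 200, B = 200) is
verified in the test suite: the 95 % interval for the CPB → AKI path
covers its generating value in 49 of 50 outer replications.

## Problem sizes used in validation

Validation exercises in the test suite use: moment checks at n = 10⁵;
parameter recovery over 20 cohorts of n = 5000 (measured mean absolute
error of the 17 standardized path coefficients ≤ 0.015, bar 0.05);
structure recovery over 20 cohorts of n = 2000 (grouping reproduced in
18/20); respecification over 20 cohorts of n = 2000; bootstrap coverage
over 50 outer replications at the study scale n = 200, B = 200; oracle
agreement on ten one-factor models against `factanal`, ten two-latent
models against a brute-force minimiser, and three principal-axis fixtures
against `statsmodels`.

## Limitations

* The synthetic defaults reconstruct the indicator covariance from the
  published coefficient tables only; any residual structure of the original
  cohort beyond the two arcs is absent (and, for the raw-trajectory route,
  replaced by one explicit shared renal component).  Passing tests
  demonstrate the machinery recovers what it generates — not that the
  original clinical covariances equal the reconstruction.
* Cohort-specific fitted values of the original study (its RMSEA, NFI,
  GFI, BIC, Bartlett χ², KMO and exact loadings) require the non-public
  patient data and are emulated only qualitatively.
* The engine fits complete-data covariance/correlation matrices: no
  missing-data (FIML) estimation, no mean structure, and no ordinal link
  for the binary mortality indicator (analysed as numeric 0/1).
* Non-recursive (feedback) models are out of scope for both the engine's
  respecification search and the trace enumeration.
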