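---
title: "Methods: Bayesian estimation and dose individualization for daptomycin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian estimation and dose individualization for daptomycin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dapdose)
```

## The pharmacokinetic model

Daptomycin disposition is described by a linear two-compartment model with
zero-order intravenous infusion input. In amounts `X1` (central) and `X2`
(peripheral),

$$\frac{dX_1}{dt} = R(t) - (K_e + K_{cp})X_1 + K_{pc}X_2,\qquad
  \frac{dX_2}{dt} = K_{cp}X_1 - K_{pc}X_2,\qquad C = X_1/V_1 .$$

The population model is parameterized with micro-constants and two
covariates:

* `V1 = V1_std * WT/70` — the central volume scales linearly with body
  weight (the population value is expressed in L per 70 kg). No allometric
  exponent is applied; the linear form is what the standardization implies.
* `Ke = Ks * (CLCR/100) + Ki` — elimination splits into a renal component
  proportional to creatinine clearance (Cockcroft–Gault, in units of
  100 mL/min) and a non-renal component.
* `Kcp`, `Kpc` — transfer constants, covariate-free.
* Total clearance is the derived quantity `CL = Ke * V1`.

Defaults (`default_param_moments()`): V1 6.90 L/70 kg (CV 39.4%), Ks
0.050 h⁻¹ per 100 mL/min (CV 89.6%), Ki 0.060 h⁻¹ (CV 83.2%), Kcp 0.693 h⁻¹
(CV 118%), Kpc 0.667 h⁻¹ (CV 97.7%) — the summary moments of a
nonparametric population analysis in adults with bone and joint infection.

### Closed-form evaluation

Concentrations are evaluated exactly, not by numerical integration. The
dosing history is cut into segments of constant infusion rate; within each
segment the state is advanced with the analytic matrix exponential of the
2×2 disposition matrix written in Putzer form with eigenvalues −α, −β
(α + β = Ke + Kcp + Kpc, αβ = Ke·Kpc). When α and β coincide within a
relative 1e−10 the confluent limit (`r2 = t·e^{−αt}` instead of a
difference quotient) is used, which avoids catastrophic cancellation near
degenerate eigenvalues. All formulas are elementwise, so one call evaluates
thousands of candidate parameter sets simultaneously — this is what makes
the discrete posterior engine cheap.

Steady state under repetition of a dose every τ hours is obtained by
solving `(I − e^{Mτ}) x_ss = x_one(τ)` analytically (geometric accumulation),
never by simulating dose after dose. By convention the reported `Cmin` is
the concentration at the end of the interval and `Cmax` the concentration at
the end of the infusion; `AUC24 = daily dose / CL` exactly, a property of
linear kinetics that the tests verify to 1e−10. The terminal half-life is
`ln 2 / β`.

An independent oracle (`ode_oracle()`, stiff-safe `deSolve::lsoda` run
segment by segment with tolerances 1e−10/1e−12) shares no code with the
analytic engine and is used in the tests to confirm agreement to a relative
1e−6 on random parameter/regimen/time triples.

Time is in hours with t = 0 at the first dose start; times before the first
dose predict 0 mg/L. The infusion duration is not part of the population
model; the default is 0.5 h per dose event, configurable.

## Residual error and censoring

The assay error is a polynomial standard deviation
`σ(C) = c0 + c1·C + c2·C² + c3·C³` evaluated at the *predicted*
concentration, which keeps the likelihood well defined when an observed
value is near zero. Defaults: `c0 = 0.5` mg/L (a quarter of the 2 mg/L
lower limit of quantification) and `c1 = 0.1` (about the assay's stated
interday precision); both are configurable because only the family of the
error model, not its coefficients, is fixed by the assay description.

Observations below the LLOQ are left-censored: they contribute the
left-tail log-probability `log Φ((LLOQ − Cpred)/σ)` (M3-style) rather than a
density term. This is a documented assumption — commercial TDM tools do not
generally state their below-LLOQ policy. A side effect of evaluating σ at
the prediction is a small, known shift of the MAP optimum away from the
generating values when the proportional term dominates (the `−log σ(Cpred)`
term rewards smaller predictions); the tests therefore check exact
parameter recovery under a near-additive error model and realistic recovery
under the default one.

## The two Bayesian engines

**Nonparametric (discrete posterior).** The prior is a set of support
points with probability masses. Since the original support of the
population analysis is not published, `build_np_prior()` reconstructs a
prior by drawing support points from independent log-normals matched to the
published mean and CV of each parameter (`sdlog² = log(1+CV²)`,
`meanlog = log(mean) − sdlog²/2`), with equal weights. Log-normals are the
natural choice for strictly positive, right-skewed PK parameters, and the
posterior machinery is agnostic to the prior's provenance. Bayes' rule is a
reweighting, `w_j ∝ prior_j · L_j`, computed in log space with max
subtraction; the only pruning is numerical underflow (no weight floor above
1e−15). If every support point has zero likelihood the engine raises a
diagnostic error instead of returning a spurious posterior. Predictions and
steady-state exposure are posterior expectations over the full support;
the per-support table is returned alongside.

**Parametric (MAP).** Typical values of (CL, V1, Q, V2) carry independent
normal priors on the log scale, guaranteeing positivity. The covariate
topology is: CLCR and sex on CL, weight (power of WT/70, default exponent
1) on Q and V2; body temperature is deliberately excluded from the model.
Because the published coefficients of the manufacturer's model are not
available here, the shipped default derives its typical values from the
nonparametric moments at reference covariates (CL 0.759 L/h, V1 6.90 L,
Q 4.78 L/h, V2 7.17 L) and declares the CLCR effect in a renal-fraction
linear form `CL = TV_CL·((1−f) + f·CLCR/100)` with `f = Ks/(Ks+Ki) ≈ 0.45`,
consistent with the elimination split; the sex factor defaults to 1
(topology present, effect neutral) until a user supplies a published value
via `parametric_prior()` or a config file, which can also select a power
form. Between-subject sds on the log scale default to (0.65, 0.38, 0.95,
1.1), obtained by propagating the micro-constant CVs to the clearance
parameterization (delta method, independence assumed) and converting with
`sqrt(log(1+CV²))`.

The MAP objective (negative log posterior over log parameters) is minimized
from a fixed, deterministic multi-start schedule — the prior mode and four
±1-prior-sd perturbation patterns — each start running BFGS followed by a
Nelder–Mead polish (numerical-gradient BFGS can stall short of the optimum
when residuals are near zero). Line-search excursions into overflow return
a large finite barrier value instead of `Inf` so the optimizer can retreat.
With zero observations the covariate-adjusted prior mode is returned
directly: it is the analytic minimizer of the prior-only objective, and
short-circuiting keeps the identity exact. Parameters with zero
between-subject variability are held fixed.

## Dose individualization

Both target doses exploit dose linearity through per-support sensitivities
to 1 mg/day on a template schedule (default q24h, 0.5 h infusion):
`s_auc = 1/CL` exactly, and `s_cmin` from the analytic steady state. Two
objectives are available:

* `expectation`: `D = T / E[s]` — the dose whose posterior-expected metric
  equals the target. Resimulating this dose reproduces the target
  expectation by construction (the tests close this loop to 0.1%).
* `mm_squared_error` (default): `D = T·E[s]/E[s²]` — the minimizer of the
  posterior-expected squared deviation of the metric from the target, in
  the style of multiple-model dosage design. By Cauchy–Schwarz this dose is
  never larger than the expectation-targeting one, with equality only for a
  degenerate posterior.

The clinical sources name the targets (AUC24 = 666 mg·h/L; Cmin =
24.3 mg/L) but not the program objectives, so the objective is an explicit
mode flag on every recommendation. Doses are reported continuous in mg/day
and mg/kg/day; the nearest-10 mg "practical" dose is reporting only.
Percentile targeting (e.g. keeping the 95th posterior percentile of Cmin
under the bound) would be a natural extension and is not implemented.
The dosing interval is an input, not a decision variable.

## The synthetic cohort generator

`generate_cohort()` emulates the TDM study design the engines are meant
for: covariates from truncated normals (weight 76 ± 18 kg > 30; CLCR
103 ± 56 mL/min > 10; age 62 ± 17 y in 18–100; 42.5% women), daily dose
`round(mg/kg draw · weight)` with policy 7.6 ± 1.3 mg/kg/day, q24h
infusions, and a three-sample occasion: pre-dose trough, an early sample
0.5 h after infusion *start*, and a late sample uniform in 5–6 h post dose,
each with ±15 min uniform jitter. "30 min after administration" is
ambiguous between infusion start and end; the generator defaults to start
(`peak_after = "start"`) and exposes the switch. The sampling occasion
defaults to dose 5 — near steady state for a terminal half-life around
13–17 h. True parameters are drawn from the discrete prior's support by
weight; observations get Gaussian assay noise and values below 2 mg/L are
censored and flagged. Covariate draws are independent because only
marginals are reported for the source population; real covariates
(weight–CLCR in particular) are correlated, and the generator makes no
claim there.

What passing tests show: that the engines recover what generated the data
under the stated design — internal consistency, identifiability under the
sparse design, and correct plumbing. What they do not show: performance on
real patients, where model misspecification, occasion-to-occasion
variability, covariate error and assay differences all enter. The
published clinical performance figures derive from real cohorts that are
not deposited, and this package makes no attempt to reproduce them
numerically.

## Evaluation statistics

`mean_error()` and `mape()` implement the standard bias/imprecision
definitions (`Σ(Cpred−Cobs)/n`; `mean |Cpred−Cobs|/Cobs`, in percent).
Censored observations are excluded from prediction pairs (their count is
reported) since a percent error has no point value for them.
`bland_altman()` reports classic limits of agreement `mean(d) ± 1.96·sd(d)`
and fits `d ~ average`; when the slope is significant at α = 0.05 (the
criterion is stated in the sources, the α is our choice) the reporting mode
switches to regression-based bands (fitted line ± 1.96·residual sd) — the
decision is made per dataset by the slope test, not hard-coded per
quantity. Zero-variance averages force classic mode. Rank tests use the
exact distribution for n ≤ 25 and the continuity-corrected normal
approximation above; identical paired samples are reported as "test
undefined" rather than p = 1. Target-attainment fractions use strict
inequalities (AUC24 < target; Cmin > limit).

## Problem sizes and numerical settings

The shipped tests exercise: 100 random parameter/regimen/time triples
against the ODE oracle (relative 1e−6); steady state against 60-dose
superposition (1e−4); discrete priors of 200–4000 points; a 200-patient
sparse-design recovery cohort with a 1000-point prior; 50 rich-design MAP
recovery patients; and 1e4-pair Bland–Altman coverage. These sizes make the
statistical checks stable while keeping a full run to a few minutes on one
core; the vectorized engine fits a 200-patient cohort with a 1000-point
prior in about a second, so larger priors are entirely practical in use.
All stochastic components take explicit integer seeds and restore the
caller's RNG state; identical seeds give bit-identical cohorts, fits and
reports.

## Known limitations

* Linear kinetics only: no saturable elimination or protein-binding
  dynamics, no tissue (bone) compartment.
* Single-occasion fitting: no inter-occasion variability; the steady-state
  summaries assume the nominal interval repeats even when the recorded
  history is irregular (the history is used for fitting, the interval for
  steady state).
* The reconstructed discrete prior is moment-matched, not the original
  support; independence across parameters is assumed.
* The default parametric prior is a documented self-contained stand-in for
  the unpublished manufacturer coefficients; users with access to them
  should supply them via configuration.
* No MCMC for the parametric model — the point MAP is what the comparison
  calls for; no model averaging across engines.
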