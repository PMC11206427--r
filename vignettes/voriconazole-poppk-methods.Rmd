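---
title: "Methods: population pharmacokinetics of voriconazole in the ICU"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population pharmacokinetics of voriconazole in the ICU}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voripopk)
```

## The model

voripopk implements a two-compartment population pharmacokinetic (PopPK)
analysis of voriconazole in critically ill patients, together with the
Monte Carlo dosing simulations that such an analysis feeds. Disposition is
linear: central volume $V_c$, peripheral volume $V_p$, intercompartmental
clearance $Q$ and elimination clearance $CL$, with zero-order infusion
input for IV dosing and first-order absorption (rate constant
$K_a = 1.2\,h^{-1}$, fixed by convention from prior literature, as richly
sampled absorption-phase data are rarely available in an ICU TDM design)
for oral and nasogastric dosing, which share one bioavailability $F$.
Concentrations are evaluated with the closed-form bi-/tri-exponential
solutions and superposition; a dose record flagged as steady state stands
for the whole established regimen (it supersedes earlier dose events and
uses the exact accumulation factors), which is how routine
therapeutic-drug-monitoring troughs are represented.

Between-subject variability is lognormal, $P_i = P_{pop}e^{\eta_i}$, with
diagonal variances on $CL$, $V_c$ and $V_p$ ($Q$ carries none), and the
residual model is combined:
$C_{obs} = C_{pred}(1+\varepsilon) + \varepsilon'$ with proportional SD
$\sigma_{prop}$ and additive SD $\sigma_{add}$ (mg/L). Reported %CV values
for the random effects are interpreted as $100\,\omega$ directly, the
usual pharmacometric reporting convention at these magnitudes; the exact
lognormal transform is available through `omega_from_cv(...,
"lognormal")` for users who prefer it.

Clearance carries the covariate model

$$CL = CL_{tv}\,
\left(\tfrac{qCRP}{73.6}\right)^{-0.142}
\left(\tfrac{CL_{CR}}{71.8}\right)^{0.218}
1.46^{\,CRRT}
\left(\tfrac{PLT}{144}\right)^{0.166}
\left(\tfrac{PT}{15}\right)^{-0.875} e^{\eta_{CL}},$$

i.e. inflammation (quick C-reactive protein) and prolonged prothrombin
time lower clearance, while renal function, platelet count and continuous
renal replacement therapy (CRRT) raise it. Signed exponents are stored as
printed in the equation above; published parameter tables often list their
magnitudes only, so the sign lives in the effect definition
(`vori_final_cov_effects()`). The normalisation constants are the
equation's printed values, not cohort medians, which differ slightly.
`vori_final_model()` returns this model with the published estimates
($CL_{tv}$ 3.55 L/h, $V_c$ 33.5 L, $V_p$ 138 L, $Q$ 52.8 L/h, $F$ 0.835,
$\omega_{CL}$ 49.8 %CV, $\sigma_{prop}$ 8.9%, $\sigma_{add}$ 0.192 mg/L).

Half-life is reported two ways because the conventions genuinely differ:
the hybrid terminal half-life $\ln 2/\beta$ is about 35 h at the typical
parameters, while grouped summary tables in this literature report roughly
6 h, which is reproduced by the mono-compartmental convention
$\ln 2\,V_c/CL$. `steady_state_metrics()` returns both, the latter as
`half_life_table3`; the reconstruction of that convention is an inference
from the printed medians, not a claim about how any particular table was
derived.

## Estimation

`pk_fit()` maximises a FOCE-style marginal likelihood: for every subject
the integral over $\eta$ is approximated by a Laplace expansion at the
empirical-Bayes (posterior-mode) $\eta_i$, with interaction — the residual
variance $g_{ij} = (f_{ij}\sigma_{prop})^2 + \sigma_{add}^2$ is evaluated
at the conditional predictions — and numerically differentiated
3×3 Hessians. The per-subject inner searches are a damped Newton iteration
written in C++ (gradient tolerance $10^{-7}$, always started from the
prior mode so the objective is a deterministic function of the parameters;
warm-starting across outer iterations is deliberately avoided because it
makes the objective history-dependent). With all $\omega = 0$ the
objective reduces to the exact fixed-effects Gaussian $-2\log L$.
Below-quantification observations (assay limit 0.097 mg/L) are excluded
from the likelihood (M1) and counted.

Accuracy of the Laplace approximation was checked against adaptive
quadrature: on rich 7-sample profiles agreement is $\sim 3\times10^{-5}$
relative; on a single-trough subject it degrades with $\omega$ (about
$5\times10^{-4}$ relative at $\omega = 0.1$, $0.4\%$ at $\omega = 0.5$).
This is the expected behaviour of all FOCE-class estimators on sparse
data and is the reason sparse-data variance estimates are biased in
well-documented ways; the test suite pins the approximation at the
configurations where the tolerance is meaningful.

The outer problem works on an unconstrained scale: log for positive
parameters, logit for $F$, identity for signed power exponents, log for
the CRRT multiplier. $K_a$ is never estimated; $F$ is only estimated when
the data contain extravascular doses (fixed with a warning otherwise);
omegas fixed at zero stay fixed. Because the marginal surface is
multimodal along weakly identified directions (notably $V_p$ and
$\omega_{V_p}$ under a trough-dominated design), the default optimiser is
a Nelder–Mead pre-search (3000 iterations) followed by a BFGS polish with
finite-difference gradients (relative step $10^{-4}$); straight BFGS from
starting values 50% off can stall in a basin with $CL_{tv}$ biased by
+18%, which the simplex stage escapes. Convergence is `optim`'s relative
tolerance $10^{-8}$ on the objective.

Standard errors come from the inverse of the central-difference Hessian of
the objective (step $5\times10^{-4}$; covariance $2H^{-1}$), delta-mapped
to the natural scale, reported as RSE%. When the Hessian is singular along
flat directions a Moore–Penrose pseudo-inverse is used and the fit is
flagged (`hessian_pd = FALSE`) — the analogue of a covariance-step
failure, which on this design affects the peripheral-compartment
variances, not the clearance-side parameters.

Covariates vary by occasion: the covariate model is evaluated with the
values in effect at each observation row, so a CRRT session raises that
occasion's clearance. Each occasion at steady state is treated as fully
equilibrated under its covariates; re-equilibration transients between
occasions (days apart relative to a 1–2 day effective accumulation time
under the dominant regimen) are neglected.

## Covariate selection

`select_covariates()` is a stepwise covariate model build on clearance
only: forward inclusion accepts the largest objective-function drop when
it exceeds 3.84 ($\chi^2_1$, p < 0.05), one covariate per cycle;
backward elimination removes the covariate whose deletion raises the
objective the least when that increase is below 7.88 (p < 0.005); a final
precision rule drops retained effects with RSE above 50%. Continuous
candidates enter as power terms normalised to the dataset median;
flags as factor terms. Ties break by larger drop then alphabetically, and
non-converged candidate fits count as no improvement, so a trace replays
identically on the same data. The published model's normalisers override
the medians when the final model is used for simulation.

## Diagnostics

`cwres()` computes conditional weighted residuals from the FOCE
linearisation at the empirical-Bayes modes — covariance-whitened
residuals, approximately N(0,1) under a correct model (mean within ±0.1,
SD within 0.9–1.1 and ≥93% of $|CWRES| \le 2$ on data simulated from the
model itself in the suite's calibration runs). `pk_bootstrap()` resamples
subjects with replacement (study convention: 1000 resamples), refits from
the point estimates for speed, excludes and counts failed fits, and
reports medians with 2.5/97.5 percentiles. `pcvpc()` is a
prediction-corrected visual predictive check: observations and simulated
replicates are scaled by bin-median over own population prediction,
binned on time-after-dose (8 quantile bins by default; bins under 5
observations merge with a neighbour; steady-state records wrap time after
dose modulo the interval), and the observed 5th/50th/95th percentiles are
compared with their simulated 95% confidence bands (1000 replicates by
convention). The correction uses the plain ratio form; corrected sets
contain no BLQ observations, mirroring their exclusion from estimation.

## Monte Carlo dosing simulations

`pta_table()` reproduces the dosing-table design: 1000 simulated subjects
per scenario over doses {200, 250, 300} mg q12h (1-h IV infusions), qCRP
strata {40, 80, 160} mg/L, CRRT yes/no and MICs
{0.016, 0.032, 0.25, 0.5, 1, 2, 8, 16} mg/L — 144 scenarios. The PK/PD
target is $fAUC_{24}/MIC > 25$ with free fraction 0.42 (58% protein
binding). Exposure uses the steady-state identity
$AUC_{24} = F\cdot\text{daily dose}/CL$ (F = 1 IV), chosen because the
monitoring condition the model describes is steady state; a first-day
numerical AUC would only lower attainment in the transient. Under that
identity only $\eta_{CL}$ affects attainment, so only it is sampled, and
the remaining covariates sit at the model's standardised references
(CL~CR~ 71.8, PLT 144, PT 15). Residual (assay) error is excluded: the
target is a true-exposure construct. One $\eta$ vector is shared across
scenarios (common random numbers), making the tabulated attainment
exactly monotone — non-increasing in MIC, non-decreasing in dose, lower
under CRRT, higher at higher qCRP — and each cell also agrees with the
closed-form lognormal probability
$\Phi\!\big(\log(CL^*/CL_{typ})/\omega_{CL}\big)$,
$CL^* = f_u\,\text{daily dose}/(25\,MIC)$, to within binomial noise.
Saturated cells (e.g. 100% at MIC 0.016 and 0% at MIC 16 for 200 mg q12h,
qCRP 40, CRRT) are insensitive to the AUC convention; intermediate cells
are not exactly recoverable under any single simple configuration, so the
package treats them as structurally (monotonicity, CRRT direction), not
cell-exactly, comparable.

## The synthetic cohort generator

`generate_dataset()` emulates the study design so the whole pipeline is
testable without patient data: 408 subjects by default, ~10% contributing
an intensive steady-state profile (pre-dose, end of 1-h infusion, and 2,
4, 6, 8, 12 h — 7 samples, matching both the stated sampling scheme and
the cohort's ~6.8 points per intensively sampled subject) and the rest
routine steady-state troughs 30 min before a dose, a quarter of them with
a second monitoring occasion four days later (the second occasion redraws
the CRRT flag with 0.7 persistence and jitters qCRP); this scales to
~746 observations at n = 408. Routes follow the cohort mix (68.1% IV,
11.0% oral, 20.8% nasogastric; intensive subjects are IV because the
schedule is infusion-anchored), regimens are dominated by 200 mg q12h
(83.8%) with the remainder over 100–300 mg q12h, and CRRT/ECMO
prevalences are 24%/22%. Continuous covariates are independent lognormals
matched to the cohort's median/IQR, with the mean-log calibrated so the
median is preserved after truncation to physiologic ranges (the heavy
qCRP tail would otherwise shift ~8%). Prothrombin time is not tabulated
in the cohort; its distribution (median 15 s, IQR 13–18 s) is a
plausibility stand-in and is documented as such. Negative simulated
concentrations are resampled rather than truncated (no point mass at
zero); BLQ values are flagged at 0.097 mg/L and retained in the file.

What the generator deliberately does not emulate: covariate correlations
(real inflammation, coagulation and liver markers co-move; decoy
covariates are generated independent of clearance precisely so selection
specificity is testable), CYP2C19 genotype and drug interactions,
nonlinear (saturable) elimination, dose adjustments reacting to measured
levels (feedback), and assay batch effects. Passing recovery tests on
this generator therefore shows the estimation machinery is correct and
calibrated under the stated design — not that the published model is the
true data-generating process for any real ICU population.

## Problem sizes and numerical choices

The test suite runs reduced configurations chosen to keep the default
check fast while still exercising every claim: recovery smoke tests at
100 subjects (the acceptance script runs the full 408), bootstraps of
10–12 resamples on 40–50 subjects, VPCs with 100–200 replicates,
selection runs with 2 generating covariates and 1–2 decoys around 100
subjects. Monte Carlo attainment always runs at the full n = 1000 per
scenario (the whole 144-cell table takes well under a second). Recovery
of $CL_{tv}$, the CRRT multiplier, $F$ and $\omega_{CL}$ from a full-size
synthetic cohort is typically within a few percent; $V_p$, $Q$ and the
volume-side omegas are weakly identified under a trough-dominated design
with 12-h intensive windows (terminal half-life ~35 h) and can wander far
with little objective change — visible in their RSEs and bootstrap
spreads, and the reason the covariance step sometimes needs the
pseudo-inverse fallback.

Other conventions: time in hours, amounts in mg, concentrations in mg/L;
dose times are absolute hours from first dose; serum creatinine enters
the Cockcroft–Gault equation in µmol/L (converted internally by 88.4);
sex is coded 0 = male, 1 = female; infusion duration defaults to 1 h when
unrecorded (`DUR` takes precedence over `RATE` when both appear in a
file). Kinetic degeneracies are guarded explicitly: $K_a$ colliding with
a hybrid rate constant is nudged by $10^{-7}$ relative, $Q = 0$ is
rejected (the system is then mono-compartmental by construction), and the
stable companion-root form $\beta = k_{10}k_{21}/\alpha$ avoids
cancellation.
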