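---
title: "Methods: population PK and PK/PD cutoff determination for benzylpenicillin in horses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population PK and PK/PD cutoffs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
structural and statistical model, the PK/PD index and cutoff machinery,
the estimator, the synthetic-data generator, and the numerical and
design choices made where the design was genuinely open.

## The structural model

Benzylpenicillin (BP) disposition in the horse is described by a
mammillary compartment model parameterized in clearances and volumes:
central volume $V_c$, peripheral volumes $V_2, V_3$ (mL/kg), plasma
clearance $CL$ and inter-compartmental clearances $CL_2, CL_3$
(mL/kg/h). A three-compartment model is the default (a low assay
quantification limit makes a slow third disposition phase identifiable);
$CL_3 = 0$ degenerates to two compartments and $CL_2 = CL_3 = 0$ to one.
All formulations share these disposition parameters and differ only in
how the dose enters the central compartment:

* **IV bolus / zero-order infusion** for the aqueous sodium and
  potassium salts;
* **single first-order rate constant** $K_a$ with bioavailability $F$
  for procaine BP suspensions;
* **two sequential rate constants separated by a lag**: the depot drains
  at $K_{a1}$ (rapid) until $T_{lag}$ after the dose, then the remaining
  amount drains at $K_{a2}$ (slow) — IM sodium BP, whose absorption is
  biphasic;
* **two parallel first-order inputs** with a dose split $p$ /
  $1 - p$ — the procaine + benzathine combination, one input per prodrug
  moiety;
* **a sequential dual input per injection site** — penethamate, given at
  several sites whose depots absorb independently.

Secondary parameters follow the standard definitions:
$V_{ss} = V_c + V_2 + V_3$, $MRT = V_{ss}/CL$,
$t_{1/2} = \ln 2/\lambda_z$ with $\lambda_z$ the smallest exponential
rate, and the mean absorption time $MAT = 1/K_a$ per rate constant.
When $1/K_a \gg MRT_{iv}$ the terminal phase of the IM profile reflects
absorption, not elimination (flip-flop); the test suite verifies this
numerically (IM procaine has $MAT \approx 21$ h against an IV terminal
half-life of about 1.5 h).

## Closed-form simulation

Every input above decomposes into three primitives whose central-
compartment response is an exact finite sum of exponentials:

* a central **bolus**, with coefficients from the eigen-decomposition of
  the rate matrix. Mammillary matrices are similar to symmetric ones
  (inter-compartmental fluxes balance), so the decomposition uses either
  the analytic cubic/quadratic root formulas or, near repeated roots, a
  symmetric eigenproblem — which always diagonalizes, avoiding defective
  cases;
* a **first-order depot**, by analytic convolution of the depot outflow
  with the bolus impulse response,
  $K_a A_0 \sum_i A_i \frac{e^{-\lambda_i t} - e^{-K_a t}}{K_a - \lambda_i}$;
* a **step input** (infusion on/off), by integrating the impulse
  response.

The rate-switching sequential depot needs no ODE either: by linearity
and time invariance it equals a full $K_{a1}$ input, minus a $K_{a1}$
input of the amount remaining at $T_{lag}$ restarted at $T_{lag}$, plus
a $K_{a2}$ input of that amount. A profile is therefore a table of
$(t_0, c, \lambda)$ terms, evaluated in closed form at any time and
integrated exactly — multi-dose mass balance
$AUC_{0\to\infty} = F \sum D / CL$ holds to near machine precision, and
the test suite checks the profiles against an independent stiff ODE
solution (`deSolve::lsoda` at tolerances 1e-10/1e-12). An ODE fallback
in the production path was considered and rejected: the exact
decomposition covers every supported input, is faster by orders of
magnitude inside the estimator's nested loops, and removes solver
tolerance as a source of error. When an absorption rate collides with a
disposition rate (a removable singularity of the convolution formula),
$K_a$ is nudged by 1 part in $10^7$ — far below any practical
identifiability — rather than switching to repeated-root algebra.

## The population layer

Between-subject variability (BSV) is exponential:
$\theta_i = \theta_{tv} e^{\eta_i}$, $\eta \sim N(0, \Omega)$, so
sampled parameters are strictly positive and BSV is reported as
$CV\% = 100\sqrt{e^{\omega^2} - 1}$. $\Omega$ may be a full covariance
(the packaged IV model ships the complete 6x6 matrix) or a diagonal
built from CV% values. The random-effect ordering is fixed as
($V_c$, $CL$, $V_2$, $V_3$, $CL_2$, $CL_3$, then absorption parameters)
and model files declare it explicitly. Bioavailability with a random
effect is sampled on the inverse-logit scale, keeping $F \le 1$.

The "source of dataset" acts as a categorical covariate on clearance,
$\theta_{source} = \theta_{ref} e^{d}$. The packaged final model carries
the published coefficients for Sweden, USA1 and USA2 plus log-ratio shifts
reproducing the Bayesian clearance estimates for the Japanese horses and
the Swedish horses dosed only IM (411 and 351 mL/kg/h against the
481 mL/kg/h reference).

Residual error is additive plus proportional,
$C_{obs} = C(1 + \varepsilon_p) + \varepsilon_a$; negative simulated
observations are floored at zero with a logged count. The unbound
fraction is a fixed constant $f_u = 0.4$ (no BSV), consistent with
reported plasma protein binding near 63%; treating it as fixed is
conservative for the cutoff because adding artificial $f_u$ variability
would only widen the index distribution.

### Variability settings for the cutoff simulations

The cutoff simulations use a diagonal $\Omega$ from the final-model BSV
values — CL 26.4%, $V_c$ 174%, $V_2$ 56.7%, $V_3$ 42% — with no BSV on
absorption parameters, whose final-model covariance was never published.
This is the one place where the packaged settings are knowingly a
simplification; its main visible consequence is that the Swedish
parameter set, with its lower clearance, can come out one MIC dilution
more favorable under fT>MIC than the value shared across countries,
which is why shared (minimum) cutoffs are reported when several
countries are compared.

## PK/PD indices and the cutoff

Both indices are computed on free concentrations ($f_u \cdot C$) over
the whole treatment window $[0, T]$ with $T$ = number of doses x
interval (72 h for q24h x 3; 96 h for the 2-dose q48h combination
regimen):

* $fAUC/MIC$ (h): exact integral of the free profile divided by the
  MIC. A value of 72 h over 72 h means the average free concentration
  equals the MIC.
* $fT>MIC$: the cumulative time the free concentration exceeds the MIC,
  *in toto* over the window (not per interval — a per-interval variant
  exists behind a flag for sensitivity analysis). Crossings between
  grid points are located by linear interpolation; the default 0.05 h
  grid keeps the crossing-time error below 0.01 h (checked against a
  0.001 h brute-force grid). The comparison is strict ($> MIC$), a
  measure-zero distinction from $\ge$.

For each scenario, 5,000 virtual horses are drawn once, each horse's
profile is simulated once, and all MICs on the grid
{0.0625, 0.125, 0.25, 0.375, 0.5, 1, 2} mg/L are evaluated on that
shared profile — faster and variance-reducing compared with re-drawing
per MIC. Quantiles use the linear-interpolation order-statistic
estimator (R type 7; Q10 of {1..100} is 10.9). PTA at a MIC is the
fraction of horses whose index is at least the PDT (ties count as
attainment; a convention documented here because practice varies). The PK/PD
cutoff is the highest grid MIC with PTA >= 0.90, equivalently with
Q10 >= PDT; if even the lowest MIC fails, the result is the sentinel
"below grid" (`NA`). PDTs: 72 h (or the window length) for fAUC/MIC;
30% or 40% of the window (21.6 / 28.8 h over 72 h) for fT>MIC; for
continuous infusion the relevant summary is the Q10 of time above the
MIC itself.

Monte Carlo error at n = 5,000 is far smaller than the 2-fold MIC grid
spacing: independent seeds give identical cutoffs (tested), so a single
run per scenario suffices.

## Non-compartmental analysis

Linear trapezoidal AUC and AUMC; for IV boluses a time-zero
concentration is back-extrapolated log-linearly through the first two
samples (without it, the missed area before the first sample biases CL
upward by several percent on rich designs). $\lambda_z$ is chosen by
maximizing adjusted $R^2$ over candidate terminal windows of at least 3
points after $T_{max}$ — the common automated rule, overridable with an
explicit point list; flat or rising tails are reported as "not
estimable" rather than erroring. $AUC_{inf} = AUC_{last} +
C_{last}/\lambda_z$ with observed $C_{last}$ by default (predicted
optional), flagged when the extrapolated fraction exceeds 20%. Observed
AUCs can be rescaled to a reference dose (linear kinetics) for
cross-formulation comparison, and cohort summaries report mean, SD, CV%,
min, median, max and the harmonic mean for half-lives. On noiseless
synthetic profiles at a 0.05 h grid the NCA clearance matches the
generating value within 2% (tested).

## Estimation

`bp_nlme` maximizes a first-order-conditional (Laplace-type)
approximate marginal likelihood: per subject the random effects are
optimized conditionally (a safeguarded Newton iteration for a single
random effect, BFGS otherwise, warm-started between outer iterations),
and the marginal contribution is the joint negative log-likelihood at
the mode plus $\tfrac12 \log\det(H/2\pi)$ with a numeric Hessian. The
approximation is exact for models linear in $\eta$ with constant
residual variance, and the test suite verifies it against the
closed-form marginal Gaussian likelihood of a random-intercept model.
No claim of numerical equality with commercial engines (QRPEM, FOCE ELS)
is made; the estimator's validation is parameter recovery on synthetic
data: across 20 seeded replicates of 40 rich IV profiles, the clearance
estimate has |bias| < 5% and RMSE < 15%, and including a generating
covariate shift on clearance is preferred by BIC with a margin above 10
("very strong") at a 23-profile study.

Parameterization: log for positive thetas, logit for bioavailability,
identity for covariate shifts; $\Omega$ by log-Cholesky (log diagonal,
free off-diagonal), guaranteeing positive semi-definiteness, diagonal or
full. Residual SDs on the log scale; the additive SD is frozen by
default (rich data well above the quantification limit barely inform
it). The outer optimizer is quasi-Newton with numeric gradients,
converging on relative objective change below 1e-8, with jittered
multi-start (default 3 starts) to guard against local minima. BIC uses
$-2\log L + k \ln n_{obs}$ with $n_{obs}$ the number of observations —
the observation-count convention is a documented choice where software
conventions differ. Empirical Bayes etas and shrinkage
($1 - SD(\hat\eta)/\omega$) are reported; shrinkage grows toward 1 as
per-subject information is thinned (tested).

Observations below the limit of quantification are dropped before
fitting (`bloq_filter`), the traditional rule that is safe while BLOQ
rows stay under about 5% of observations — the filter reports the
fraction and warns beyond that threshold. A censored-likelihood (M3)
treatment is out of scope. The naive pooled initializer minimizes
squared log-concentration residuals (equivalent to proportional
weighting for small errors), recovering noiseless identifiable
parameters exactly; the two-stage strategy of freezing IV-estimated
disposition parameters while fitting absorption is expressed through
the `fixed` list of `fit_spec`.

Visual predictive checks simulate replicate studies of the observed
design (default 500), bin observations by nominal time when there are
few distinct times and by quantile cuts into 8 bins otherwise (empty
bins merge with a warning), and overlay observed 10/50/90% quantiles
(20/50/80 optional) on simulated confidence bands.

## The synthetic-data generator

`design_library()` encodes the structure of the five contributing
datasets: a French 3x3 crossover (procaine 10 mg/kg q24h x 3; procaine +
benzathine 12.4 mg/kg x 2 q48h; penethamate 11.91/5.96/5.96 mg/kg)
followed by a single IV occasion at 12.36 mg/kg; a Swedish single-dose
IV arm (n = 4); a Swedish 2x2 IM crossover (n = 8; procaine ~11.8 mg/kg
q24h x 4, sodium ~14.07 mg/kg q12h x 7); a Japanese single IM dose of
5.617 mg/kg (n = 6); a USA1 arm (n = 7; two IV boluses 6 h apart, then
IM procaine, truncated 12 h post-IM to reproduce the extrapolation
caveat of that dataset's very long apparent MAT); and a USA2 single IV
arm (n = 6). Quantification limits are 5.5 (Sweden), 10 (France, USA1),
30 (Japan) and 40 (USA2) ng/mL. Together the designs contribute 63 rich
profiles and, at the default schedules, on the order of 900
observations — the size of the real study.

`generate_study()` draws each subject's random effects once (shared
across crossover occasions: inter-occasion variability is deliberately
absent, matching the model), simulates every occasion, adds residual
error and flags sub-LLOQ rows. A ground-truth sidecar (individual
parameters, etas, noiseless concentrations, seed) accompanies every
dataset for recovery experiments, and regeneration under the same seed
is bit-identical.

What the generator does **not** emulate: the real sampling schedules
(supplementary-only; the defaults use dense early sampling, pre-dose
troughs and a rich window after the last dose, chosen so NCA and
estimation are feasible and overridable per design), assay-specific
calibration error, demographic covariates, and the exact per-country
enrolment bookkeeping. Passing tests therefore demonstrate that the
pipeline recovers what it assumes — correctly specified structural and
error models — not that those assumptions hold in any real dataset.

## Parameters that matter

| parameter | units | default | why |
|---|---|---|---|
| `fu` | – | 0.4 | unbound fraction; fixed, no BSV |
| `n_sim` | horses | 5000 | MC noise ≪ MIC grid spacing |
| `dt` | h | 0.05 | crossing-time error < 0.01 h |
| `mic_grid` | mg/L | 0.0625–2, 2-fold + 0.375 | exploration grid |
| PDT (fAUC/MIC) | h | 72 per 72 h window | mean free conc = MIC |
| PDT (fT>MIC) | % window | 30 or 40 | time-dependent killing |
| `p` (parallel dual) | – | 0.5 | SPC split unpublished; override when known |
| penethamate $K_{a1}, K_{a2}, T_{lag}$ | 1/h, h | 0.5, 1/45, 0.5 | synthetic stand-ins (never published); chosen to land in the reported overall MAT range, and marked `synthetic` in the model file |
| `starts` (`bp_nlme`) | – | 3 | jittered multi-start |
| outer `reltol` | – | 1e-8 | convergence criterion |

## Problem sizes used by the tests

Monte Carlo acceptance runs use the full n = 5,000; estimator validation
uses 40 subjects x 20 replicates (clearance recovery), 23 profiles (BIC
covariate comparison), 12–14 subjects for the smaller property checks;
VPC calibration uses 12 subjects x 200 replicates. These sizes were
chosen as the smallest designs at which the statistical properties under
test are expected to hold with comfortable margins.

## Known limitations

* Linear kinetics only: no saturable elimination, no allometry or
  renal-function scaling, no tissue-site (e.g. epithelial lining fluid)
  concentrations.
* The penethamate absorption constants are synthetic stand-ins; cutoffs
  computed with them illustrate the machinery and are not field
  estimates.
* The USA1 procaine MAT (~230 h) is an extrapolation from 12 h of data;
  simulations with that scheme should be labelled accordingly.
* No BSV on absorption parameters in the packaged final model, and
  diagonal $\Omega$ for the cutoff simulations (full final-model
  covariance unpublished).
* BLOQ data are dropped, not modelled; bootstrap standard errors and
  automated covariate searches are out of scope.
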