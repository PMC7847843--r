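---
title: "Methods: hierarchical modelling and dose optimization of pediatric ganciclovir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical modelling and dose optimization of pediatric ganciclovir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements: the
hierarchical model and its estimation, the covariate machinery, the
validation diagnostics, the Monte Carlo dose optimization, and — because the
clinical data are not public — what the synthetic-data generator does and
does not emulate. Nothing here states an empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## The problem and the model

Critically ill children receiving intravenous ganciclovir (GCV) are sampled
opportunistically: 1–3 residual specimens per patient, irregular times, 138
concentrations across 104 children. Such data cannot support individual
curve fitting; they are exactly what nonlinear mixed-effects (population)
modelling is for. The structural model is a one-compartment disposition with
first-order elimination and zero-order infusion input. During an infusion at
rate $R_0$ started at $t_0$ with duration $T$,

$$C(t) = \frac{R_0}{CL}\left(1 - e^{-k_e (t - t_0)}\right),\qquad
  k_e = CL / V_d,$$

and after its end the accumulated amount decays exponentially; profiles for
repeated dosing are the sum of per-dose contributions (exact under
linearity). `concentration()` implements this closed form; an ODE
integration (deSolve) serves as the independent oracle in the tests, never
in the pipeline — the closed form is both exact and fast enough for
10,000-patient simulation.

Between-subject variability is lognormal on both parameters,
$P_i = P_{typ} e^{\eta_i}$ with diagonal $\Omega$; the residual error is
proportional, $Y = f \cdot (1 + \varepsilon)$. Additive and combined error
models are implemented behind the same interface (the study explored them
and settled on proportional).

The final covariate model is

$$V_d = \theta_{V_d} (WT/12)^{\theta_1}, \qquad
  CL = \theta_{CL}\, KF^{\theta_2} (WT/12)^{\theta_3},$$

where $KF$ is eGFR normalized by 120 mL/min/1.73 m² and 12 kg is the cohort
median weight. The defaults of `theta_final()` are the published estimates
(11.35 L, 5.23 L/h, 0.80, 0.92, 1.02); everything downstream
(`final_cl()`, `simulate_pta()`, the generator truth) derives from them.

## Estimation: FOCE with interaction

`fit_foce()` maximizes the Laplace-type approximation of the marginal
likelihood evaluated at each subject's conditional mode of
$\eta = (\eta_{CL}, \eta_{V_d})$, with the residual variance computed at the
conditional prediction (the "interaction" convention, the natural choice
with proportional error). Design choices that mattered:

* **Inner problem.** The per-subject penalized $-2\log$ joint density is
  minimized by a damped Newton iteration run for all subjects in parallel,
  with analytic gradients of the infusion model and the Gauss–Newton
  (linearized) curvature, which is positive definite by construction. The
  Laplace determinant uses the same Gauss–Newton curvature — this is the
  classical FOCE linearization rather than the full-Hessian Laplace; the two
  agree exactly for models linear in $\eta$, which the test suite exploits
  as an oracle.
* **Multimodality.** With 1–3 observations per subject the conditional
  objective can have two modes in the volume direction (a high-$V_d$/slow
  and low-$V_d$/fast explanation of the same point). The inner search
  therefore runs from the prior mode and from $\eta_{V_d} = \pm 1.2$,
  keeping the per-subject best; any subject short of the $10^{-6}$ gradient
  tolerance is polished by a scalar quasi-Newton solve on its own objective.
  Starting deterministically (never warm-starting from optimizer history)
  makes the outer objective a pure function of the parameters — without
  this, finite-difference outer gradients and standard errors are noise.
* **Outer problem.** Bounded quasi-Newton (`nlminb`) on log-transformed
  typical values, IIV standard deviations and residual SDs (covariate
  exponents stay on the natural scale), with an explicit forward-difference
  gradient (step $10^{-4}$, far above the inner-solve noise floor) and
  block scaling that reflects the typical curvature of each parameter class.
  Convergence tolerance is $10^{-6}$ relative OFV change, with up to three
  seeded random restarts. During the outer search the inner gradient
  tolerance is relaxed to $10^{-4}$ (OFV error $\ll 10^{-6}$), which roughly
  halves runtime; reported EBEs always use $10^{-6}$.
* **Degenerate hierarchy.** When all $\omega = 0$ the marginal is available
  exactly and is returned without approximation — one of the engine's
  oracle checks.
* **Uncertainty.** Standard errors come from the central finite-difference
  Hessian of the objective at the optimum (step $5\times10^{-3}$ on the
  transformed scale), reported as 100·SE/estimate to match the convention
  of the field's software. A non-positive-definite Hessian yields missing
  SEs with a warning, never fabricated values.
* **Criteria.** AIC $=$ OFV $+ 2k$ and BIC $=$ OFV $+ k\ln n_{obs}$ with $k$
  counting fixed effects plus variance parameters and $n_{obs}$ the number
  of quantifiable concentration records — the convention that reproduces
  the published candidate-model triples exactly.

CWRES follow the first-order-conditional convention: linearize $f$ around
$\hat\eta$, so $\mathrm{E}[y] \approx f(\hat\eta) - G\hat\eta$ and
$\mathrm{Cov}[y] \approx G \Omega G' + \mathrm{diag}(g^2)$, then decorrelate
with the Cholesky factor. Under a correct model they are approximately
standard normal; the tests check the $\pm 3$ band and near-zero mean on
simulated data.

## Covariates and selection

Continuous covariates enter as normalized powers, categorical ones as
exponential shifts — `pk_model_spec()` composes any number of them on CL and
Vd. The seven classical pediatric clearance parameterizations (fixed 3/4
allometry, estimated weight/BSA exponents, sigmoid age maturation, and
weight/age/BSA-dependent exponents) are implemented in `candidate_cl()`;
BSA-based candidates normalize by the cohort median 0.55 m², an inference
the printed generic form leaves open (flagged in the code), and the
BSA-dependent exponent is applied to the weight power exactly as the
candidate table prints it despite the apparent typesetting inconsistency.
Clearance is reported as absolute clearance: dosing is intravenous, so
bioavailability is identically 1.

`stepwise_search()` runs forward inclusion (ΔOFV ≤ −3.84, χ²₁ at 0.05) to a
full model and backward elimination (retention requires ΔOFV ≥ +6.63, χ²₁
at 0.01), one parameter per step, candidates warm-started from the parent
fit for stability. A correlation pre-screen (|r| > 0.5) keeps collinear
covariates (weight and height, say) from entering together. Ties break on
the larger OFV drop, then lexicographic covariate name, making the search
order-invariant. The candidate pool default is all demographic/renal
covariates on both parameters, subject to the screen.

## Validation diagnostics

* **Bootstrap** (`bootstrap_model()`): subjects resampled with replacement
  to the original cohort size, each replicate refitted, summaries are the
  median and 2.5/97.5 percentiles over converged replicates, and bias is
  100·(bootstrap median − estimate)/estimate. Runs with under 80%
  convergence are flagged. Resampling is unstratified — nothing in the
  design calls for strata.
* **VPC** (`vpc()`): replicate datasets simulated under the fit on the same
  design; observed 2.5/50/97.5 percentiles per bin compared with the 95%
  band of the same percentiles across simulations. The 2.5/50/97.5 set
  follows the figure-caption convention (the body text's "25th" is treated
  as a slip). Binning is equal-count on time after the most recent dose —
  opportunistic sampling makes fixed-width bins unstable — with bins under
  5 observations merged leftward. Because the dataset contains only
  quantifiable concentrations, the simulated percentiles are conditioned on
  the same support (simulated values below the 0.1 µg/mL limit are dropped
  replicate-wise); without that conditioning the lower band is
  systematically too low and the check miscalibrates.
* **NPDE** (`npde()`): per-subject decorrelation of observed and simulated
  vectors via the Cholesky factor of the simulated covariance, rank of the
  observation within its simulated distribution with a
  $(r + 0.5)/(K + 1)$ continuity correction, inverse-normal transform.
  Tests: Wilcoxon signed rank (location), a χ² variance test against 1,
  Shapiro–Wilk, and a Bonferroni global test (min p × 3, capped at 1) —
  the global test's definition is the package's choice since the source
  convention is unstated.

## Dose optimization

At steady state with linear kinetics the 24-h AUC is daily dose / CL —
independent of $V_d$, so only $\eta_{CL}$ variability enters the PTA
(changing $\omega_{V_d}$ provably leaves results unchanged, an invariant in
the tests). `simulate_pta()` draws weight (fixed or from the cohort
distribution), KF (fixed or uniform on a stratum interval — the
within-stratum law is unstated, uniform is the least-informative choice),
and $\eta_{CL}$, and reports mean AUC, range, and the fraction at or above
40 µg·h/mL. Parameter-estimate uncertainty is deliberately not propagated:
the simulation uses the point estimates, as the source procedure describes.
`optimal_dose()` scans a 0.5 mg/kg/d grid from 5 to 40 with common random
numbers (so PTA is monotone in dose and the minimal dose well defined), and
has a closed-form check: with lognormal CL the minimal dose is
$40\,CL_{typ}e^{z_{0.80}\omega_{CL}}/WT$, which the Monte Carlo must match
within one grid step. The elevated-renal-function stratum is capped at
KF = 1.08 (the cohort maximum eGFR / 120) rather than left unbounded.
"Steady state" is operationalized as 10 elimination half-lives or 7 days of
dosing, whichever comes first; a first-day trapezoidal AUC remains
available through `exposure_metrics()` since the integration day of the
source analysis is unstated.

## The synthetic cohort: what it does and does not emulate

`generate_cohort()` matches the published summary statistics, not the real
joint distribution: weight is truncated-lognormal (median 12 kg, range
2.5–55, mean/SD near 13.7/8.3); height follows a growth-curve link
$31.7\,WT^{0.42}$ with 5% noise (so the weight–height correlation exceeds
the 0.5 screen threshold and the pre-screen has a true positive to find);
age is truncated-lognormal and sampled independently of weight — a
deliberate simplification; eGFR is a four-component mixture reproducing the
12/80/11/1 renal-class frequencies in expectation; sex is 54:50. Matching
the printed mean/SD/median/range is the fidelity criterion — the
distribution families themselves are modelling choices.

Sampling times are uniform over 0.5–12 h after a randomly chosen dose
within 3–7 days of therapy. With a typical half-life near 1.5 h, a tail of
such draws falls below the 0.1 µg/mL quantification limit, which the
emulated study never recorded (its observed minimum was above the limit);
times whose simulated concentration is below the limit are therefore
redrawn (bounded retries), mimicking the fact that only quantifiable
residual specimens enter such datasets. This truncation slightly favours
high concentrations; the parameter-recovery tests bound its practical
effect (median bias of the typical values stays under 10% across
replicates). It also makes the sampling times mildly informative about the
subject's own random effects — a feature of real opportunistic sampling
that a fixed-design VPC cannot reproduce exactly, which is why the VPC
calibration test distinguishes data simulated at fixed design times
(strict 95% calibration) from the generator's own output (qualitative
coverage). Observation counts allocate 1–3 samples per subject to hit the
138-observation target exactly.

What passing tests on this cohort do **not** show: robustness to real-world
covariate measurement error, within-subject covariate drift (covariates are
constant per subject by design), model misspecification of the structural
kinetics, or non-random sampling tied to clinical state. The generator is a
ground-truth harness, not a clinical data twin.

## Numerical choices and limitations

Tolerances: inner gradient $10^{-6}$ (EBEs), outer OFV $10^{-6}$ relative,
SE Hessian step $5\times10^{-3}$; BLQ observations are flagged and excluded
from the likelihood (the emulated dataset contains none by construction);
residual variances are floored at $10^{-12}$ to keep zero predictions
finite; concentrations at $t = 0$ are exactly 0. Problem sizes in the test
suite (cohorts of 10–200 subjects, 8–20 bootstrap replicates, simulation
sizes of 200–1000) are chosen so the full suite exercises every pathway at
study-like scale while remaining a routine run; the acceptance script uses
the full 104-subject reference dataset and 10,000-patient Monte Carlo.

Known limitations: no two-compartment structural alternative is implemented
(the model interface does not preclude one — the engine sees only a
prediction function — but the closed form shipped is one-compartment); no
SAEM or importance-sampling estimators; diagonal $\Omega$ only; no
prediction-corrected VPC; no covariate effects on residual error; eGFR is
an input column (the pediatric formula behind it is not re-derived — a
pluggable calculator interface with an identity default exists instead).
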