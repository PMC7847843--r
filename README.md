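# gcvppk — population pharmacokinetics and dose optimization of intravenous ganciclovir in critically ill children

Ganciclovir (GCV) is the first-line antiviral for cytomegalovirus disease,
cleared almost entirely by the kidney. In critically ill children it is dosed
at 5 mg/kg twice daily as 1-h infusions, yet exposure is highly variable and
routine (rich) pharmacokinetic sampling is not feasible — concentrations come
from 1–3 opportunistic residual specimens per patient. This package
implements the full analysis pipeline such sparse data call for: a
hierarchical (population) one-compartment model estimated by FOCE-I,
allometric/maturation covariate modelling, stepwise covariate selection,
bootstrap/VPC/NPDE validation, and Monte Carlo dose optimization against the
established efficacy target AUC₀₋₂₄ ≥ 40 µg·h/mL. Because the underlying
clinical dataset is not public, the package ships a synthetic-cohort
generator that emulates the study design (104 children, 138 concentrations,
weight 2.5–55 kg, mostly normal renal function) and serves as ground truth
for every stage.

## The model

Structural model: one-compartment kinetics with first-order elimination and
zero-order (infusion) input; concentrations follow the closed-form
superposition of per-dose contributions. Between-subject variability is
lognormal and the residual error proportional:

    P_i      = P_typ · exp(η_i),            η_i ~ N(0, ω²)
    Y_ij     = f(t_ij; CL_i, V_i) · (1 + ε_ij),   ε_ij ~ N(0, σ²)

Final covariate model (reference weight 12 kg, KF = eGFR / 120):

    Vd (L)     = θ_Vd · (WT / 12)^θ1
    CL (L·h⁻¹) = θ_CL · KF^θ2 · (WT / 12)^θ3

with reported estimates θ_Vd = 11.35 L, θ_CL = 5.23 L/h, θ1 = 0.80,
θ2 = 0.92, θ3 = 1.02, ω_Vd = 65.78%, ω_CL = 12.90%, σ = 8.23%. Estimation is
first-order conditional with interaction: each subject's conditional
random-effect mode is found by a damped (Levenberg) Newton search with
analytic gradients, and the marginal −2 log-likelihood is the Laplace
objective with the Gauss–Newton (FOCE) curvature. At steady state the daily
AUC reduces to daily dose / CL, so the probability of target attainment (PTA)
for a dosing stratum follows from simulating CL alone.

## Worked example

```r
library(gcvppk)

ref <- reference_dataset()          # packaged synthetic study, fixed seed
ref$dataset
#> pk_dataset: 104 subjects, 1028 doses, 138 observations (0 BLQ)
#>   WT 3.3-42.8 kg (median 12.0), eGFR 20.4-126.7

fit <- fit_foce(ref$dataset, final_model_spec(), seed = 1)
fit
#> FOCE-I fit: OFV 101.85  AIC 117.85  BIC 141.27  (8 parameters, 138 obs)
#>            estimate se_pct
#> tv_cl       5.57900   1.56
#> tv_vd      12.69000   4.66
#> beta_cl_wt  1.05700   2.49
#> beta_cl_kf  0.89050   4.27
#> beta_vd_wt  0.88560  10.20
#> omega_cl    0.11760  13.00
#> omega_vd    0.59390   6.26
#> sigma_prop  0.05219  20.20
```

The typical clearance (5.58 L/h) and volume (12.69 L) recover the generating
values 5.23 L/h and 11.35 L from 138 sparse observations to within 7% and
12% — the sampling error a design this sparse implies. Dose optimization for
a 2.5-kg infant with normal kidney function:

```r
optimal_dose(kf = 1.0, wt = 2.5, seed = 1)
#> [1] 19
simulate_pta(10, kf = c(0.75, 1.0), wt = "cohort", seed = 1)
#> dose 10.0 mg/kg/d: mean AUC0-24 26.33 (range 15.23-47.47), PTA 0.16%
```

i.e. the conventional 10 mg/kg/d leaves virtually every patient with normal
renal function below the efficacy target, while ~19 mg/kg/d is needed to put
80% of 2.5-kg patients on target — the central clinical finding this
pipeline reproduces.

The numbered scripts under `analysis/` run the stages in order (synthetic
cohort → final-model fit → candidate clearance models → covariate selection
→ bootstrap/VPC/NPDE validation → dose optimization) and write their tables
under `results/`.

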