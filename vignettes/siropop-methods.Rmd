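---
title: "Methods: population PK of sirolimus in pediatric TSC and initial-dose optimization"
author: "siropop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population PK of sirolimus in pediatric TSC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(siropop)
```

## The problem

Children with tuberous sclerosis complex (TSC) receive sirolimus for
seizure control, targeting trough concentrations of 5–10 ng/ml. The
drug is monitored only through sparse pre-dose samples collected during
routine care, so the available data are a handful of steady-state
troughs per child, with weight spanning an order of magnitude across
the population and frequent antiepileptic comedication. Two questions
follow: (i) what population model describes these troughs, and
(ii) which initial mg/kg dose maximizes the probability that a new
patient's trough lands in the window before any level is available.

## Structural and covariate model

Disposition is one-compartment with first-order absorption and
elimination; with trough-only data nothing richer is identifiable, and
the absorption rate constant cannot be estimated at all, so Ka is fixed
at 0.485 h⁻¹ (a published value for this population). All parameters
are apparent (CL/F, V/F): bioavailability is never separated. Weight
enters through fixed-exponent allometry — clearance scales with
(WT/70)^0.75 and volume linearly — and oxcarbazepine comedication
multiplies clearance by θ_OXC, reflecting CYP3A4 induction:

$$\mathrm{CL/F} = \theta_{CL}\,(WT/70)^{0.75}\,\theta_{OXC}^{OXC},
\qquad \mathrm{V/F} = \theta_V\,(WT/70).$$

Defaults are the final published estimates (θ_CL = 8.59 L/h,
θ_V = 294 L, θ_OXC = 1.16). A consequence of the 0.75 exponent,
visible throughout the dose tables, is that clearance per kilogram
falls with weight, so small children need higher mg/kg doses.

Observations are predicted by the closed-form steady-state trough of
the one-compartment oral model (`trough_steady_state()`), with the
single mg/L→ng/ml conversion (×1000) applied in that one place. The
absorption–elimination degeneracy Ka = Ke is handled by the analytic
limit once |Ka−Ke|/Ka < 1e−9; it is never reached by realistic
parameters but keeps the function continuous. `concentration_profile()`
provides the finite-dose superposition curve; it converges to the
steady-state trough within about five doses at these half-lives, which
is why dose recommendations are evaluated directly at steady state.

## Random effects and residual error

Inter-individual variability is lognormal,
$CL_i = TV(CL)\exp(\eta_i)$ with $\eta\sim N(0,\omega^2)$. The base
model allows an η on volume too, but with trough-only data its variance
estimates near zero and the fitting routine drops it below 1e−4
(`drop_small_eta`), leaving the single clearance random effect of the
final model. Residual error is additive, proportional or combined; the
final model is additive.

**Scale convention.** Reported variability values such as ω_CL = 0.175
and σ₁ = 1.913 do not announce whether they are variances or standard
deviations. The package treats them as variances (the NONMEM
OMEGA/SIGMA reporting convention) by default and carries an explicit
`scale` switch on both containers. The variance reading is also the one
under which the Monte Carlo dose optimization reproduces the published
recommendation table; the acceptance test prints the recommendation
under both readings side by side.

**Negative simulated concentrations** are possible under additive
error. They are kept internally (truncation would bias estimation
checks), floored only when a dataset is written (a recorded assay value
cannot be negative), and count as outside the target window in PTA — a
negative draw cannot be in-window regardless of policy.

## Estimation

The marginal likelihood integrates each subject's contribution over η.
`ofv()` evaluates −2 log L with adaptive Gauss–Hermite quadrature:
Newton iterations (analytic gradient, tolerance 1e−8) locate the
conditional mode of the joint density, a Gauss–Newton (FOCE-style)
Hessian — positive definite by construction, residual variance at the
conditional prediction, i.e. *with interaction* — sets the quadrature
scale, and 9 nodes integrate the subject's likelihood. One node is the
classical Laplace approximation; 9 nodes agree with brute-force
adaptive quadrature to ~1e−6 relative on test datasets while costing
only eight extra vectorized evaluations. With two random effects the
plain Laplace form with the Gauss–Newton Hessian is used. With all
variances at zero the OFV collapses to the fixed-effects weighted
least-squares deviance.

The outer problem is solved by `nlminb` on log-transformed positive
parameters (continuous-covariate exponents stay untransformed since
they may be negative). Standard errors come from the observed
information (half the numerical Hessian of the OFV) at the optimum;
empirical-Bayes η estimates are returned per subject. Covariate
screening (`covariate_screen()`) is classical stepwise ΔOFV: forward
inclusion at 3.84 (χ², p<0.05), largest drop first with ties broken by
candidate order, then backward elimination keeping only covariates
whose removal raises the OFV by more than 6.63 (p<0.01). Categorical
covariates enter as θ^x, continuous ones as (x/median)^θ. Observations
below the assay's 3.5 ng/ml linear limit are kept by default
(`exclude_blq = TRUE` drops them).

**Identifiability of V/F.** Steady-state troughs at a single dosing
interval carry very little information about volume: the profile
likelihood in θ_V is nearly flat (a few OFV units across 100–3000 L at
800 observations), because as V grows the trough tends to the
volume-free limit D/(CL·τ) and clearance re-scales along a ridge. The
estimator therefore recovers clearance and the comedication effect
well, while single-dataset V/F estimates can wander several-fold — consistent with bootstrap intervals for V/F in this
population that span an order of magnitude. This is a property of the design (trough-only,
one interval), not of the optimizer; users who need a stable V/F
should fix it or add non-trough samples. For the same reason the power
to *replicate* the selection of a modest (1.16-fold) comedication
effect at the study's prevalence is modest — in replicate
simulations only a third to a half of datasets clear both thresholds —
so a covariate selection of this size is a single-dataset significance
call, not a reproducible event.

## Synthetic cohorts

`generate_cohort()` emulates the study population so every stage is
testable without patient data: 80 subjects; weights log-normal,
moment-matched to mean 23.5 / SD 11.7 kg (positivity and the right
skew of pediatric weights) and truncated to the observed 8–68 kg;
oxcarbazepine prevalence 23/80 and the other six antiepileptics at
their observed prevalences; 1 + Poisson draws averaging 2.35 troughs
per subject; once-daily dosing. Since administered doses are not
reported, each subject's dose is drawn so the typical steady-state
trough is uniform on 4–25 ng/ml — titration toward the window within
the assay's 3.5–30 ng/ml linear range — and rounded to 0.01 mg.
Demographics and laboratory covariates (age, sex, dosage form, liver
and kidney panels, hematology) are generated from the published summary
statistics but are *inert*: they do not enter the truth model, so
covariate screening has true negatives to reject. Observed troughs are
model troughs under sampled individual clearances plus residual error,
floored at 0.1 ng/ml, flagged BLQ below 3.5 ng/ml. Generation is
bit-reproducible from a seed; what the generator does **not** emulate
is real-world non-adherence, dose changes between visits,
non-steady-state sampling, or assay failure modes, so green tests here
certify the machinery, not clinical transferability.

## Validation machinery

The nonparametric bootstrap resamples *subjects* (the longitudinal
unit) with replacement, refits from the original estimates, and reports
medians, 2.5–97.5 percentiles and bias = (median−estimate)/estimate
× 100 over converged replicates; a run with >50 % non-convergence is
flagged failed. Goodness-of-fit tables carry PRED, IPRED,
|iWRES| and a first-order conditional weighted residual built from the
per-subject linearized covariance, approximately standard normal under
a correct model. The visual predictive check is prediction-corrected
(values scaled by bin-median PRED over individual PRED) and binned by
weight quartile, since trough sampling times are uninformative; sparse
bins are merged. Coverage is the fraction of prediction-corrected
observations inside the pooled simulated 2.5–97.5 % band.

## Dose optimization

`simulate_pta()` draws virtual patients per weight, computes their
steady-state troughs on each candidate dose (0.01–0.10 mg/kg/day;
twice-daily regimens split the daily amount evenly with τ = 12 h), and
reports the fraction inside 5–10 ng/ml, endpoints inclusive. Two
design choices matter:

* **The same virtual population is re-dosed at every candidate dose.**
  Dose comparisons then share their Monte Carlo noise, which is what
  stabilizes the argmax where adjacent doses are nearly tied — at 5 kg
  with oxcarbazepine, once daily, the attainment gap between 0.08 and
  0.09 mg/kg/day is ~4×10⁻⁴, so resolving the ordering needs on the
  order of 10⁷ draws even with common random numbers.
* **The attainment endpoint is the error-free model trough.** The
  window describes the patient's true exposure; assay noise is not part
  of the target. Including additive residual error (available via
  `include_residual = TRUE`) flattens the PTA curves and shifts two
  argmax doses at 5 kg down one grid step, away from the published
  recommendations — evidence the published table was likewise built on
  error-free troughs.

`derive_weight_bands()` refines the eight-point weight grid to 0.5 kg
steps, takes the PTA-argmax dose per weight (ties to the lower dose),
enforces the physiologically required non-increasing dose-per-kg by
isotonic smoothing (any adjustment is logged), and collapses runs into
contiguous bands. Exact strict-argmax boundaries do not coincide
everywhere with the published band edges, whose interpolation rule
between the eight simulated weights was never stated; near-boundary
weights sit on near-ties and can legitimately flip one step. The anchor
cells at 5 and 70 kg are unambiguous.

## Numerical choices and problem sizes

Inner Newton tolerance 1e−8 on η; outer `nlminb` defaults with up to
400 iterations; quadrature 9 nodes (1-D η); Gauss–Hermite nodes by
Golub–Welsch eigen-decomposition; finite-difference step 1e−5 on η for
prediction gradients; ω²/σ² floored at 1e−10 inside the likelihood to
keep the η_V→0 limit continuous. Simulation studies in the test suite
use 20 replicate cohorts of 200 subjects × 4 troughs for parameter
recovery, a 200-replicate bootstrap on an 80-subject cohort, 1000-
replicate VPC at the study's 188-observation size, and 5×10³–10⁷
virtual patients per PTA cell depending on how close the compared doses
are; these sizes keep every Monte Carlo margin several standard errors
wide of its decision threshold.

## Known limitations

* V/F is reported but weakly identified from trough-only data (above);
  its bootstrap intervals are honest about this.
* No inter-occasion variability, no η correlation blocks, no
  Michaelis–Menten elimination, no absorption lag, no covariate effects
  on Ka, and no Bayesian individual dose adaptation after an observed
  level — all outside the scope of an *initial*-dose analysis on
  trough-only data.
* The dose tables inherit every assumption above; they are simulation
  outputs, not clinical guidance.
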