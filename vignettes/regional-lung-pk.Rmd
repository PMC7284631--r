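---
title: "Semi-mechanistic modelling of regional lung pharmacokinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-mechanistic modelling of regional lung pharmacokinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungpk)
```

## The problem

Inhaled drugs for asthma and COPD act in the conducting airways, yet lung
exposure is usually summarized by a single whole-lung concentration. The
lung is heterogeneous: the alveolar parenchyma receives the entire cardiac
output through the pulmonary circulation, while trachea and bronchi are
perfused by the much smaller systemic (bronchial) circulation. Regional
tissue affinity and regional blood flow together set how fast each lung
region equilibrates with plasma and how long a drug is retained there.
`lungpk` implements a semi-mechanistic model of this process for
intravenous infusion studies in rats, together with the estimation,
derived-quantity and study-design machinery around it.

## Model structure

Systemic disposition is an empirical one- or two-compartment model with
bodyweight-normalized clearance CL, central volume $V_C$ and (for
two-compartment drugs) intercompartmental clearance Q and peripheral
volume $V_P$. Each lung region (trachea, bronchi, alveolar parenchyma) is
a *virtual* compartment: it is driven by the plasma concentration but
returns no mass, which is valid because the lung tissue weights
(0.0002 / 0.0008 / 0.004 kg per kg bodyweight) are a negligible fraction
of the systemic distribution volume. Only unbound drug permeates, so the
regional blood flow $Q_{pul}$ is scaled by the plasma fraction unbound
$f_u$:

$$\frac{dC_{tis}}{dt} = \frac{Q_{pul} f_u}{V_{pul}} C_p(t)
  - \frac{Q_{pul} f_u}{V_{pul} K_p} C_{tis},$$

where $K_p$ is the tissue-to-plasma partition coefficient. At
distribution equilibrium $C_{tis}/C_p = K_p$. The efflux rate constant

$$k_{a,pul} = \frac{Q_{pul} f_u}{V_{pul} K_p}, \qquad
  t_{1/2,pul} = \ln(2)/k_{a,pul}$$

is the unidirectional absorption (tissue-to-plasma) rate; its half-life
measures local retention, not a full terminal half-life, because
redistribution from plasma back into tissue is deliberately excluded.

The source never states its differential equations; the form above—influx
driven by *total* plasma concentration scaled by $f_u$—is the one
consistent with the published absorption rate constant and with every
published concentration ratio, and is what we implement.

### Numerical backends

The system is linear and time-invariant, so the primary backend is closed
form: the plasma bolus response is a sum of one or two exponentials, the
infusion-on response its convolution with a step, and the tissue response
the convolution of that with the first-order tissue filter. The end of
infusion is handled by superposition, $x(t) - x(t - T_{inf})$, which is
exact. This matters because the fast salmeterol distribution phase
($\lambda_1 \approx 58\,h^{-1}$) makes naive integration stiff. A stiff
ODE integrator (`deSolve::lsoda`, tolerances $10^{-11}/10^{-13}$, the
integration split at the infusion stop) is retained as an independent
check; the two backends agree to better than $10^{-6}$ relative
everywhere we test, and the near-degenerate filter case
$k_{a} \approx \lambda_i$ falls back to the analytic limit
$t e^{-kt}$.

## Packaged parameters

The four model drugs span one basic (salmeterol), two neutral
(fluticasone propionate, linezolid) and one acidic (indomethacin) drug.
Their systemic parameters and regional $K_p$ values, the regional blood
flows ($Q_T = 0.054$, $Q_B = 0.777$, $Q_A = 10.6$ L/h/kg) and the
whole-lung comparator values ship as a configuration file.

The plasma fractions unbound are not published directly; they are
reconstructed at load time from published derived quantities
(`derive_fu_plasma()`):

* **salmeterol** from the free EC50 anchor:
  $f_u = 0.0271 \cdot K_{p,B} / 36 = 0.0140$;
* **fluticasone** and **indomethacin** by inverting the half-life
  relation against their tracheal values (52.4 min and 14 s), giving
  0.0153 and 0.235.

These reconstructions are mutually consistent: anchoring on any one
tissue reproduces the other two published half-lives within the 5%
that 3-significant-figure parameter rounding allows (a property test
enforces this). **Linezolid** is the exception: no $f_u \le 1$ reproduces
its published half-lives (the inversion yields $\approx 7$, which is not
a fraction). We do not guess; linezolid defaults to $f_u = 1$ with a
warning, every operation remains functional with a user-supplied value,
and linezolid is excluded from half-life comparisons against published
numbers.

```{r fixtures}
fx <- default_fixtures(quiet = TRUE)
fx$drugs$salmeterol
```

## Two-stage estimation

Estimation mirrors the study's two-stage approach. Stage 1 fits CL,
$V_C$ (and Q, $V_P$) to plasma data alone. Stage 2 fixes those and fits
the regional $K_p$ per drug *plus the three blood flows shared across
all drugs simultaneously* — blood flow is a property of the animal, not
of the drug, and the joint fit is what makes the small tracheal flow
identifiable.

Choices the source leaves open, and how we resolved them:

* **Objective.** Residuals on log concentrations (equivalent to
  proportional error). The data span more than two orders of magnitude
  and parameter uncertainty is reported as %CV, both of which point to
  multiplicative error; the original software's settings are unknown.
* **Positivity.** Parameters are fitted on the log scale, avoiding
  constrained optimization. CV% is $100 \cdot SE(\log\theta)$, the delta
  method on the log scale, with the covariance from the scaled inverse
  Hessian of the sum-of-squares objective.
* **Starts and restarts.** Stage-2 $K_p$ starts are the observed
  tissue-to-plasma ratio at the latest sampling time (computed
  order-invariantly); flow starts come from physiology (alveolar flow
  from cardiac output, airway flows from a small share of it split by
  tissue weight). Multi-start (log-uniform perturbations, fixed private
  seed) guards against local optima; the best objective wins. On
  noise-free data literature starts and random restarts reach the same
  optimum, and every free parameter is recovered to well under 1%.
* **Convergence classification.** A tolerance-limited optimizer stop
  ("singular convergence") at a point a restart cannot improve is
  counted as converged; true failures surface in the SSE convergence
  rate.
* **Identifiability guard.** A tissue observed at fewer than two
  distinct times makes $K_p$ and its blood flow trade off freely; the
  fit refuses with a structural non-identifiability error rather than
  returning an arbitrary point.

No mixed-effects structure is used: the analysis pools animals into
single point estimates per parameter, as the original two-stage analysis
does.

## Derived quantities and human scaling

`half_life_table()` evaluates $t_{1/2,pul}$ for every drug and region,
including the whole-lung comparator. Human scaling uses fixed allometric
exponents — 0.75 for flows, 1 for volumes, $K_p$ conserved — so on the
per-kg scale flows change by $(70/0.28)^{-0.25}$ and every human/rat
half-life ratio is exactly $(70/0.28)^{0.25} \approx 3.98$. Values are
kept in hours internally; `format_half_life()` picks h/min/s only at the
presentation layer.

`percent_of_steady_state()` expresses observed tissue-to-plasma ratios
as a percentage of $K_p$, aggregating replicate-level ratios to
mean ± SD per time point. One subtlety: after the infusion stops, plasma
falls faster than slow tissues, so the *instantaneous* ratio overshoots
$K_p$ (for salmeterol bronchi the model reaches ~240% of $K_p$ at 4 h —
which is just the published late-time EC50 fold-bias of 0.418 read in
reverse). The monotone approach to 100% from below holds *during* a
constant infusion; we therefore demonstrate the slow-vs-fast
equilibration contrast (salmeterol trachea still < 100% at 4 h,
linezolid/indomethacin ≥ 95% within the first samples) under a sustained
infusion covering the observation window.

## PK/PD: time-dependent EC50 bias

The effect is modelled as hyperbolic Emax on the *unbound bronchial*
concentration, with the true free EC50 anchored by scaling a published
total-lung EC50 (36 nM for salmeterol) with $f_u/K_{p,B}$ to 0.0271 nM.
`estimate_plasma_ec50()` reproduces what a plasma-based PD experiment
does: simulate a dose-escalation (default 30 doses log-spaced over six
decades centred on the half-maximal dose), read effect and unbound
plasma concentration at one time point, and fit the Emax model in plasma
space (same log-scale least squares as the estimation module, Emax
fixed). Under linear PK the resulting estimate over the true free EC50
equals the unbound plasma/bronchi concentration ratio
$K_{p,B} C_p(t)/C_B(t)$ exactly — `fold_bias_analytic()` — which makes
the result provably insensitive to the unpublished dose grid and fitting
details; the tests require the two routes to agree within 1% and the
dose grid to be irrelevant.

```{r bias}
d <- study_design()
ec50_bias_table(fx$drugs$salmeterol, fx$physiology, d)[, 1:3]
```

The bias crosses 1 shortly after the infusion stops (~1.02 h) and spans
roughly 16-fold between 0.25 h and 4 h: a plasma-read potency for a
slowly equilibrating drug depends strongly on *when* you measure.

## Synthetic data and design evaluation

`generate_study_data()` emulates the in vivo design: a 1-h zero-order
infusion in a 0.28 kg rat, 65 plasma samples (60 within the infusion
hour plus 1.25/1.5/2/3/4 h, matching "about 67, mostly in the first
hour"), and 3 replicate tissue samples at 0.25/0.75/2/4 h — 12 samples
per tissue and drug. The infused amount is arbitrary (only a volumetric
rate is published) and harmless: every headline output is a
dose-invariant ratio or parameter-derived, and a property test pins the
linearity down.

Residual error is multiplicative lognormal with
$sd_{log} = \sqrt{\log(1+CV^2)}$, defaults 15% (plasma) and 25%
(tissue). The published analysis does not state its error model; these
are our assumptions, chosen once as typical bioanalytical magnitudes
with tissue homogenates noisier than plasma. No between-animal
variability is simulated — the two-stage analysis pools animals, so
residual noise is the only stochastic term.

`run_sse()` repeats simulate-then-refit (systemic fixed at truth,
replicate $r$ seeded `seed + r`) and reports per-parameter relative bias,
empirical CV and convergence rate; `compare_designs()` ranks designs by
their worst-parameter CV, a maximin criterion that punishes a design for
the one parameter it cannot pin down. At the study design with the
default error model and 50 replicates, the median absolute $K_p$ bias is
well under 10% and convergence is complete; a late-only three-point
design (1/2/3 h) roughly doubles the empirical CV of the tracheal blood
flow, which is exactly why the in-vivo study put two tissue samples
inside the infusion hour.

Problem sizes used in the shipped tests and analysis scripts — 50 SSE
replicates for the acceptance properties, 20–25 for the narrative
scripts and consistency checks — were chosen as the smallest runs whose
Monte-Carlo noise is comfortably below the effects being demonstrated.

## What the synthetic study does and does not show

The generator reproduces the design, the error magnitude and the true
parameters; it does not reproduce between-animal variability, residual
blood in tissue samples, assay censoring at the LLOQ, or any
permeability-limited or transporter-mediated kinetics. Passing the
simulation-based tests therefore shows the estimation machinery is
correct and the design adequate *under the model's own assumptions*; it
cannot certify the model for drugs that violate them — notably acidic
drugs like indomethacin, whose real tissue data the perfusion-limited
model is known not to capture (its fixtures here describe the model fit,
and the synthetic checks exercise the machinery, not that drug's real
kinetics).

## Limitations

* Absorption half-lives exclude redistribution from plasma; they are
  retention measures, not effective pulmonary half-lives.
* No oral-inhalation processes (deposition, mucociliary clearance,
  dissolution) and no nonlinear tissue binding.
* $K_p$ prediction from physicochemical properties is out of scope; all
  affinities are estimated or supplied.
* The linezolid fraction unbound cannot be reconciled with its published
  half-lives (see above) and is left at 1 with a warning.
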