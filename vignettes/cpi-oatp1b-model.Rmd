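---
title: "Coproporphyrin I as an OATP1B biomarker: model, estimation and study design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coproporphyrin I as an OATP1B biomarker: model, estimation and study design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`copropk` models coproporphyrin I (CPI) — an endogenous substrate of the
hepatic uptake transporters OATP1B1/1B3 — together with the prototypical
OATP inhibitor rifampicin (RIF) and the clinical probe rosuvastatin
(RSV), and uses the fitted system to design transporter DDI studies.
This vignette is the package's own account of the science: the models and
their assumptions, the tunable parameters, the numerical machinery, and
what the synthetic data can and cannot tell you.

## Structural models

**Rifampicin (perpetrator).** A single 600-mg oral dose enters through a
transit-compartment absorption delay and is cleared from a
one-compartment central space. With a continuous number of transit
compartments $n$ and mean transit time $MTT$ (so $k_{tr} = (n+1)/MTT$),
the absorption input is the gamma-density rate

$$\mathrm{in}(t) = F\,D\;k_{tr}\,\frac{(k_{tr} t)^{n} e^{-k_{tr} t}}{\Gamma(n+1)},$$

evaluated in log space because $(k_{tr}t)^{8.63}$ overflows naively. It
integrates to the absorbed dose and peaks at $n\,MTT/(n+1)$. Clearance
and volume are apparent oral parameters, so bioavailability is fixed at
$F=1$; the dose is converted to µmol with a molar mass of 822.94 g/mol so
plasma concentrations are µM (RSV likewise with 481.54 g/mol).

**CPI (biomarker).** A turnover model: zero-order synthesis $k_{syn}$
(nM/h) into a volume $V$, first-order loss through biliary ($CL_b$) and
renal ($CL_R$) clearances, with RIF competitively inhibiting only the
biliary (OATP1B-mediated) route:

$$\frac{dC}{dt} = \frac{1}{V}\left[k_{syn}
  - \frac{CL_b\,C}{1 + C_{RIF}(t)/K_i} - CL_R\,C\right],
  \qquad \frac{dU}{dt} = CL_R\,C .$$

$K_i$ is on the total-plasma-concentration scale; multiplying by the RIF
unbound fraction (0.11) gives the unbound constant (0.13 µM). The
baseline is the steady state $C_{ss} = k_{syn}/(CL_b + CL_R)$, which is
also the initial condition of every simulation — CPI is endogenous and
its observed pre-dose baseline is flat, so nothing else is defensible.
Urinary collections are interval amounts, i.e. differences of the
cumulative $U$.

**Rosuvastatin (probe).** Two-compartment disposition with first-order
absorption; elimination from the central compartment splits into a
biliary component (inhibited by RIF exactly as for CPI, with its own
$K_i$) and a renal component observed in urine.

**RIF-condition covariate.** On occasions where RIF is co-administered
the CPI volume drops (6.59 → 3.4 L) and the RSV distribution parameters
change ($V_1$, $V_2$, $Q$), implemented as a binary occasion-level
covariate applied after the random effects.

## Population layer

Individual parameters follow the exponential model
$\theta_{ik} = \theta\,e^{\eta_i + \kappa_{ik}}$ with interindividual
effects $\eta_i$ (drawn once per subject) and interoccasion effects
$\kappa_{ik}$ (independent per subject-occasion). Variabilities are
specified as %CV and converted by $\omega^2 = \log(1 + (CV/100)^2)$, the
exact relation for log-normal parameters; the covariance matrices are
diagonal (no correlation estimates are reported for this system).
Observations carry combined proportional + additive residual error,
$y = f(1+\varepsilon_p) + \varepsilon_a$, per stream (RIF plasma, CPI
plasma, CPI urine, RSV plasma, RSV urine). Simulated observations may go
negative through the additive term; they are retained (no truncation),
with an optional LLOQ-censoring switch that is off by default. The full
parameterisation ships as a YAML file
(`inst/extdata/poppk_parameters.yaml`) with explicit units, and
`load_parameters()` rebuilds the three population models from it.

## The synthetic trial

`default_design()` encodes the three-occasion crossover: 12 healthy
subjects, 7-day washouts; OCC1 600 mg RIF, OCC2 5 mg RSV, OCC3 both.
Only the per-occasion sample *counts* are published, so the clock times
are a design choice: drugs are sampled post-dose at
{0.25, 0.5, 1, 1.5, 2, 3, 4, 6, 8, 12, 16, 24} h (the 16-h sample is
dropped where an occasion carries 11 samples), and CPI at
{0, 0.5, …, 24} h so that every occasion has a pre-dose baseline row —
needed for the baseline-variability analysis — while the totals match
the published 276/420/264 plasma records. Urine is collected over
(−7, 0), (0, 7) and (7, 24) h for CPI and post-dose for RSV. The
published urine totals (34 pre- and 68 post-treatment CPI samples) imply
a few missing collections that cannot be reconstructed; the generator
produces complete data, with a missingness probability switch (default
0) for sensitivity work.

The generator emulates: the crossover structure with shared $\eta$ and
occasion-specific $\kappa$; each subject's own RIF exposure driving that
subject's CPI and RSV within the occasion; and stream-specific residual
noise. It does not emulate: dropout, LLOQ censoring patterns,
circadian baseline drift, genotype covariates (the clinical subjects
were all wildtype *SLCO1B1*), or model misspecification — so passing
recovery tests demonstrates internal consistency of the estimator, not
correctness of the model for real patients.

## Estimation

`fit_nlme()` maximises a Laplace approximation to the marginal
likelihood. Per subject, the joint negative log-density of data and
random effects is minimised over $u = (\eta, \kappa)$ by a damped
Gauss–Newton iteration in compiled code; the gradient is the full joint
gradient — including the term from the dependence of the residual
variance on the prediction, which matters at the 34% proportional urine
CV and whose omission produced a measurable upward bias in $CL_b$ and
$K_i$ during development — while the Gauss–Newton matrix
$J^TWJ + \Omega^{-1}$ serves as metric and as the curvature in the
log-determinant correction (the FOCE convention). Fixed effects (and
optionally variances and proportional error SDs) are optimised on the
log scale with `nlminb` (relative tolerance $10^{-6}$), warm-starting
each subject's $u$ across objective evaluations and restarting once on a
premature convergence code.

The workflow is sequential, as is standard for a perpetrator–probe
system: the RIF model is fitted first; its empirical Bayes parameter
estimates define continuous subject-specific concentration curves
$C_{RIF}(t)$ (not interpolated observations — the inhibition term needs
the whole curve), which are then fixed inputs to the CPI fit
(simultaneous plasma + urine, both conditions) and the RSV fit.

Diagnostics: `vpc()` simulates replicate trials and returns 2.5/50/97.5
percentile bands per stream, condition and nominal time plus the
replicate interval of the bin medians; `gof_table()` returns PRED,
IPRED, IWRES and a linearisation-based conditional weighted residual
(`CWRES_L`, a first-order expansion around the empirical Bayes mode —
labelled distinctly because classic CWRES is defined for the FOCE
linearisation around zero).

**Identifiability.** In the fitted parameterisation the baseline CPI
volume is informed only by dynamic data: at baseline the system sits at
steady state, where $V$ cancels. `profile_likelihood()` therefore checks
the base (single-volume) model: profiled over ±50%, the objective rises
by far more than 3.84 (the 95% χ²(1) cut) when plasma *and* urine data
from both conditions are used, and stays flat with baseline plasma
alone. This reproduces, as a numerical property, the claim that urine
and DDI-phase data are what make $V_{CPI}$ estimable.

**Recovery harness.** The package's simulation–estimation study fits 20
replicate 12-subject trials generated at the packaged estimates,
starting each fit from one fixed set of deliberately wrong initial
values and estimating the six CPI fixed effects with the random-effect
variances and residual SDs held at their generating values — a
12-subject trial carries little information about seven variance
components, and the scientific question is fixed-effect recovery. Median
bias for $k_{syn}$, $CL_b$, $CL_R$ and $K_i$ is a few percent; the
baseline $V$ is (by the argument above) not recoverable in this design
and is excluded from that expectation.

## DDI simulation and power

`simulate_ddi_population()` simulates a two-period crossover per virtual
subject: a control period at the individual baseline and an inhibited
period where the driving term $C_{RIF}(t)/K_i$ in the CPI equation is
scaled by the scenario multiplier $r$ (0.025–20 emulates weaker or
stronger perpetrators; $r=1$ is the RIF reference). AUC(0–24 h) is
computed by trapezoid on the trial sampling grid in each period, exactly
as a clinical analysis would. A second scenario knob $\rho$ applies the
same driving term to synthesis, $k_{syn}/(1+\rho\,C_{RIF}/K_i)$:
$\rho = 0$ leaves synthesis untouched and reproduces the transporter-only
simulation bit for bit; increasing $\rho$ lowers the apparent AUCR and
illustrates how synthesis inhibition by a perpetrator would bias a
biomarker readout.

Defaults, fixed after calibrating the simulation switches against the
reported summary values (the mean simulated AUCR vector and the minimal
sample sizes):

* `vshift = TRUE` — the RIF-condition volume applies in the inhibited
  period of hypothetical-inhibitor scenarios (mean AUCR at
  $r \in \{0.05, 0.25, 1, 20\}$ then lands within ~6% of the reported
  {1.26, 2.02, 3.46, 6.9});
* `iov = TRUE`, `share_eta = TRUE` — a true crossover with
  period-specific $\kappa$;
* `noise = FALSE` — AUCs are computed from noise-free sampled profiles,
  so the spread of log AUCR reflects the random effects only; with this
  setting the weak-inhibitor sample size reproduces the reported value
  (residual noise moves it by about one subject).

`power_curve()` estimates, for each sample size $n$, the rejection
fraction of a two-sided one-sample t-test of mean log AUCR $\neq 0$ at
level $\alpha$ over simulated trials, and reports the smallest $n$
reaching the target power (0.8). At $r = 0$ the rejection rate is the
type-I error and sits inside the binomial interval around $\alpha$.

One reported quantity resists reproduction: the minimal sample size for
the moderate inhibitor ($r = 0.25$, reported as 10 at $\alpha = 0.01$).
Under the published variabilities the per-subject SD of log AUCR is
about 0.26, so the mean effect $\log 2.02 = 0.70$ reaches 80% power at
5–6 subjects — under every switch setting (noise on or off, shared or
independent $\eta$). Ten subjects would require a log-AUCR SD near 0.5,
which neither the published random-effect magnitudes nor the reported
13% CV of clinical CPI AUCR supports; the power-simulation details
beyond the main text are not available. The package reports its honestly
computed value.

## Numerical choices

* **Two solution routes.** User-facing `simulate_*()` functions default
  to `deSolve::lsoda` (rtol $10^{-8}$, atol $10^{-10}$) with dose and
  collection boundaries as explicit output times. Population-scale work
  (trial generation, estimation, power) uses compiled fixed-grid
  propagators: exponential-trapezoid recursions for the linear RIF and
  CPI systems (the CPI step is exact for constant coefficients, so the
  endogenous baseline holds $C_{ss}$ to machine precision) and RK4 with
  stability-aware substepping for RSV (the RIF-condition $V_1$ of ~3 L
  makes that system stiff). The two routes agree well within 0.5% and
  are cross-checked in the test suite, including against an independent
  convolution quadrature for the transit-input model.
* **Grids.** The estimation grid is 1/16 h: every design time is an
  exact binary multiple, so observation times map to grid indices
  without rounding error. Trial generation uses 1/32 h; the transit
  input additionally substeps 4× internally because $t^{8.63}$ rises
  steeply through the first samples.
* **Degenerate inputs.** Zero dose yields identically zero profiles;
  parameters without a random effect get a negligible prior variance
  floor ($10^{-8}$) in the Laplace engine; a failed inner optimisation
  is penalised rather than fatal and flagged on the fit object;
  ill-conditioned Gauss–Newton systems fall back to a Levenberg-style
  ridge.
* **Problem sizes.** The packaged analyses use 1000 virtual subjects
  per AUCR scenario, 2000–5000 simulated trials per power point, 20
  replicate trials in the recovery study, and 100–500 VPC replicates —
  sizes at which the Monte-Carlo error is comfortably below the
  tolerances being checked.

## Known limitations

* No hepatic (permeability-limited) liver compartment, no MRP2 efflux,
  no enterohepatic recirculation — the model reads strictly systemically.
* The binary occasion-level covariate cannot represent a time-varying
  volume within an occasion, which is why the baseline $V$ is
  unidentified whenever the shift is estimated.
* Exact NONMEM objective values are not a goal; the Laplace/FOCE-style
  OFV is validated against adaptive quadrature on small models and used
  for recovery-based checks only.
* Standard errors are not computed (no covariance step); bootstrap over
  simulated trials is the intended route.
* The power machinery assumes the fitted variabilities transfer to the
  hypothetical-inhibitor scenarios; for inhibitors with very different
  PK the RIF-shaped exposure profile is itself an assumption.
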