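---
title: "A lipid-based PBTK model for a PCB mixture: model, induction
  balance, and hierarchical Bayesian calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A lipid-based PBTK model for a PCB mixture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lipidpbtk)
```

## The model

`lipidpbtk` implements a five-compartment physiologically based
toxicokinetic (PBTK) model for a mixture of six PCB congeners (118,
138, 153, 170, 180, 187) in rats, written entirely on a *lipid basis*:
the state variables are chemical masses in the neutral-lipid-equivalent
(NLE) spaces of blood, fat, liver, and the rapidly and poorly perfused
tissue lumps.  The NLE space of a tissue is all of its neutral lipids
plus 30% of its phospholipids.  Because highly lipophilic chemicals
such as PCBs are assumed to distribute only in that space, and to be at
equal concentration per unit lipid across equilibrated compartments, no
tissue/blood partition coefficients are needed — the only
chemical-specific parameters are metabolic.

For each congener and each non-hepatic tissue,

$$\frac{dA_{nlt}}{dt} = Q_{nlt}\,(C_{nla} - C_{nlt}), \qquad
  C_{nlt} = A_{nlt}/V_{nlt},$$

where $A_{nlt}$ (µg) is the mass in the tissue's NLE, $Q_{nlt}$
(mL NLE/h) the NLE flow through the tissue, and $C_{nla}$ the NLE
concentration of arterial blood.  Concentrations convert to the
measurable total-lipid basis via the tissue's NLE/total-lipid fraction,
$C_{tlt} = C_{nlt}\,V_{nlt}/V_{tlt}$.  The liver adds a first-order
metabolic sink driven by CYP450:

$$\frac{dA_{nlL}}{dt} = Q_{nlL}(C_{nla} - C_{nlL})
  - v_0\,\mathrm{BW}^{0.75}\,\frac{A^{CYP}}{A^{CYP}_0}\,C_{nlL},$$

with $v_0$ the basal clearance (mL/h/kg^0.75, body weight in kg) and
$A^{CYP}$ the hepatic amount of the metabolizing enzyme.  Enzyme
turnover follows a production/degradation balance with linear,
concentration-driven induction:

$$\frac{dA^{CYP}}{dt} = k_0 - k_e A^{CYP} + k_0 F\, C_{IND},$$

which is stationary at $A^{CYP}_0 = k_0/k_e$ in the absence of inducer
(the package derives $A_0$ from this closure).  Two enzymes are
tracked.  PCB 118, the only mono-ortho congener in the mixture, is
metabolized via CYP1A and drives CYP1A induction through its own liver
NLE concentration; the five multi-ortho congeners are metabolized via
CYP2B, whose inducer concentration is the summed liver NLE
concentration of all six congeners (additive induction with equal
weights).  A single $(A_0, k_e, k_0)$ set serves both enzymes by
default — only the ratio $A/A_0$ enters the kinetics, so absolute
baselines are nearly irrelevant — with per-enzyme overrides available.
A Hill-type stimulation, Ah-receptor occupancy, time-lagged
stimulation, competitive P450 inhibition and Phase-II induction are
deliberately out of scope: the linear slope $F$ lumps the unresolved
steps between lipid-space concentration and enzyme synthesis.

### Blood and absorption closures

Two pieces are not fixed by the compartment equations and are package
design choices:

* **Blood pool.**  An explicit well-mixed blood NLE compartment: the
  arterial concentration equals the pool concentration, and the pool
  receives the flow-weighted venous return
  $\sum_t Q_{nlt} C_{nlt} - Q_{co} C_{nla}$.
* **Absorption.**  Oral doses are applied as instantaneous boluses into
  the liver NLE compartment with 100% bioavailability.  PCBs are nearly
  completely absorbed orally, and routing the bolus through the liver
  preserves first-pass exposure of the induction sensor.  Dose events
  are specified in µg/kg per congener; by default the administered mass
  is recomputed from the body weight current at each event (configurable
  to fixed amounts).

### Physiology, growth, and covariates

Reference physiology is a 225 g rat (conventional flows/volumes scaled
by lipid-content ratios to the NLE basis).  Body weight between study
start and sacrifice is interpolated linearly from the measured
endpoints; volumes scale linearly with weight and flows with
BW^0.75, matching the allometric scaling of clearance.  A measured
liver-weight fraction, when available, overrides the scaled liver
volume (1 g tissue = 1 mL).  Plasma observations are mapped from the
blood pool by assuming equal NLE-basis concentration in plasma and
whole-blood lipid, then converting with the plasma NLE/total-lipid
ratio (0.748).

The printed blood NLE ratio (0.0019) carries two significant figures;
the reference NLE flow column is consistent with 9.45/4980 ≈ 0.0018976.
The package stores the printed value as the default and exposes the
back-calculated ratio as an override, rather than inventing unprinted
precision silently.

## Numerical integration

Between dose events the per-congener flow system is linear with slowly
varying coefficients, and its Jacobian is arrow-shaped (tissues couple
only through blood).  The default integrator (`method = "sdirk"`,
compiled) exploits this:

* a two-stage, L-stable SDIRK scheme (Alexander's method,
  $\gamma = 1 - 1/\sqrt{2}$) advances each congener with *exact* linear
  stage solves via a closed-form Schur complement on the blood row;
* the scalar enzyme balances are advanced by their exact exponential
  solution in half-steps around the congener update (Strang-type
  splitting), with the inducer concentration clamped at zero so the
  ratio $A/A_0$ never drops below 1;
* step sizes follow a geometric ladder restarted at every dose event
  (`h0` doubling to `hmax`), resolving the post-bolus transient while
  taking long steps between doses; L-stability damps the fast blood
  mode (time scale ≈ 0.004 h) at any step length;
* the metabolized-mass increment uses the same stage combination as the
  state update, so absorbed dose = body burden + metabolized holds to
  machine precision *by construction*, independent of step size.

Defaults are `h0 = 0.01` h and `hmax = 3` h, which agree with a
tight-tolerance `deSolve::lsoda` solution of the reference
right-hand side (`pbtk_rhs`) to ≈0.1% on the hardest case (daily
500 µg/kg, 90 days, full induction).  During MCMC the package uses
`h0 = 0.1`, `hmax = 24` (≈0.4% accuracy) — measurement error SDs are
0.2–0.4 on the log scale, so a 0.004 model perturbation is
inconsequential there, and the calibration needs on the order of a
million solves.  The `lsoda` path (relative tolerance 1e-8, absolute
1e-10 µg, events applied with a 1 µh offset so outputs at a dose time
are pre-dose on both paths) remains available for verification.

The second-order stages can leave tiny negative masses immediately
after a bolus; these decay within a step and are clamped only where
logarithms or the inducer concentration are formed.

## The synthetic-study generator

No public deposit of the original in vivo data exists, so the package
generates studies with the statistical structure the analysis assumes:
the full crossing of 3 dose levels (5/50/500 µg/kg per congener),
4 dosing protocols (daily; weekly; daily to day 13 then nothing;
13 irregularly timed doses), and 2 sacrifice days (41/90), with 6 rats
per cell (144 rats) by default.  The original study's irregular dose
times and exact per-cell counts (totalling 142) are unprinted; the
nonperiodic protocol defaults to doses on days
{0, 1, 2, 5, 8, 9, 15, 22, 29, 43, 57, 71, 85} and is fully
overridable.

Per-rat quantities are drawn once per study:

* initial body weight ~ Normal(225 g, 15 g), truncated positive;
* day-90 growth factor ~ Normal(1.6, 0.1), with linear interpolation to
  the rat's sacrifice day (the study measured weights but not their
  distribution; these are documented, configurable defaults chosen as
  typical of young male rats over a 90-day study);
* liver-weight fraction ~ Normal(0.04, 0.004), truncated to (0, 0.1);
* basal clearances $v_{0,ik}$ ~ lognormal$(\mu_k, \Sigma_k)$ per
  congener.  Throughout the package, $\mu$ is the mean and $\Sigma$ the
  SD of *natural-log* clearance, so $e^{\mu}$ is the population median
  and $e^{2\Sigma}$ reads as "deviating from the median by a factor of
  ~2" when $\Sigma \approx 0.35$.

Observations are the simulated total-lipid concentrations at sacrifice
in plasma and liver (plus fat for rats sacrificed at ≥90 days,
mirroring the study) multiplied by lognormal measurement error with
per-tissue log-SD $\sigma$.  True per-rat clearances are stored with
the study, so parameter-recovery experiments are self-contained.

What the generator does *not* emulate: assay detection limits or
censoring, congener cross-contamination, inter-rat physiology variation
beyond body/liver weight (the original analysis found physiology
variation immaterial), tissue-specific congener affinity, or dropout.
Passing tests therefore demonstrate statistical correctness of the
pipeline under the model's own assumptions — not robustness to the
tissue-affinity misspecification known to exist in real data (see
*Limitations*).

## Priors

* $\mu_k$ (population mean log clearance): uniform on the log scale
  with $e^{\mu} \in [0.001, 1]$ mL/h/kg^0.75 — documented defaults; the
  original bounds were set by observing model behaviour and never
  printed.
* $\Sigma_k$: inverse-gamma(shape 1, scale 0.8).  The source is
  ambiguous about whether the IG sits on $\Sigma$ or $\Sigma^2$; since
  0.8 is identified with "the initial assumption on the lognormal
  $\Sigma$", the package defaults to IG on the SD itself and exposes
  `sigma_v0_parameterization = "variance"` as a switch.
* $F_{1A}, F_{2B}$: uniform on [0, 10] (per µg/mL NLE), sampled on the
  log scale with the Jacobian included.
* $\sigma$ (per-tissue error SD): uniform on [0.01, 2].
* Per-rat $v_{0,ik}$: lognormal$(\mu_k, \Sigma_k)$ at the current
  population values (step 1) or at the step-1 posterior medians
  (step 2).

## Two-step calibration

Basal and induced clearance are not jointly identifiable from high-dose
data, so the calibration is decomposed:

1. **Step 1 — basal clearances.**  Only lowest-dose records, induction
   off ($F = 0$; induction is negligible at 5 µg/kg, which the model
   itself reproduces).  Sampled: $\mu_k$, $\Sigma_k$ (6 congeners, or
   one shared pair in `pooled_v0_variant()`), all per-rat clearances,
   and the three error SDs.
2. **Step 2 — induction.**  The 50 and 500 µg/kg records.  Per-rat
   clearances are still sampled, but under the step-1 population
   posteriors as *fixed* informative priors; the population mean and
   variance are not updated.  Sampled: $F_{1A}$, $F_{2B}$ (no
   inter-individual variation — individual variability is carried by
   basal clearance), per-rat clearances, error SDs.  If more than 5% of
   the per-rat clearance medians end up outside the 3σ band of their
   step-1 priors, the fit warns that the population parameters should
   be re-optimized.  Error SDs are deliberately re-estimated in both
   steps; letting them float improves mixing.

### Sampler design

Blockwise Gaussian random-walk Metropolis on log-transformed positive
parameters:

* blocks: one $(\mu_k, \log\Sigma_k)$ pair per congener (prior-only —
  no simulation), one block per rat (exactly one compiled ODE solve),
  one error block (reweights cached residuals — no simulation), and in
  step 2 one induction block (re-simulates every rat, since $F$ is
  shared).  The likelihood cache stores per-rat log-residual vectors
  and invalidates only what a block touched; this caching is what makes
  the sampler affordable.
* proposal scales adapt by Robbins–Monro
  ($s \leftarrow s\,e^{(a - a^\*)/n^{0.55}}$) toward a target
  acceptance of 10% during burn-in only and are frozen afterwards, so
  the retained draws satisfy detailed balance.  The 10% target suits
  this system's block dimensions; it is a setting, not an asserted
  optimum.
* burn-in: the first 40% of iterations.
* three chains from over-dispersed starts: population means uniform
  over their full prior bounds, $\Sigma$ from its IG prior clamped to
  [0.1, 1.5] (the IG(1, ·) tail is heavy enough to stall chains
  otherwise), per-rat log-clearances Normal around the drawn mean with
  twice the drawn SD (capped at 1), $\log F$ uniform on
  $[\log 10^{-4}, \log 10]$, error SDs log-uniform on [0.05, 1.5].
* everything is seeded: chain $c$ uses `seed + c` for its initial draw
  and continues the same stream for proposals, so fits replay
  bit-identically.

Convergence is judged by the classic Gelman–Rubin
$\hat R = \sqrt{((n-1)/n\,W + B/n)/W}$ across the three chains.
Posterior summaries report the pooled post-burn-in median per
parameter, the CV of the per-chain medians (the package's reading of a
"chain CV"), and $\hat R$ computed on the sampling scale.

### Problem sizes

The package's recovery experiment (in the acceptance test suite) uses a
reduced study of 36 rats — 3 dose levels × {daily, weekly} × {41, 90}
days × 3 rats per cell — with 10,000 iterations × 3 chains per step,
generated at the reference calibration medians.  These sizes were
chosen as the smallest design that still identifies all parameter
groups (daily/weekly contrast for the induction dynamics, both
sacrifice days for fat observations and growth, ≥12 low-dose rats for
the population means); the full 144-rat frame remains the generator
default and runs the same code path.

## Population evaluation

`monte_carlo_population()` draws per-rat clearances from the calibrated
lognormal population (induction factors at their medians), simulates
each draw, and reports pointwise 2.5/50/97.5% bands per tissue and
congener.  `induction_ratio_report()` tracks $A/A_0$ (equivalently
$v_{cl}/v_0$) for both enzymes in the deterministic median-parameter
rat and reports terminal and maximum factors — both, because "increase
by a factor of n" can mean either; at 500 µg/kg daily they nearly
coincide.  `predicted_vs_observed()` tabulates observed against
simulated concentrations with per-tissue log-residual SDs and
per-congener/tissue mean residuals for spotting systematic offsets.

```{r example}
pop <- population_params()            # reference calibration medians
induction_ratio_report(pop, 500, "daily", horizon_days = 90)
```

## Known limitations

* **Tissue-dependent congener ordering.**  With one lipid space and no
  partition coefficients, the model predicts the *same* concentration
  ordering of the multi-ortho congeners in every tissue at
  quasi-steady state (a property the test suite asserts).  Real rats
  show small tissue-dependent reorderings (e.g. PCB 180 relatively
  enriched in fat lipid, PCB 187 in plasma), which this model class
  cannot reproduce; it surfaces as congener/tissue-specific offsets in
  predicted-vs-observed plots.
* **Basal-rate identification.**  Step 1 assumes induction is truly
  negligible at the lowest dose; if clearance were already elevated at
  5 µg/kg, the induction factors in step 2 would be biased low.
* **One-sided clearance sensitivity at small study sizes.**  For a
  slowly metabolized congener, a rat that clears only ~15% of its
  burden by sacrifice has a likelihood that is nearly flat as its log
  clearance falls toward zero (the predictions converge to the
  no-metabolism limit), while rising clearance is sharply penalized.
  With few low-dose rats the hierarchical posterior cannot fully
  deconvolve this asymmetry from measurement noise: population SDs
  inflate and population medians drift low for the weakly identified
  congeners.  The package's own recovery experiments exhibit this at
  12 low-dose rats; it fades with study size, and the original study's
  low-dose arm was four times larger.
* **Step-1 → step-2 prior transfer** uses independent per-congener
  marginals; posterior correlations between clearances are not carried
  over (a multivariate transfer destabilizes convergence and is
  out of scope).
* The enzyme baseline $(A_0, k_e, k_0)$ is shared between CYP1A and
  CYP2B and taken from the literature; only $A/A_0$ matters, so
  rescaling baselines leaves results essentially unchanged — but
  enzyme-specific turnover *rates* (not just amounts) would change the
  induction dynamics' time constant.
* Solver accuracy is traded deliberately during MCMC (≈0.4%); all
  reported simulations use the accurate default ladder, and the exact
  mass balance is independent of that trade.
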