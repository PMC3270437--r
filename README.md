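# lipidpbtk

Lipid-based physiologically based toxicokinetic (PBTK) modelling of a
six-congener PCB mixture in rats, with CYP1A/CYP2B induction and
hierarchical Bayesian population calibration by blockwise
random-walk Metropolis MCMC.

## The problem

Polychlorinated biphenyls are highly lipophilic, persist in the body
for years, and occur as mixtures (here: PCBs 118, 138, 153, 170, 180,
187). Conventional PBTK models need a partition coefficient per
chemical-tissue pair — dozens of parameters for a mixture. A
*lipid-based* PBTK model removes them by assuming the chemical lives
only in the neutral-lipid-equivalent (NLE) space of blood and tissues,
at equal concentration per unit lipid across equilibrated
compartments. The remaining chemical-specific parameters are
metabolic, and those are what the data can identify.

For each congener, non-hepatic compartments obey

    dA_nlt/dt = Q_nlt (C_nla − C_nlt),     C_tlt = C_nlt · V_nlt/V_tlt

(masses in tissue NLE, flows in mL NLE/h, with conversion to the
measurable total-lipid basis), and the liver adds a first-order
metabolic sink whose clearance is scaled by body weight and by enzyme
induction:

    v_cl = v0 · BW^0.75 · A_CYP/A0,
    dA_CYP/dt = k0 − ke·A_CYP + k0·F·C_IND,   A0 = k0/ke.

PCB 118 (mono-ortho) is metabolized via CYP1A and induces it through
its own liver NLE concentration; the five multi-ortho congeners go
through CYP2B, induced by the summed liver NLE concentration of all
six congeners. One linear slope factor per enzyme (F_1A, F_2B) covers
all dose levels and dosing protocols.

Inter-rat variability enters through lognormal per-rat basal
clearances, v0_ik ~ LN(mu_k, sigma_k); observations carry lognormal
measurement error with a separate log-SD per tissue (plasma, liver,
fat). Because the original 142-rat dataset is not deposited, the
package ships a synthetic-study generator with the same design
(3 dose levels x 4 protocols x 2 sacrifice days), and the calibration
is validated by parameter recovery on synthetic studies.

The calibration follows a two-step decomposition: basal clearances
from the low-dose data with induction off, then induction factors from
the high-dose data with the step-1 population posteriors as fixed
informative priors. Chains are blockwise Metropolis with per-rat ODE
caching, ~10% target acceptance, and Gelman–Rubin convergence checks.

## Worked example

Simulate the median-calibration rat under the most intense protocol —
daily 500 µg/kg of each congener for 90 days, body weight growing from
225 g to 360 g:

```r
library(lipidpbtk)
phys <- scale_to_nle(conventional_physiology(), lipid_content())
sim <- simulate_rat(phys, pcb_mixture(),
                    induction_params(F_1A = 0.045, F_2B = 0.0025),
                    build_schedule("daily", 500, 90),
                    rat_covariates(225, 360, 90, 0.04),
                    t_grid = c(0, 2160))
sim
#> lipid-basis PBTK simulation (sdirk)
#>   2 output times to 90 days; 6 congeners
#>   terminal CYP ratios A/A0: CYP1A 4.64, CYP2B 3.24
max(abs(mass_balance(sim)$rel_error))
#> [1] 2.978827e-15
```

The terminal CYP ratios say metabolic clearance of PCB 118 ends up
~4.6-fold above basal and the multi-ortho congeners ~3.2-fold — the
high-dose induction the model exists to capture. The mass-balance
check (absorbed dose = body burden + cumulative metabolized) holds to
machine precision by construction of the integrator.

The same report for the calibrated population:

```r
induction_ratio_report(population_params(), 500, "daily",
                       horizon_days = 90)
#> clearance-increase factors (A/A0):
#>   CYP1A (PCB 118):     terminal 4.64, maximum 4.64
#>   CYP2B (multi-ortho): terminal 3.24, maximum 3.24
```

A full calibration round-trip on synthetic data:

```r
study <- generate_population(study_design(), seed = 1)   # 144 rats
fit <- calibrate_two_step(study, settings = mcmc_settings(seed = 1))
fit$summary      # parameter, median, chain CV, Gelman-Rubin R
```

See the vignette (`vignettes/lipid-pbtk-calibration.Rmd`) for the
model assumptions, prior choices, sampler design and limitations, and
`inst/cli/lipidpbtk.R` for a command-line front end
(`generate | simulate | calibrate | evaluate`).

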