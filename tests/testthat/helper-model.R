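# Shared fixtures, built in code and cached for the session.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures))
    assign(name, force(expr), envir = .fixtures)
  get(name, envir = .fixtures)
}

default_phys <- function() {
  fixture("phys", scale_to_nle(conventional_physiology(),
                               lipid_content()))
}

# Reference-calibration induction parameters
ref_induction <- function() {
  induction_params(F_1A = 0.045, F_2B = 0.0025)
}

# A growing rat with the synthetic-population mean covariates
mean_cov <- function(days = 90) {
  rat_covariates(225, 225 + 225 * 0.6 * days / 90, days, 0.04)
}

# Small, cheap synthetic study (weekly protocol keeps the ODE solves
# light): 3 dose levels x 2 sacrifice days x 2 rats = 12 rats.
small_study <- function() {
  fixture("small_study", generate_population(
    study_design(protocols = "weekly", rats_per_cell = 2), seed = 99))
}
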