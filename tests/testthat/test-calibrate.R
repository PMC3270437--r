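# Short-chain calibrations exercise the machinery end to end; the
# full-length parameter-recovery experiment lives in the acceptance
# suite.

tiny_settings <- function(n_iter = 300, n_chains = 2, seed = 5)
  mcmc_settings(n_iter = n_iter, n_chains = n_chains, seed = seed)

tiny_study <- function() {
  fixture("tiny_study", generate_population(
    study_design(protocols = "weekly", sacrifice_days = c(41, 90),
                 rats_per_cell = 1), seed = 12))
}

test_that("the two-step calibration returns a complete, well-formed
           fit", {
  fit <- fixture("tiny_fit",
                 calibrate_two_step(tiny_study(),
                                    settings = tiny_settings()))
  expect_s3_class(fit, "pcb_calibration")
  ks <- pcb_mixture()$congener
  expect_setequal(
    fit$summary$parameter[fit$summary$step == 1],
    c(paste0("v0_", ks), paste0("sigma_v0_", ks),
      paste0("sigma_", c("plasma", "liver", "fat"))))
  expect_setequal(
    fit$summary$parameter[fit$summary$step == 2],
    c("F_1A", "F_2B", paste0("sigma_", c("plasma", "liver", "fat"))))
  expect_true(all(is.finite(fit$summary$median)))
  expect_true(all(fit$summary$median > 0))
  for (ch in c(fit$step1$chains, fit$step2$chains)) {
    expect_true(all(ch$acceptance >= 0 & ch$acceptance <= 1))
    expect_true(all(is.finite(ch$log_post)))
  }
  expect_s3_class(fit$pop, "population_params")
  # step 1 samples only low-dose rats; step 2 only the higher doses
  st <- tiny_study()
  n_low <- sum(st$design$dose_level == 5)
  n_high <- sum(st$design$dose_level > 5)
  expect_equal(nrow(fit$step1$layout$idx$v0), n_low)
  expect_equal(nrow(fit$step2$layout$idx$v0), n_high)
})

test_that("calibrations replay identically under the same settings", {
  a <- fixture("tiny_fit",
               calibrate_two_step(tiny_study(),
                                  settings = tiny_settings()))
  b <- calibrate_two_step(tiny_study(), settings = tiny_settings())
  expect_identical(a$summary, b$summary)
  expect_identical(a$step2$chains[[1]]$samples,
                   b$step2$chains[[1]]$samples)
})

test_that("a single dose level is refused", {
  st <- subset_study(tiny_study(),
                     which(tiny_study()$design$dose_level == 5))
  expect_error(calibrate_two_step(st, settings = tiny_settings()),
               "span")
})

test_that("with tiny noise the posterior collapses near the truth", {
  des <- study_design(dose_levels = c(5, 500), protocols = "weekly",
                      sacrifice_days = c(41, 90), rats_per_cell = 2,
                      bw_sd = 0, growth_sd = 0, liver_ratio_sd = 0)
  pop <- population_params(
    sigma_v0 = setNames(rep(0.01, 6), names(population_params()$mu_v0)),
    sigma_err = c(plasma = 0.02, liver = 0.02, fat = 0.02))
  st <- generate_population(des, pop, seed = 31)
  fit <- calibrate_two_step(
    st, settings = mcmc_settings(n_iter = 1500, n_chains = 2,
                                 seed = 17))
  ks <- names(pop$mu_v0)
  est <- fit$summary$median[match(paste0("v0_", ks),
                                  fit$summary$parameter)]
  expect_equal(est, unname(exp(pop$mu_v0)), tolerance = 0.15)
})

test_that("the pooled clearance variant condenses the six congeners", {
  # all congeners share one generating distribution
  mu_all <- log(0.027)
  pop <- population_params(
    mu_v0 = setNames(rep(mu_all, 6), names(population_params()$mu_v0)),
    sigma_v0 = setNames(rep(0.3, 6), names(population_params()$mu_v0)))
  st <- generate_population(
    study_design(dose_levels = c(5, 50), protocols = "weekly",
                 sacrifice_days = c(41, 90), rats_per_cell = 2),
    pop, seed = 23)
  pf <- pooled_v0_variant(st, settings = mcmc_settings(
    n_iter = 1200, n_chains = 2, seed = 19))
  expect_s3_class(pf, "pcb_pooled_fit")
  expect_true("v0_all" %in% pf$summary$parameter)
  # pooled median consistent with the shared generating distribution
  expect_equal(pf$mu, mu_all, tolerance = 0.25 * abs(mu_all))
  expect_gt(pf$sigma, 0)
})
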