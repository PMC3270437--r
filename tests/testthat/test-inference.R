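make_params <- function(study, sigma_err = c(plasma = 0.19,
                                             liver = 0.40, fat = 0.30),
                        F_1A = 0, F_2B = 0) {
  pop <- population_params()
  hierarchical_params(mu_v0 = pop$mu_v0, sigma_v0 = pop$sigma_v0,
                      F_1A = F_1A, F_2B = F_2B, sigma_err = sigma_err,
                      v0_individual = study$true_params$v0)
}

test_that("zero residuals reduce the log-likelihood to its
           normalizing constant", {
  # noiseless observations at the true parameters
  des <- study_design(dose_levels = 5, protocols = "weekly",
                      sacrifice_days = 41, rats_per_cell = 2,
                      bw_sd = 0, growth_sd = 0, liver_ratio_sd = 0)
  pop0 <- population_params(F_1A = 0, F_2B = 0,
                            sigma_err = c(plasma = 0, liver = 0,
                                          fat = 0))
  st <- generate_population(des, pop0, seed = 4)
  s <- 0.25
  params <- make_params(st, sigma_err = c(plasma = s, liver = s,
                                          fat = s))
  ctx <- sim_context(st, control = list(h0 = 0.01, hmax = 3))
  ll <- log_likelihood(params, st, ctx)
  N <- nrow(st$observations)
  expect_equal(ll, -N * log(s * sqrt(2 * pi)), tolerance = 1e-6)
})

test_that("scaling sigma changes each term by the Normal-density
           algebra", {
  st <- small_study()
  ctx <- sim_context(st)
  s <- 0.3
  p1 <- make_params(st, sigma_err = c(plasma = s, liver = s, fat = s))
  p2 <- make_params(st, sigma_err = c(plasma = 2 * s, liver = 2 * s,
                                      fat = 2 * s))
  ll1 <- log_likelihood(p1, st, ctx)
  ll2 <- log_likelihood(p2, st, ctx)
  # sum of residual squares recovered from the two evaluations
  N <- nrow(st$observations)
  rss <- sum(vapply(seq_along(ctx$rats), function(i) {
    lp <- lipidpbtk:::predict_rat(ctx, i, st$true_params$v0[i, ], 0, 0)
    sum((ctx$rats[[i]]$log_obs - lp)^2)
  }, numeric(1)))
  expect_equal(ll2 - ll1,
               -N * log(2) - rss / 2 * (1 / (4 * s^2) - 1 / s^2),
               tolerance = 1e-8)
})

test_that("a three-observation case matches a hand-summed density
           oracle", {
  st <- subset_study(small_study(), 1)
  obs3 <- st$observations[1:3, ]
  st$observations <- obs3
  params <- make_params(st)
  ctx <- sim_context(st, control = list(h0 = 0.01, hmax = 3))
  d <- st$design[1, ]
  sim <- simulate_rat(default_phys(),
                      pcb_mixture(v0 = st$true_params$v0[1, ]),
                      induction_params(),
                      build_schedule(d$protocol, d$dose_level,
                                     d$sacrifice_day),
                      rat_covariates(d$bw_initial, d$bw_final,
                                     d$sacrifice_day,
                                     d$liver_weight_ratio),
                      t_grid = c(0, d$sacrifice_day * 24),
                      control = list(h0 = 0.01, hmax = 3))
  sig <- c(plasma = 0.19, liver = 0.40, fat = 0.30)
  oracle <- 0
  for (r in seq_len(3)) {
    pred <- sim$conc_tl[2, obs3$tissue[r], obs3$congener[r]]
    oracle <- oracle + dnorm(log(obs3$concentration[r]) - log(pred),
                             0, sig[[obs3$tissue[r]]], log = TRUE)
  }
  expect_equal(log_likelihood(params, st, ctx), oracle,
               tolerance = 1e-9)
})

test_that("log-likelihood rejects malformed inputs by name", {
  st <- small_study()
  bad <- st
  bad$observations$concentration[1] <- -1
  expect_error(sim_context(bad), "rat001")
  params <- make_params(st)
  params$v0_individual <- params$v0_individual[1:3, ]
  expect_error(log_likelihood(params, st, sim_context(st)), "rows")
})

test_that("the log prior matches its closed forms and support", {
  st <- small_study()
  params <- make_params(st, F_1A = 0.045, F_2B = 0.0025)
  priors <- prior_spec()
  lp <- log_prior(params, priors)
  expect_true(is.finite(lp))

  # outside any uniform support the prior is -Inf, not an error
  out <- params; out$mu_v0[1] <- log(5)
  expect_identical(log_prior(out, priors), -Inf)
  out2 <- params; out2$F_1A <- 99
  expect_identical(log_prior(out2, priors), -Inf)
  out3 <- params; out3$sigma_err[1] <- 3
  expect_identical(log_prior(out3, priors), -Inf)

  # a per-rat clearance at exp(mu) contributes the lognormal
  # mode-region density
  one <- params
  one$v0_individual[1, "118"] <- exp(one$mu_v0[["118"]])
  delta <- log_prior(one, priors) -
    (log_prior(params, priors) -
       dlnorm(params$v0_individual[1, "118"], params$mu_v0[["118"]],
              params$sigma_v0[["118"]], log = TRUE))
  expect_equal(delta,
               dlnorm(exp(one$mu_v0[["118"]]), one$mu_v0[["118"]],
                      one$sigma_v0[["118"]], log = TRUE),
               ignore_attr = TRUE)

  # inverse-gamma(1, 0.8) on the SD peaks at scale/(shape+1) = 0.4
  grid <- seq(0.05, 2, by = 0.001)
  dens <- lipidpbtk:::ldinvgamma(grid, 1, 0.8)
  expect_equal(grid[which.max(dens)], 0.4, tolerance = 1e-6)
})

test_that("the variance parameterization switch changes the
           sigma prior consistently", {
  st <- small_study()
  params <- make_params(st)
  p_sd <- prior_spec()
  p_var <- prior_spec(sigma_v0_parameterization = "variance")
  diff_lp <- log_prior(params, p_var) - log_prior(params, p_sd)
  manual <- sum(lipidpbtk:::ldinvgamma(params$sigma_v0^2, 1, 0.8) +
                  log(2 * params$sigma_v0)) -
    sum(lipidpbtk:::ldinvgamma(params$sigma_v0, 1, 0.8))
  expect_equal(diff_lp, manual)
})
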