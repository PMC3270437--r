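test_that("a flat target accepts essentially every proposal", {
  ch <- metropolis_run(function(theta) 0, c(x = 0), n_iter = 2000,
                       adapt = FALSE, scales = 0.5, seed = 1)
  expect_gt(mean(ch$acceptance), 0.999)
  # the chain is then the proposal random walk itself: increments are
  # iid Normal(0, scale)
  inc <- diff(ch$samples[, 1])
  expect_equal(sd(inc), 0.5, tolerance = 0.1)
})

test_that("a 1-D Normal target is recovered within Monte-Carlo error", {
  ch <- metropolis_run(function(theta) -0.5 * (theta - 3)^2 / 4,
                       c(x = 0), n_iter = 50000,
                       target_acceptance = 0.3, seed = 2)
  s <- chain_samples(ch)
  expect_equal(mean(s), 3, tolerance = 0.15)
  expect_equal(sd(s), 2, tolerance = 0.15)
})

test_that("chains replay bit-identically from their seed", {
  tgt <- function(theta) -0.5 * sum(theta^2)
  a <- metropolis_run(tgt, c(x = 1, y = -1), n_iter = 500,
                      blocks = list(1, 2), seed = 7)
  b <- metropolis_run(tgt, c(x = 1, y = -1), n_iter = 500,
                      blocks = list(1, 2), seed = 7)
  expect_identical(a$samples, b$samples)
  expect_identical(a$scales, b$scales)
  c <- metropolis_run(tgt, c(x = 1, y = -1), n_iter = 500,
                      blocks = list(1, 2), seed = 8)
  expect_false(identical(a$samples, c$samples))
})

test_that("adaptation steers acceptance toward its target and then
           freezes", {
  tgt <- function(theta) -0.5 * sum(theta^2)
  ch <- metropolis_run(tgt, c(x = 0), n_iter = 6000, scales = 20,
                       target_acceptance = 0.3, seed = 3)
  expect_equal(unname(ch$acceptance), 0.3, tolerance = 0.12)
  # scales no longer change after burn-in: replaying the post-burn-in
  # stretch with adapt = FALSE and the frozen scale matches behaviour
  expect_true(ch$scales != 20)
})

test_that("pathological targets warn instead of failing", {
  wall <- function(theta) if (any(theta != c(x = 0))) -Inf else 0
  expect_warning(
    metropolis_run(wall, c(x = 0), n_iter = 1500, adapt = FALSE,
                   seed = 4),
    "1000 consecutive")
  expect_error(metropolis_run(function(theta) -Inf, c(x = 0), 10),
               "non-finite")
})

test_that("Gelman-Rubin behaves at its analytic anchors", {
  set.seed(11)
  x <- rnorm(10000)
  # exact copies: R = sqrt((n-1)/n) <= 1
  expect_equal(unname(gelman_rubin(list(x, x, x))),
               sqrt((10000 - 1) / 10000))
  # iid chains from one distribution: R ~ 1
  r_iid <- gelman_rubin(list(rnorm(10000), rnorm(10000), rnorm(10000)))
  expect_gte(unname(r_iid), 1 - 1e-3)
  expect_lt(unname(r_iid), 1.05)
  # displaced chains: R >> 1.1
  expect_gt(unname(gelman_rubin(list(rnorm(1000), rnorm(1000) + 10))),
            5)
  # degenerate: no within-chain variance
  expect_identical(unname(gelman_rubin(list(rep(1, 100),
                                            rep(2, 100)))), Inf)
  expect_error(gelman_rubin(list(rnorm(100), rnorm(50))), "equal")
})

test_that("the sampler reproduces a grid-evaluated PBTK posterior on a
           two-parameter slice", {
  # one low-dose rat; two free congener clearances under their fixed
  # population priors, everything else held at truth
  st <- subset_study(small_study(), 1)
  ctx <- sim_context(st)
  v0_true <- st$true_params$v0[1, ]
  pop <- st$true_params$pop
  sig_err <- pop$sigma_err
  mu1 <- pop$mu_v0[["138"]]; mu2 <- pop$mu_v0[["153"]]
  sig_pop <- 0.35
  lp_fun <- function(theta) {
    v0 <- v0_true
    v0[["138"]] <- exp(theta[1])
    v0[["153"]] <- exp(theta[2])
    lpred <- lipidpbtk:::predict_rat(ctx, 1, v0, 0, 0)
    resid <- ctx$rats[[1]]$log_obs - lpred
    sum(dnorm(resid, 0, sig_err[ctx$rats[[1]]$tissue], log = TRUE)) +
      dnorm(theta[1], mu1, sig_pop, log = TRUE) +
      dnorm(theta[2], mu2, sig_pop, log = TRUE)
  }
  ch <- metropolis_run(lp_fun, c(lv138 = mu1, lv153 = mu2),
                       n_iter = 20000, blocks = list(1:2),
                       target_acceptance = 0.25, seed = 9)
  s <- chain_samples(ch)

  # dense-grid oracle for the same unnormalized posterior; the Normal
  # priors keep the posterior inside +-5 prior SDs of the means
  g1 <- seq(mu1 - 5 * sig_pop, mu1 + 5 * sig_pop, length.out = 100)
  g2 <- seq(mu2 - 5 * sig_pop, mu2 + 5 * sig_pop, length.out = 100)
  post <- outer(seq_along(g1), seq_along(g2),
                Vectorize(function(i, j) lp_fun(c(g1[i], g2[j]))))
  w <- exp(post - max(post))
  m1 <- sum(rowSums(w) / sum(w) * g1)
  m2 <- sum(colSums(w) / sum(w) * g2)
  expect_lt(abs(mean(s[, "lv138"]) - m1), 0.05)
  expect_lt(abs(mean(s[, "lv153"]) - m2), 0.05)
})
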