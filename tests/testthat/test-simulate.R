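test_that("RHS terms vanish where the model says they must", {
  phys <- default_phys()
  mix <- pcb_mixture()
  p <- induction_params(F_1A = 0.045, F_2B = 0.0025)
  tissues <- c("blood", "fat", "liver", "rapid", "poor")
  zero <- matrix(0, 5, 6, dimnames = list(tissues, mix$congener))
  A0 <- c(CYP1A = 0.1, CYP2B = 0.1)
  d <- pbtk_rhs(0, zero, A0, phys, mix, p)
  expect_equal(d$dmass, zero)
  expect_equal(unname(d$dcyp), c(0, 0))
  expect_equal(d$dmet, rep(0, 6))

  # equal NLE concentration in a tissue and arterial blood: no net flux
  m <- zero
  m["blood", ] <- phys$nle_volumes[["blood"]] * 2      # C_nla = 2
  m["fat", ] <- phys$nle_volumes[["fat"]] * 2          # C_fat = 2
  d2 <- pbtk_rhs(0, m, A0, phys, mix, p)
  expect_equal(unname(d2$dmass["fat", ]), rep(0, 6))

  # compartment-mass balance closes onto the metabolic sink
  m2 <- zero; m2[] <- abs(rnorm(30, 5))
  d3 <- pbtk_rhs(0, m2, A0, phys, mix, p)
  expect_equal(unname(colSums(d3$dmass)), -d3$dmet)

  expect_error(pbtk_rhs(0, m2 * NaN, A0, phys, mix, p), "non-finite")
})

test_that("zero dose stays at zero and conservation is exact", {
  phys <- default_phys()
  mix <- pcb_mixture()
  p <- induction_params()
  sched <- build_schedule("daily", 0, 10)
  sim <- simulate_rat(phys, mix, p, sched, t_grid = c(0, 120, 240))
  expect_true(all(sim$conc_tl == 0))
  expect_true(all(sim$cyp_ratio == 1))

  # single bolus, (near-)zero clearance: burden equals absorbed dose
  tiny <- pcb_mixture(v0 = setNames(rep(1e-12, 6), mix$congener))
  b <- build_schedule("custom", 50, 30, times = 0)
  sim2 <- simulate_rat(phys, tiny, induction_params(), b,
                       t_grid = c(0, 360, 720))
  mb <- mass_balance(sim2)
  expect_lt(max(abs(mb$rel_error)), 1e-12)
  expect_equal(mb$in_body[mb$time_h == 720],
               mb$absorbed[mb$time_h == 720], tolerance = 1e-9)
})

test_that("mass balance holds across all four protocols", {
  phys <- default_phys()
  mix <- pcb_mixture()
  p <- ref_induction()
  for (prot in study_protocols()) {
    sched <- build_schedule(prot, 500, 90)
    sim <- simulate_rat(phys, mix, p, sched, mean_cov(90),
                        t_grid = c(0, 984, 2160))
    expect_lt(max(abs(mass_balance(sim)$rel_error)), 1e-3,
              label = paste("relative mass error,", prot))
  }
})

test_that("per-kg doses are recomputed from the growing body weight", {
  phys <- default_phys()
  cov <- mean_cov(41)
  sched <- build_schedule("weekly", 50, 41)
  sim <- simulate_rat(phys, pcb_mixture(), induction_params(), sched,
                      cov, t_grid = c(0, 984))
  expected <- sum(50 * body_weight_at(cov, sched$time_h / 24) / 1000)
  expect_equal(unname(sim$absorbed[2, "153"]), expected)
})

test_that("without induction the kinetics are linear in dose", {
  phys <- default_phys()
  mix <- pcb_mixture()
  p0 <- induction_params()          # F = 0
  tg <- c(0, 480, 984)
  lo <- simulate_rat(phys, mix, p0, build_schedule("daily", 5, 41),
                     mean_cov(41), t_grid = tg)
  hi <- simulate_rat(phys, mix, p0, build_schedule("daily", 500, 41),
                     mean_cov(41), t_grid = tg)
  expect_equal(hi$conc_tl, lo$conc_tl * 100, tolerance = 1e-10)
})

test_that("more CYP2B induction never raises a multi-ortho
           concentration", {
  phys <- default_phys()
  mix <- pcb_mixture()
  tg <- c(0, 480, 984, 2160)
  sims <- lapply(c(0, 0.0025, 0.01), function(f2b)
    simulate_rat(phys, mix, induction_params(F_1A = 0.045, F_2B = f2b),
                 build_schedule("daily", 500, 90), mean_cov(90),
                 t_grid = tg))
  multi <- pcb_mixture()$congener[-1]
  for (j in 1:2) {
    a <- sims[[j]]$conc_tl[, , multi]
    b <- sims[[j + 1]]$conc_tl[, , multi]
    expect_true(all(b <= a * (1 + 1e-9)))
  }
})

test_that("the enzyme pool never drops below baseline", {
  phys <- default_phys()
  sim <- simulate_rat(phys, pcb_mixture(), ref_induction(),
                      build_schedule("nonperiodic", 500, 90),
                      mean_cov(90), t_grid = seq(0, 2160, by = 24))
  expect_true(all(sim$cyp_ratio >= 1 - 1e-12))
})

test_that("multi-ortho concentration ordering is tissue-independent at
           quasi-steady state", {
  phys <- default_phys()
  sim <- simulate_rat(phys, pcb_mixture(), ref_induction(),
                      build_schedule("daily", 50, 90), mean_cov(90),
                      t_grid = c(0, 2160))
  multi <- pcb_mixture()$congener[-1]
  orders <- apply(sim$conc_nle[2, , multi], 1, order)
  for (j in 2:ncol(orders))
    expect_equal(orders[, j], orders[, 1])
})

test_that("compiled integrator agrees with the lsoda reference", {
  phys <- default_phys()
  mix <- pcb_mixture()
  p <- ref_induction()
  sched <- build_schedule("daily", 500, 20)
  cov <- mean_cov(20)
  tg <- c(0, 240, 480)
  a <- simulate_rat(phys, mix, p, sched, cov, t_grid = tg)
  b <- simulate_rat(phys, mix, p, sched, cov, t_grid = tg,
                    method = "lsoda")
  expect_equal(a$conc_tl[2:3, , ], b$conc_tl[2:3, , ],
               tolerance = 5e-3)
  expect_equal(a$cyp_ratio, b$cyp_ratio, tolerance = 1e-3)
})

test_that("terminal washout decays at the slowest eigenvalue of the
           flow system", {
  phys <- default_phys()
  mix <- pcb_mixture()
  cov <- rat_covariates(225, 225, 90)      # constant physiology
  sched <- build_schedule("custom", 5, 90, times = 0)
  sim <- simulate_rat(phys, mix, induction_params(), sched, cov,
                      t_grid = c(0, 1800, 2160), method = "lsoda")
  # Jacobian of the single-congener linear system (PCB 118)
  V <- phys$nle_volumes[c("blood", "fat", "liver", "rapid", "poor")]
  Q <- phys$nle_flows[c("fat", "liver", "rapid", "poor")]
  vcl <- mix$v0[1] * 0.225^0.75
  J <- matrix(0, 5, 5)
  J[1, 1] <- -sum(Q) / V[1]
  for (t in 2:5) {
    J[1, t] <- Q[t - 1] / V[t]
    J[t, 1] <- Q[t - 1] / V[1]
    J[t, t] <- -Q[t - 1] / V[t]
  }
  J[3, 3] <- J[3, 3] - vcl / V[3]
  lambda_slow <- max(Re(eigen(J, only.values = TRUE)$values))
  slope <- diff(log(sim$conc_tl[2:3, "fat", "118"])) / diff(c(1800,
                                                              2160))
  expect_equal(unname(slope), lambda_slow, tolerance = 0.01)
})

test_that("tidy output carries both bases and every tissue", {
  phys <- default_phys()
  sim <- simulate_rat(phys, pcb_mixture(), induction_params(),
                      build_schedule("weekly", 5, 14),
                      t_grid = c(0, 168, 336))
  df <- as.data.frame(sim)
  expect_setequal(unique(df$basis), c("total_lipid", "NLE"))
  expect_true(all(c("plasma", "fat", "liver") %in% df$tissue))
  expect_equal(nrow(df), 2 * 3 * 5 * 6)
  # total-lipid concentration = NLE concentration x NLE/total-lipid
  nle <- df[df$basis == "NLE" & df$tissue == "liver", ]
  tl <- df[df$basis == "total_lipid" & df$tissue == "liver", ]
  expect_equal(tl$concentration, nle$concentration * 0.710)
})
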