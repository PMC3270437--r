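test_that("the default design reproduces the study frame", {
  st <- fixture("default_study_head", {
    # design frame only: 3 doses x 4 protocols x 2 days x 6 rats
    d <- study_design()
    expand.grid(dose_level = d$dose_levels, protocol = d$protocols,
                sacrifice_day = d$sacrifice_days,
                rat = seq_len(d$rats_per_cell))
  })
  expect_equal(nrow(st), 144)
  small <- small_study()
  expect_equal(nrow(small$design), 12)
  expect_s3_class(small, "pcb_study")
})

test_that("fixed seeds give byte-identical studies", {
  des <- study_design(protocols = "weekly", sacrifice_days = 41,
                      rats_per_cell = 2)
  a <- generate_population(des, seed = 5)
  b <- generate_population(des, seed = 5)
  expect_identical(a, b)
  c <- generate_population(des, seed = 6)
  expect_false(identical(a$observations$concentration,
                         c$observations$concentration))
})

test_that("adipose tissue is observed only at the 90-day sacrifice", {
  st <- small_study()
  obs <- merge(st$observations, st$design[c("rat_id", "sacrifice_day")])
  expect_true(all(obs$sacrifice_day[obs$tissue == "fat"] >= 90))
  d41 <- obs[obs$sacrifice_day == 41, ]
  expect_setequal(unique(d41$tissue), c("plasma", "liver"))
  expect_true(all(st$observations$concentration > 0))
})

test_that("degenerate noise collapses observations onto the model", {
  des <- study_design(dose_levels = c(5, 500), protocols = "weekly",
                      sacrifice_days = 41, rats_per_cell = 2,
                      bw_sd = 0, growth_sd = 0, liver_ratio_sd = 0)
  pop <- population_params(
    sigma_v0 = setNames(rep(1e-12, 6),
                        names(population_params()$mu_v0)),
    sigma_err = c(plasma = 0, liver = 0, fat = 0))
  st <- generate_population(des, pop, seed = 3)
  # same-cell rats are identical
  split_cells <- split(st$observations,
                       st$design$dose_level[match(
                         st$observations$rat_id, st$design$rat_id)])
  for (cell in split_cells) {
    per_rat <- split(cell$concentration, cell$rat_id)
    expect_equal(per_rat[[1]], per_rat[[2]], ignore_attr = TRUE)
  }
  # observations equal noise-free predictions
  pvo <- predicted_vs_observed(st)
  expect_equal(pvo$table$observed, pvo$table$predicted,
               tolerance = 1e-9)
})

test_that("sampled clearances converge to the population lognormal", {
  # 10,000 rats through the cheapest design cell
  des <- study_design(dose_levels = 5, protocols = "weekly",
                      sacrifice_days = 41, rats_per_cell = 10000)
  st <- generate_population(des, seed = 8)
  lv <- log(st$true_params$v0)
  pop <- st$true_params$pop
  for (k in colnames(lv)) {
    expect_equal(mean(lv[, k]), pop$mu_v0[[k]], tolerance = 0.02)
    expect_equal(sd(lv[, k]), pop$sigma_v0[[k]], tolerance = 0.02)
  }
})

test_that("log residuals against noise-free predictions are the
           stipulated Normal noise", {
  des <- study_design(dose_levels = c(5, 50), protocols = "weekly",
                      sacrifice_days = c(41, 90), rats_per_cell = 15)
  st <- generate_population(des, seed = 21)
  pvo <- predicted_vs_observed(st)
  pop <- st$true_params$pop
  z <- pvo$table$log_resid / pop$sigma_err[pvo$table$tissue]
  expect_gt(shapiro.test(z)$p.value, 1e-3)
  expect_lt(abs(mean(z)), 0.1)
  expect_equal(sd(z), 1, tolerance = 0.1)
  for (tis in names(pvo$residual_sd))
    expect_equal(unname(pvo$residual_sd[tis]),
                 unname(pop$sigma_err[tis]), tolerance = 0.25)
})

test_that("studies round-trip through delimited text", {
  st <- subset_study(small_study(), 1:3)
  dir <- withr::local_tempdir()
  paths <- write_study(st, dir)
  back <- read_study(paths["design"], paths["observations"],
                     paths["true_v0"])
  expect_equal(back$design, st$design, tolerance = 1e-11)
  expect_equal(back$observations, st$observations, tolerance = 1e-11)
  expect_equal(back$true_params$v0, st$true_params$v0,
               tolerance = 1e-11, ignore_attr = TRUE)

  # empty study writes header-only files
  empty <- subset_study(small_study(), integer(0))
  p2 <- write_study(empty, dir, prefix = "empty")
  expect_equal(length(readLines(p2[["design"]])), 1L)
  rt <- read_study(p2["design"], p2["observations"])
  expect_equal(nrow(rt$observations), 0L)
})

test_that("malformed tables fail with named parse errors", {
  st <- subset_study(small_study(), 1:2)
  dir <- withr::local_tempdir()
  paths <- write_study(st, dir)
  des <- read.delim(paths[["design"]])
  des$protocol <- NULL
  write.table(des, file.path(dir, "bad.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  expect_error(read_study(file.path(dir, "bad.tsv"),
                          paths["observations"]), "protocol")
  obs <- read.delim(paths[["observations"]])
  obs$concentration[2] <- "not-a-number"
  write.table(obs, file.path(dir, "badobs.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  expect_error(read_study(paths["design"],
                          file.path(dir, "badobs.tsv")),
               "row 2.*concentration")
})
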