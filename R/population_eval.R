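#' Posterior-predictive Monte-Carlo population simulation
#'
#' Samples per-rat basal clearances from the calibrated lognormal
#' population distribution (median population \code{mu} and
#' \code{sigma}), simulates each sampled rat through a design cell, and
#' summarizes the resulting total-lipid concentration time courses as
#' pointwise median and 95\% bands per tissue and congener.  Induction
#' factors are held at their posterior medians (no inter-individual
#' variation).
#'
#' @param pop A \code{\link{population_params}} (e.g. the \code{pop}
#'   component of a \code{\link{calibrate_two_step}} fit).
#' @param dose_level Dose per congener per event (\eqn{\mu}g/kg).
#' @param protocol Protocol label (see \code{\link{build_schedule}}).
#' @param sacrifice_day Simulation horizon (days).
#' @param n_draws Number of Monte-Carlo rats (>= 2).
#' @param seed Integer seed.
#' @param t_grid Output times (h); default daily.
#' @param phys,congeners,cyp Model context.
#' @param control Solver controls.
#' @return Object of class \code{population_run}: \code{times},
#'   \code{bands} (array time x tissue x congener x
#'   \{lower, median, upper\}), draw counts and the design cell.
#' @export
monte_carlo_population <- function(pop, dose_level, protocol,
                                   sacrifice_day = 90, n_draws = 1000,
                                   seed = 1L, t_grid = NULL,
                                   phys = scale_to_nle(
                                     conventional_physiology(),
                                     lipid_content()),
                                   congeners = pcb_mixture(),
                                   cyp = induction_params(),
                                   control = list()) {
  stopifnot(inherits(pop, "population_params"), n_draws >= 2)
  if (is.null(t_grid)) t_grid <- seq(0, sacrifice_day * 24, by = 24)
  sched <- build_schedule(protocol, dose_level, sacrifice_day)
  cov <- mean_rat_covariates(sacrifice_day)
  p <- induction_params(ke = cyp$ke, k0 = cyp$k0, A0 = cyp$A0,
                        F_1A = pop$F_1A, F_2B = pop$F_2B)
  ks <- congeners$congener
  set.seed(seed)
  draws <- matrix(NA_real_, n_draws, length(ks),
                  dimnames = list(NULL, ks))
  for (k in ks)
    draws[, k] <- rlnorm(n_draws, pop$mu_v0[[k]], pop$sigma_v0[[k]])
  sims <- vector("list", n_draws)
  failed <- 0L
  for (d in seq_len(n_draws)) {
    mix <- pcb_mixture(v0 = setNames(draws[d, ], ks))
    sims[[d]] <- tryCatch(
      simulate_rat(phys, mix, p, sched, cov, t_grid = t_grid,
                   control = control)$conc_tl,
      error = function(e) NULL)
    if (is.null(sims[[d]])) failed <- failed + 1L
  }
  if (failed > 0)
    warning("monte_carlo_population: ", failed, " of ", n_draws,
            " draws failed and were dropped", call. = FALSE)
  sims <- sims[!vapply(sims, is.null, logical(1))]
  if (!length(sims))
    stop("monte_carlo_population: no draw simulated successfully",
         call. = FALSE)
  arr <- simplify2array(sims)     # time x tissue x congener x draw
  bands <- apply(arr, 1:3, quantile, probs = c(0.025, 0.5, 0.975),
                 names = FALSE)
  bands <- aperm(bands, c(2, 3, 4, 1))
  dimnames(bands) <- c(dimnames(sims[[1]]),
                       list(c("lower", "median", "upper")))
  structure(list(times = t_grid, bands = bands,
                 n_draws = n_draws, n_failed = failed,
                 dose_level = dose_level, protocol = protocol,
                 pop = pop),
            class = "population_run")
}

# Mean covariates of the synthetic population: 225 g at start, growing
# linearly to 1.6x by day 90, liver 4% of body weight.
mean_rat_covariates <- function(sacrifice_day, bw0 = 225,
                                growth_90 = 1.6, liver_ratio = 0.04) {
  bw_final <- bw0 + (bw0 * growth_90 - bw0) * sacrifice_day / 90
  rat_covariates(bw0, bw_final, sacrifice_day, liver_ratio)
}

#' @export
print.population_run <- function(x, ...) {
  cat("Monte-Carlo population run: ", x$n_draws - x$n_failed,
      " draws (", x$n_failed, " failed), ", x$dose_level,
      " ug/kg ", x$protocol, "\n", sep = "")
  invisible(x)
}

#' Induction-ratio trajectory of the median-parameter rat
#'
#' Simulates the deterministic rat with median population parameters
#' through a design cell and reports the CYP amount relative to baseline
#' (equivalently induced/basal clearance, since clearance is
#' proportional to \eqn{A/A_0}) for both enzymes over time, together
#' with the terminal and maximum factors.
#'
#' @inheritParams monte_carlo_population
#' @param horizon_days Simulation horizon (days).
#' @return Data frame of class \code{induction_report} with columns
#'   \code{time_h}, \code{enzyme}, \code{ratio}; attributes
#'   \code{terminal} and \code{maximum} carry the named per-enzyme
#'   factors.
#' @export
induction_ratio_report <- function(pop, dose_level, protocol,
                                   horizon_days = 90,
                                   phys = scale_to_nle(
                                     conventional_physiology(),
                                     lipid_content()),
                                   congeners = pcb_mixture(),
                                   cyp = induction_params(),
                                   control = list()) {
  stopifnot(inherits(pop, "population_params"))
  mix <- pcb_mixture(v0 = setNames(exp(unlist(pop$mu_v0)),
                                   names(pop$mu_v0)))
  p <- induction_params(ke = cyp$ke, k0 = cyp$k0, A0 = cyp$A0,
                        F_1A = pop$F_1A, F_2B = pop$F_2B)
  sched <- build_schedule(protocol, dose_level, horizon_days)
  cov <- mean_rat_covariates(horizon_days)
  t_grid <- seq(0, horizon_days * 24, by = 24)
  sim <- simulate_rat(phys, mix, p, sched, cov, t_grid = t_grid,
                      control = control)
  out <- data.frame(
    time_h = rep(t_grid, 2),
    enzyme = rep(c("CYP1A", "CYP2B"), each = length(t_grid)),
    ratio = c(sim$cyp_ratio[, "CYP1A"], sim$cyp_ratio[, "CYP2B"]))
  n <- length(t_grid)
  attr(out, "terminal") <- c(CYP1A = unname(sim$cyp_ratio[n, "CYP1A"]),
                             CYP2B = unname(sim$cyp_ratio[n, "CYP2B"]))
  attr(out, "maximum") <- c(CYP1A = max(sim$cyp_ratio[, "CYP1A"]),
                            CYP2B = max(sim$cyp_ratio[, "CYP2B"]))
  class(out) <- c("induction_report", "data.frame")
  out
}

#' @export
print.induction_report <- function(x, ...) {
  tr <- attr(x, "terminal"); mx <- attr(x, "maximum")
  cat("clearance-increase factors (A/A0):\n")
  cat(sprintf("  CYP1A (PCB 118):     terminal %.2f, maximum %.2f\n",
              tr["CYP1A"], mx["CYP1A"]))
  cat(sprintf("  CYP2B (multi-ortho): terminal %.2f, maximum %.2f\n",
              tr["CYP2B"], mx["CYP2B"]))
  invisible(x)
}

#' Predicted-versus-observed evaluation
#'
#' Simulates every rat of a study at supplied per-rat clearances (for
#' example the true synthetic values, or per-rat posterior medians) and
#' tabulates observed against predicted concentrations, with per-tissue
#' log-residual statistics and per-congener/tissue mean log residuals
#' for detecting systematic over- or underprediction.
#'
#' @param study A \code{pcb_study}.
#' @param v0_individual Matrix of per-rat clearances (rows in design
#'   order, columns named by congener); defaults to the study's stored
#'   true values.
#' @param F_1A,F_2B Induction factors used in the simulations.
#' @param phys,congeners,cyp,control Model context.
#' @return List of class \code{pvo}: \code{table} (rat_id, congener,
#'   tissue, observed, predicted), \code{residual_sd} (per tissue, log
#'   scale), \code{offsets} (per congener x tissue mean log residual).
#' @export
predicted_vs_observed <- function(study, v0_individual = NULL,
                                  F_1A = NULL, F_2B = NULL,
                                  phys = scale_to_nle(
                                    conventional_physiology(),
                                    lipid_content()),
                                  congeners = pcb_mixture(),
                                  cyp = induction_params(),
                                  control = list(h0 = 0.01, hmax = 3)) {
  stopifnot(inherits(study, "pcb_study"))
  if (is.null(v0_individual)) {
    v0_individual <- study$true_params$v0
    if (is.null(v0_individual))
      stop("predicted_vs_observed: no per-rat clearances supplied and ",
           "the study stores no true values", call. = FALSE)
  }
  if (is.null(F_1A)) F_1A <- study$true_params$pop$F_1A
  if (is.null(F_2B)) F_2B <- study$true_params$pop$F_2B
  if (is.null(F_1A) || is.null(F_2B))
    stop("predicted_vs_observed: induction factors are required",
         call. = FALSE)
  if (nrow(study$observations) == 0)
    return(structure(list(
      table = data.frame(rat_id = character(), congener = character(),
                         tissue = character(), observed = numeric(),
                         predicted = numeric()),
      residual_sd = numeric(0),
      offsets = data.frame()), class = "pvo"))
  if (nrow(v0_individual) != nrow(study$design))
    stop("predicted_vs_observed: v0_individual must have one row per ",
         "rat in the design", call. = FALSE)
  ctx <- sim_context(study, phys, congeners, cyp, control)
  tabs <- vector("list", length(ctx$rats))
  for (i in seq_along(ctx$rats)) {
    lp <- predict_rat(ctx, i, v0_individual[i, ctx$congeners],
                      F_1A, F_2B)
    tabs[[i]] <- data.frame(
      rat_id = ctx$rats[[i]]$rat_id,
      congener = ctx$rats[[i]]$congener,
      tissue = ctx$rats[[i]]$tissue,
      observed = exp(ctx$rats[[i]]$log_obs),
      predicted = exp(lp),
      log_resid = ctx$rats[[i]]$log_obs - lp,
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, tabs)
  rownames(tab) <- NULL
  residual_sd <- tapply(tab$log_resid, tab$tissue, sd)
  offs <- aggregate(log_resid ~ congener + tissue, data = tab,
                    FUN = mean)
  names(offs)[names(offs) == "log_resid"] <- "mean_log_resid"
  structure(list(table = tab[, c("rat_id", "congener", "tissue",
                                 "observed", "predicted", "log_resid")],
                 residual_sd = residual_sd, offsets = offs),
            class = "pvo")
}

#' @export
print.pvo <- function(x, ...) {
  cat("predicted vs observed: ", nrow(x$table), " pairs\n", sep = "")
  if (length(x$residual_sd)) {
    cat("  log-residual SD per tissue:\n")
    print(signif(x$residual_sd, 3))
  }
  invisible(x)
}
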