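#' MCMC settings for the population calibration
#'
#' @param n_iter Iterations per chain (per step).
#' @param n_chains Number of independent chains (over-dispersed starts).
#' @param burn_in_frac Fraction of iterations discarded as burn-in (the
#'   adaptation window).
#' @param target_acceptance Blockwise acceptance rate the proposal
#'   adaptation aims for (about 10\% suits this high-dimensional system).
#' @param seed Base integer seed; chain \eqn{c} uses \code{seed + c}.
#' @param thin Keep every \code{thin}-th iteration.
#' @param control ODE solver controls used during calibration
#'   (see \code{\link{sim_context}}).
#' @param scales Named initial proposal SDs per block kind:
#'   \code{pop}, \code{rat}, \code{error}, \code{induction}.
#' @return List of class \code{mcmc_settings}.
#' @export
mcmc_settings <- function(n_iter = 10000, n_chains = 3,
                          burn_in_frac = 0.4, target_acceptance = 0.1,
                          seed = 1L, thin = 1L,
                          control = list(h0 = 0.1, hmax = 24),
                          scales = c(pop = 0.1, rat = 0.3, error = 0.15,
                                     induction = 0.3)) {
  stopifnot(n_iter >= 1, n_chains >= 1, burn_in_frac >= 0,
            burn_in_frac < 1, target_acceptance > 0,
            target_acceptance < 1)
  structure(list(n_iter = as.integer(n_iter),
                 n_chains = as.integer(n_chains),
                 burn_in_frac = burn_in_frac,
                 target_acceptance = target_acceptance,
                 seed = as.integer(seed), thin = as.integer(thin),
                 control = control, scales = scales),
            class = "mcmc_settings")
}

# ---------------------------------------------------------------------
# Internal: cached hierarchical target for one calibration stage.
#
# Sampling scale: population means mu_k are sampled directly (they are
# already log-clearances); sigma_v0, per-rat v0, the error SDs and the
# induction factors are sampled as logs with the Jacobian included in
# the prior term.  The likelihood cache holds per-rat log-residual
# vectors, so a block update recomputes only what it touched:
#   pop block  - prior only, no simulation;
#   rat block  - one compiled ODE solve;
#   error block- reweighting of cached residuals, no simulation;
#   F block    - (stage 2) re-simulation of every rat.
make_hier_target <- function(stage, study, ctx, priors,
                             pooled = FALSE, pop_fixed = NULL) {
  ks <- ctx$congeners
  nk <- length(ks)
  nrat <- length(ctx$rats)
  tissues3 <- c("plasma", "liver", "fat")
  sig_idx <- lapply(ctx$rats, function(r) match(r$tissue, tissues3))

  # --- theta layout
  npop <- if (pooled) 1L else nk
  pop_names <- if (pooled) "all" else ks
  if (stage == 1) {
    idx_mu <- seq_len(npop)
    idx_lsig <- npop + seq_len(npop)
    off <- 2L * npop
    idx_F <- integer(0)
  } else {
    idx_F <- 1:2
    off <- 2L
    idx_mu <- idx_lsig <- integer(0)
  }
  idx_v0 <- matrix(off + seq_len(nrat * nk), nrat, nk, byrow = TRUE)
  off <- off + nrat * nk
  idx_serr <- off + 1:3
  nm <- character(off + 3)
  if (stage == 1) {
    nm[idx_mu] <- paste0("mu_", pop_names)
    nm[idx_lsig] <- paste0("lsigma_", pop_names)
  } else {
    nm[idx_F] <- c("lF_1A", "lF_2B")
  }
  for (i in seq_len(nrat))
    nm[idx_v0[i, ]] <- paste0("lv0_", ctx$rat_ids[i], "_", ks)
  nm[idx_serr] <- paste0("lserr_", tissues3)

  # --- blocks
  blocks <- list(); kinds <- character(0); rat_of <- integer(0)
  if (stage == 1) {
    for (j in seq_len(npop)) {
      blocks <- c(blocks, list(c(idx_mu[j], idx_lsig[j])))
      kinds <- c(kinds, "pop"); rat_of <- c(rat_of, NA_integer_)
    }
  } else {
    blocks <- c(blocks, list(idx_F))
    kinds <- c(kinds, "induction"); rat_of <- c(rat_of, NA_integer_)
  }
  for (i in seq_len(nrat)) {
    blocks <- c(blocks, list(idx_v0[i, ]))
    kinds <- c(kinds, "rat"); rat_of <- c(rat_of, i)
  }
  blocks <- c(blocks, list(idx_serr))
  kinds <- c(kinds, "error"); rat_of <- c(rat_of, NA_integer_)

  lb_mu <- log(priors$mu_v0_bounds)
  lF_max <- log(priors$F_bounds[2])
  lse_b <- log(priors$sigma_err_bounds)
  ig <- priors$sigma_v0_ig
  on_sd <- priors$sigma_v0_parameterization == "sd"
  kcol <- if (pooled) rep(1L, nk) else seq_len(nk)

  log_prior_theta <- function(theta) {
    lserr <- theta[idx_serr]
    if (any(lserr < lse_b[1] | lserr > lse_b[2])) return(-Inf)
    lp <- sum(lserr)                       # Jacobian of log transform
    if (stage == 1) {
      mu <- theta[idx_mu]
      if (any(mu < lb_mu[1] | mu > lb_mu[2])) return(-Inf)
      lsig <- theta[idx_lsig]
      sig <- exp(lsig)
      igterm <- if (on_sd) ldinvgamma(sig, ig["shape"], ig["scale"])
        else ldinvgamma(sig^2, ig["shape"], ig["scale"]) + log(2 * sig)
      lp <- lp + sum(igterm) + sum(lsig)
    } else {
      lF <- theta[idx_F]
      if (any(lF > lF_max)) return(-Inf)
      lp <- lp + sum(lF)
      mu <- pop_fixed$mu_v0
      sig <- pop_fixed$sigma_v0
    }
    for (j in seq_len(nk)) {
      mj <- if (stage == 1) mu[kcol[j]] else mu[[ks[j]]]
      sj <- if (stage == 1) sig[kcol[j]] else sig[[ks[j]]]
      lp <- lp + sum(dnorm(theta[idx_v0[, j]], mj, sj, log = TRUE))
    }
    lp
  }

  # --- likelihood cache
  e <- new.env(parent = emptyenv())
  e$resid <- vector("list", nrat)
  e$ll <- numeric(nrat)
  e$sigma <- rep(NA_real_, 3)
  e$prop <- NULL

  sim_resid <- function(theta, i) {
    v0 <- exp(theta[idx_v0[i, ]])
    F1A <- if (stage == 1) 0 else exp(theta[idx_F[1]])
    F2B <- if (stage == 1) 0 else exp(theta[idx_F[2]])
    ctx$rats[[i]]$log_obs - predict_rat(ctx, i, v0, F1A, F2B)
  }
  ll_of <- function(resid, i, sigma)
    sum(dnorm(resid, 0, sigma[sig_idx[[i]]], log = TRUE))

  init <- function(theta) {
    e$sigma <- exp(theta[idx_serr])
    for (i in seq_len(nrat)) {
      e$resid[[i]] <- sim_resid(theta, i)
      e$ll[i] <- ll_of(e$resid[[i]], i, e$sigma)
    }
    e$prop <- NULL
    log_prior_theta(theta) + sum(e$ll)
  }
  propose <- function(theta, b) {
    e$prop <- NULL
    lp <- log_prior_theta(theta)
    if (!is.finite(lp)) return(-Inf)
    kind <- kinds[b]
    if (kind == "pop") {
      lp + sum(e$ll)
    } else if (kind == "rat") {
      i <- rat_of[b]
      r <- sim_resid(theta, i)
      lli <- ll_of(r, i, e$sigma)
      e$prop <- list(kind = "rat", i = i, resid = r, ll = lli)
      lp + sum(e$ll) - e$ll[i] + lli
    } else if (kind == "error") {
      sg <- exp(theta[idx_serr])
      lln <- vapply(seq_len(nrat),
                    function(i) ll_of(e$resid[[i]], i, sg), numeric(1))
      e$prop <- list(kind = "error", sigma = sg, ll = lln)
      lp + sum(lln)
    } else {                       # induction factors: all rats affected
      rs <- lapply(seq_len(nrat), function(i) sim_resid(theta, i))
      lln <- vapply(seq_len(nrat),
                    function(i) ll_of(rs[[i]], i, e$sigma), numeric(1))
      e$prop <- list(kind = "all", resid = rs, ll = lln)
      lp + sum(lln)
    }
  }
  accept <- function() {
    p <- e$prop
    if (is.null(p)) return(invisible(NULL))
    if (p$kind == "rat") {
      e$resid[[p$i]] <- p$resid
      e$ll[p$i] <- p$ll
    } else if (p$kind == "error") {
      e$sigma <- p$sigma
      e$ll <- p$ll
    } else {
      e$resid <- p$resid
      e$ll <- p$ll
    }
    e$prop <- NULL
    invisible(NULL)
  }
  reject <- function() {
    e$prop <- NULL
    invisible(NULL)
  }

  list(target = list(init = init, propose = propose, accept = accept,
                     reject = reject),
       names = nm, blocks = blocks, kinds = kinds,
       idx = list(mu = idx_mu, lsig = idx_lsig, F = idx_F, v0 = idx_v0,
                  serr = idx_serr),
       pooled = pooled, pop_names = pop_names)
}

# Over-dispersed initial state for one chain (uses the current RNG
# stream).  Initials are drawn from the priors, with the heavy
# inverse-gamma tail clamped to a workable range.
draw_init <- function(layout, stage, priors, pop_fixed = NULL) {
  nm <- layout$names
  theta <- setNames(numeric(length(nm)), nm)
  lse_b <- log(priors$sigma_err_bounds)
  if (stage == 1) {
    lb <- log(priors$mu_v0_bounds)
    npop <- length(layout$idx$mu)
    mu <- runif(npop, lb[1], lb[2])
    sig <- pmin(pmax(1 / rgamma(npop, priors$sigma_v0_ig["shape"],
                                rate = priors$sigma_v0_ig["scale"]),
                     0.1), 1.5)
    theta[layout$idx$mu] <- mu
    theta[layout$idx$lsig] <- log(sig)
  } else {
    theta[layout$idx$F] <- runif(2, log(1e-4),
                                 log(priors$F_bounds[2]))
    mu <- pop_fixed$mu_v0
    sig <- pop_fixed$sigma_v0
  }
  nrat <- nrow(layout$idx$v0)
  nk <- ncol(layout$idx$v0)
  for (j in seq_len(nk)) {
    mj <- if (stage == 1) mu[if (layout$pooled) 1 else j] else mu[[j]]
    sj <- if (stage == 1) sig[if (layout$pooled) 1 else j] else
      sig[[j]]
    theta[layout$idx$v0[, j]] <- rnorm(nrat, mj, min(2 * sj, 1))
  }
  theta[layout$idx$serr] <- runif(3, log(0.05), log(1.5))
  theta
}

run_stage <- function(stage, study, ctx, priors, settings,
                      pooled = FALSE, pop_fixed = NULL,
                      verbose = FALSE) {
  chains <- vector("list", settings$n_chains)
  layout <- NULL
  for (c in seq_len(settings$n_chains)) {
    lay <- make_hier_target(stage, study, ctx, priors, pooled,
                            pop_fixed)
    layout <- lay
    set.seed(settings$seed + c)
    init <- draw_init(lay, stage, priors, pop_fixed)
    scales <- unname(settings$scales[lay$kinds])
    chains[[c]] <- metropolis_run(
      lay$target, init, n_iter = settings$n_iter, blocks = lay$blocks,
      scales = scales,
      target_acceptance = settings$target_acceptance,
      burn_in = floor(settings$burn_in_frac * settings$n_iter),
      adapt = TRUE, seed = NULL, thin = settings$thin)
    if (verbose)
      message("  stage ", stage, " chain ", c, ": mean acceptance ",
              sprintf("%.2f", mean(chains[[c]]$acceptance)))
  }
  list(chains = chains, layout = layout)
}

# Pooled post-burn-in samples of one named parameter across chains.
pooled_samples <- function(chains, name) {
  unlist(lapply(chains, function(ch) chain_samples(ch)[, name]),
         use.names = FALSE)
}

# Summary row: median on the reporting scale, CV of per-chain medians,
# Gelman-Rubin on the sampling scale.
summarize_params <- function(chains, names_sampling, names_report,
                             transform = exp) {
  rhat <- if (length(chains) >= 2)
    gelman_rubin(lapply(chains, function(ch)
      chain_samples(ch)[, names_sampling, drop = FALSE]))
  else setNames(rep(NA_real_, length(names_sampling)), names_sampling)
  rows <- lapply(seq_along(names_sampling), function(j) {
    nmj <- names_sampling[j]
    meds <- vapply(chains, function(ch)
      transform(median(chain_samples(ch)[, nmj])), numeric(1))
    data.frame(parameter = names_report[j],
               median = transform(median(pooled_samples(chains, nmj))),
               cv = sd(meds) / mean(meds),
               rhat = unname(rhat[j]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Two-step hierarchical Bayesian calibration
#'
#' Calibrates the population PBTK/induction model by blockwise
#' random-walk Metropolis, decomposed into two steps because basal and
#' induced clearance are inherently non-identifiable from high-dose data
#' alone:
#' \enumerate{
#'   \item \strong{Basal clearances} - lowest-dose records only,
#'     induction switched off; samples the population means and SDs of
#'     log basal clearance, every per-rat clearance and the per-tissue
#'     error SDs.
#'   \item \strong{Induction factors} - higher-dose records only;
#'     per-rat clearances are still sampled but under the step-1
#'     population posteriors as fixed informative priors (population
#'     mean and variance are not updated), and the two induction slope
#'     factors (no inter-individual variation) plus the error SDs are
#'     estimated.
#' }
#' Each step runs several independent chains from over-dispersed starts;
#' convergence is judged by the Gelman-Rubin statistic.  If more than
#' 5\% of the step-2 per-rat clearance medians fall outside the 3-sigma
#' band of their step-1 population priors, a warning advises
#' re-optimizing the population parameters.
#'
#' @param study A \code{pcb_study} spanning low and high dose levels.
#' @param priors A \code{\link{prior_spec}}.
#' @param settings An \code{\link{mcmc_settings}}.
#' @param phys,congeners,cyp Model context (reference physiology,
#'   congener table, baseline CYP parameters).
#' @param verbose Print per-chain progress messages?
#' @return Object of class \code{pcb_calibration}: per-step chains and
#'   summaries, a combined \code{summary} table (parameter, median, CV
#'   of per-chain medians, Gelman-Rubin R), and \code{pop} - the
#'   calibrated \code{\link{population_params}} (step-1 clearance
#'   distributions, step-2 induction factors and error SDs).
#' @export
calibrate_two_step <- function(study, priors = prior_spec(),
                               settings = mcmc_settings(),
                               phys = scale_to_nle(
                                 conventional_physiology(),
                                 lipid_content()),
                               congeners = pcb_mixture(),
                               cyp = induction_params(),
                               verbose = FALSE) {
  stopifnot(inherits(study, "pcb_study"))
  doses <- sort(unique(study$design$dose_level))
  if (length(doses) < 2)
    stop("calibrate_two_step: study must span low and high dose levels",
         call. = FALSE)
  low <- doses[1]
  i_low <- which(study$design$dose_level == low)
  i_high <- which(study$design$dose_level > low)
  s_low <- subset_study(study, i_low)
  s_high <- subset_study(study, i_high)
  ks <- congeners$congener

  ctx1 <- sim_context(s_low, phys, congeners, cyp, settings$control)
  if (verbose) message("step 1: ", length(i_low), " low-dose rats")
  st1 <- run_stage(1, s_low, ctx1, priors, settings, verbose = verbose)

  mu_names <- paste0("mu_", ks)
  lsig_names <- paste0("lsigma_", ks)
  serr_names <- paste0("lserr_", c("plasma", "liver", "fat"))
  sum1 <- rbind(
    summarize_params(st1$chains, mu_names, paste0("v0_", ks)),
    summarize_params(st1$chains, lsig_names, paste0("sigma_v0_", ks)),
    summarize_params(st1$chains, serr_names,
                     paste0("sigma_", c("plasma", "liver", "fat"))))
  mu_hat <- setNames(vapply(mu_names, function(n)
    median(pooled_samples(st1$chains, n)), numeric(1)), ks)
  sig_hat <- setNames(vapply(lsig_names, function(n)
    exp(median(pooled_samples(st1$chains, n))), numeric(1)), ks)
  pop_fixed <- list(mu_v0 = as.list(setNames(mu_hat, ks)),
                    sigma_v0 = as.list(setNames(sig_hat, ks)))

  ctx2 <- sim_context(s_high, phys, congeners, cyp, settings$control)
  if (verbose) message("step 2: ", length(i_high), " high-dose rats")
  st2 <- run_stage(2, s_high, ctx2, priors, settings,
                   pop_fixed = pop_fixed, verbose = verbose)
  sum2 <- rbind(
    summarize_params(st2$chains, c("lF_1A", "lF_2B"),
                     c("F_1A", "F_2B")),
    summarize_params(st2$chains, serr_names,
                     paste0("sigma_", c("plasma", "liver", "fat"))))

  # per-rat clearances should stay consistent with their step-1 priors
  v0_names <- st2$layout$names[st2$layout$idx$v0]
  v0_med <- matrix(vapply(v0_names, function(n)
    median(pooled_samples(st2$chains, n)), numeric(1)),
    nrow = nrow(st2$layout$idx$v0))
  outside <- 0L
  for (j in seq_along(ks))
    outside <- outside + sum(abs(v0_med[, j] - mu_hat[j]) >
                               3 * sig_hat[j])
  frac_out <- outside / length(v0_med)
  if (frac_out > 0.05)
    warning("calibrate_two_step: ", round(100 * frac_out, 1),
            "% of per-rat clearances sit outside their step-1 ",
            "population priors; re-optimize the population parameters",
            call. = FALSE)

  F_hat <- exp(c(median(pooled_samples(st2$chains, "lF_1A")),
                 median(pooled_samples(st2$chains, "lF_2B"))))
  serr_hat <- setNames(vapply(serr_names, function(n)
    exp(median(pooled_samples(st2$chains, n))), numeric(1)),
    c("plasma", "liver", "fat"))
  pop <- population_params(mu_v0 = mu_hat, sigma_v0 = sig_hat,
                           F_1A = F_hat[1], F_2B = F_hat[2],
                           sigma_err = serr_hat)
  summary <- rbind(cbind(step = 1L, sum1), cbind(step = 2L, sum2))
  rownames(summary) <- NULL
  structure(list(step1 = list(chains = st1$chains, summary = sum1,
                              layout = st1$layout),
                 step2 = list(chains = st2$chains, summary = sum2,
                              layout = st2$layout,
                              frac_outside_prior = frac_out,
                              v0_medians = v0_med),
                 summary = summary, pop = pop,
                 priors = priors, settings = settings),
            class = "pcb_calibration")
}

#' @export
print.pcb_calibration <- function(x, digits = 3, ...) {
  cat("Two-step hierarchical PBTK calibration\n")
  s <- x$summary
  s$median <- signif(s$median, digits)
  s$cv <- signif(s$cv, 2)
  s$rhat <- signif(s$rhat, 3)
  print(s, row.names = FALSE)
  invisible(x)
}

#' Pooled basal-clearance variant
#'
#' Step-1 analysis with a single population distribution shared by all
#' six congeners (one \code{mu}, one \code{sigma} for the consolidated
#' clearance), as a condensed description of the mixture's basal
#' metabolism.
#'
#' @inheritParams calibrate_two_step
#' @return List of class \code{pcb_pooled_fit} with \code{chains},
#'   \code{summary} and the pooled population \code{mu}/\code{sigma}
#'   medians.
#' @export
pooled_v0_variant <- function(study, priors = prior_spec(),
                              settings = mcmc_settings(),
                              phys = scale_to_nle(
                                conventional_physiology(),
                                lipid_content()),
                              congeners = pcb_mixture(),
                              cyp = induction_params(),
                              verbose = FALSE) {
  stopifnot(inherits(study, "pcb_study"))
  low <- min(study$design$dose_level)
  s_low <- subset_study(study, which(study$design$dose_level == low))
  ctx <- sim_context(s_low, phys, congeners, cyp, settings$control)
  st <- run_stage(1, s_low, ctx, priors, settings, pooled = TRUE,
                  verbose = verbose)
  serr_names <- paste0("lserr_", c("plasma", "liver", "fat"))
  summary <- rbind(
    summarize_params(st$chains, "mu_all", "v0_all"),
    summarize_params(st$chains, "lsigma_all", "sigma_v0_all"),
    summarize_params(st$chains, serr_names,
                     paste0("sigma_", c("plasma", "liver", "fat"))))
  structure(list(chains = st$chains, summary = summary,
                 layout = st$layout,
                 mu = median(pooled_samples(st$chains, "mu_all")),
                 sigma = exp(median(pooled_samples(st$chains,
                                                   "lsigma_all")))),
            class = "pcb_pooled_fit")
}
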