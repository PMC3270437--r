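#' Population parameters of the hierarchical model
#'
#' Container for the population-level quantities the calibration
#' estimates, also used as generating truth by the synthetic-study
#' generator.  Per-congener basal clearances are lognormal:
#' \code{mu_v0} is the mean of log v0 (natural log; so \code{exp(mu_v0)}
#' is the population median clearance in mL/h/kg^0.75) and
#' \code{sigma_v0} the SD of log v0.  Measurement error is lognormal with
#' per-tissue log-scale SD \code{sigma_err}.  Defaults are the package's
#' reference population calibration medians.
#'
#' @param mu_v0 Named (per congener) mean of log basal clearance.
#' @param sigma_v0 Named per-congener SD of log basal clearance.
#' @param F_1A,F_2B Induction slope factors (no inter-individual
#'   variation).
#' @param sigma_err Named per-tissue (plasma, liver, fat) log-scale error
#'   SD.
#' @return Object of class \code{population_params}.
#' @export
population_params <- function(
    mu_v0 = log(c(`118` = 0.038, `138` = 0.026, `153` = 0.025,
                  `170` = 0.029, `180` = 0.035, `187` = 0.017)),
    sigma_v0 = c(`118` = 0.24, `138` = 0.35, `153` = 0.35, `170` = 0.38,
                 `180` = 0.31, `187` = 0.55),
    F_1A = 0.045, F_2B = 0.0025,
    sigma_err = c(plasma = 0.19, liver = 0.40, fat = 0.30)) {
  congeners <- c("118", "138", "153", "170", "180", "187")
  if (!setequal(names(mu_v0), congeners) ||
      !setequal(names(sigma_v0), congeners))
    stop("population_params: mu_v0 and sigma_v0 must be named by the six ",
         "congeners", call. = FALSE)
  if (!setequal(names(sigma_err), c("plasma", "liver", "fat")))
    stop("population_params: sigma_err must name plasma, liver, fat",
         call. = FALSE)
  if (any(sigma_v0 < 0) || any(sigma_err < 0) || F_1A < 0 || F_2B < 0)
    stop("population_params: SDs and induction factors must be ",
         "nonnegative", call. = FALSE)
  structure(list(mu_v0 = mu_v0[congeners], sigma_v0 = sigma_v0[congeners],
                 F_1A = F_1A, F_2B = F_2B,
                 sigma_err = sigma_err[c("plasma", "liver", "fat")]),
            class = "population_params")
}

#' Factorial study design
#'
#' Defines the design frame of a rat study: the crossing of dose levels,
#' dose protocols and sacrifice days, with a fixed number of rats per
#' cell.  The defaults reproduce the reference study frame: 3 dose levels
#' (5, 50, 500 \eqn{\mu}g/kg per congener) x 4 protocols x sacrifice at
#' 41 or 90 days, 6 rats per cell (144 rats; the original in vivo study
#' had approximately six per cell, 142 in total).
#'
#' Body-weight and liver-weight generation parameters are part of the
#' design: initial body weight is Normal(\code{bw_mean}, \code{bw_sd})
#' truncated positive, body weight grows linearly to
#' Normal(\code{growth_mean}, \code{growth_sd}) times the initial weight
#' by day 90, and the liver-weight ratio is
#' Normal(\code{liver_ratio_mean}, \code{liver_ratio_sd}) truncated to
#' (0, 0.1).
#'
#' @param dose_levels Dose per congener per event (\eqn{\mu}g/kg).
#' @param protocols Protocol labels (see \code{\link{build_schedule}}).
#' @param sacrifice_days Days of sacrifice.
#' @param rats_per_cell Rats per design cell.
#' @param bw_mean,bw_sd Initial body weight distribution (g).
#' @param growth_mean,growth_sd Day-90 growth factor distribution.
#' @param liver_ratio_mean,liver_ratio_sd Liver-weight ratio distribution.
#' @return Object of class \code{study_design}.
#' @export
study_design <- function(dose_levels = c(5, 50, 500),
                         protocols = study_protocols(),
                         sacrifice_days = c(41, 90),
                         rats_per_cell = 6,
                         bw_mean = 225, bw_sd = 15,
                         growth_mean = 1.6, growth_sd = 0.1,
                         liver_ratio_mean = 0.04,
                         liver_ratio_sd = 0.004) {
  stopifnot(length(dose_levels) >= 1, length(protocols) >= 1,
            length(sacrifice_days) >= 1, rats_per_cell >= 1)
  bad <- setdiff(protocols, c(study_protocols(), "custom"))
  if (length(bad))
    stop("study_design: unknown protocol(s) ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(dose_levels = dose_levels, protocols = protocols,
                 sacrifice_days = sacrifice_days,
                 rats_per_cell = rats_per_cell,
                 bw_mean = bw_mean, bw_sd = bw_sd,
                 growth_mean = growth_mean, growth_sd = growth_sd,
                 liver_ratio_mean = liver_ratio_mean,
                 liver_ratio_sd = liver_ratio_sd),
            class = "study_design")
}

rnorm_trunc <- function(n, mean, sd, lower = 0, upper = Inf) {
  out <- rnorm(n, mean, sd)
  bad <- which(out <= lower | out >= upper)
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] <= lower | out[bad] >= upper]
  }
  out
}

#' Generate a synthetic rat study
#'
#' Draws a population of rats from the hierarchical model, simulates each
#' rat through its design cell with the PBTK/induction model, and applies
#' lognormal measurement error to the tissue-lipid concentrations at
#' sacrifice.  Plasma and liver total-lipid concentrations are observed
#' for every rat; adipose (fat) concentrations only for rats sacrificed
#' at 90 days or later, mirroring the reference study.  True per-rat
#' clearances are stored alongside the observations.
#'
#' @param design A \code{\link{study_design}}.
#' @param pop A \code{\link{population_params}} used as generating truth.
#' @param seed Integer seed; the output is byte-identical for a fixed
#'   seed.
#' @param phys Reference \code{nle_physiology}.
#' @param congeners \code{\link{pcb_mixture}} table (structure only; the
#'   basal clearances are drawn from \code{pop}).
#' @param cyp Baseline CYP turnover parameters
#'   (\code{\link{induction_params}}; its \code{F} slots are replaced by
#'   the population values).
#' @param control Solver controls passed to \code{\link{simulate_rat}}.
#' @return Object of class \code{pcb_study}: list with data frames
#'   \code{design} (one row per rat) and \code{observations} (one row per
#'   rat x congener x tissue; concentrations in \eqn{\mu}g/mL total
#'   lipid), and \code{true_params} (per-rat \code{v0} matrix, the
#'   generating \code{pop}, the \code{seed}).
#' @export
generate_population <- function(design = study_design(),
                                pop = population_params(),
                                seed = 1L,
                                phys = scale_to_nle(
                                  conventional_physiology(),
                                  lipid_content()),
                                congeners = pcb_mixture(),
                                cyp = induction_params(),
                                control = list()) {
  stopifnot(inherits(design, "study_design"),
            inherits(pop, "population_params"))
  cells <- expand.grid(dose_level = design$dose_levels,
                       protocol = design$protocols,
                       sacrifice_day = design$sacrifice_days,
                       stringsAsFactors = FALSE)
  n_rat <- nrow(cells) * design$rats_per_cell
  cells <- cells[rep(seq_len(nrow(cells)), each = design$rats_per_cell), ]
  rownames(cells) <- NULL
  congener_ids <- congeners$congener
  p <- induction_params(ke = cyp$ke, k0 = cyp$k0, A0 = cyp$A0,
                        F_1A = pop$F_1A, F_2B = pop$F_2B)

  set.seed(seed)
  bw0 <- rnorm_trunc(n_rat, design$bw_mean, design$bw_sd)
  growth <- rnorm_trunc(n_rat, design$growth_mean, design$growth_sd)
  lwr <- rnorm_trunc(n_rat, design$liver_ratio_mean, design$liver_ratio_sd,
                     upper = 0.1)
  v0 <- matrix(NA_real_, n_rat, length(congener_ids),
               dimnames = list(NULL, congener_ids))
  for (k in congener_ids)
    v0[, k] <- rlnorm(n_rat, pop$mu_v0[[k]], pop$sigma_v0[[k]])

  des <- data.frame(rat_id = sprintf("rat%03d", seq_len(n_rat)),
                    cells,
                    bw_initial = bw0,
                    bw_final = bw0 + (bw0 * growth - bw0) *
                      cells$sacrifice_day / 90,
                    liver_weight_ratio = lwr,
                    stringsAsFactors = FALSE)

  obs_list <- vector("list", n_rat)
  for (i in seq_len(n_rat)) {
    d <- des[i, ]
    covi <- rat_covariates(d$bw_initial, d$bw_final, d$sacrifice_day,
                           d$liver_weight_ratio)
    sched <- build_schedule(d$protocol, d$dose_level, d$sacrifice_day)
    mix <- pcb_mixture(v0 = setNames(v0[i, ], congener_ids))
    sim <- simulate_rat(phys, mix, p, sched, covi,
                        t_grid = c(0, d$sacrifice_day * 24),
                        control = control)
    tissues <- if (d$sacrifice_day >= 90) c("plasma", "liver", "fat") else
      c("plasma", "liver")
    pred <- sim$conc_tl[2, tissues, , drop = FALSE]
    rows <- expand.grid(tissue = tissues, congener = congener_ids,
                        stringsAsFactors = FALSE)
    pred_v <- mapply(function(tis, k) pred[1, tis, k],
                     rows$tissue, rows$congener)
    noise <- exp(rnorm(nrow(rows), 0, pop$sigma_err[rows$tissue]))
    obs_list[[i]] <- data.frame(rat_id = d$rat_id,
                                congener = rows$congener,
                                tissue = rows$tissue,
                                concentration = pred_v * noise,
                                stringsAsFactors = FALSE)
  }
  obs <- do.call(rbind, obs_list)
  rownames(obs) <- NULL
  structure(list(design = des, observations = obs,
                 true_params = list(v0 = v0, pop = pop, seed = seed)),
            class = "pcb_study")
}

#' @export
print.pcb_study <- function(x, ...) {
  cat("synthetic PCB rat study: ", nrow(x$design), " rats, ",
      nrow(x$observations), " observations\n", sep = "")
  cat("  dose levels: ",
      paste(sort(unique(x$design$dose_level)), collapse = ", "),
      " ug/kg; protocols: ",
      paste(unique(x$design$protocol), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write a study to delimited-text tables
#'
#' Writes the design and observation tables (and, when present, the true
#' per-rat clearances) as tab-separated files with 12-significant-digit
#' numeric formatting, so that \code{\link{read_study}} round-trips the
#' study.
#'
#' @param study A \code{pcb_study}.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the named vector of file paths written.
#' @export
write_study <- function(study, dir, prefix = "study") {
  stopifnot(inherits(study, "pcb_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fmt <- function(df) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) signif(x, 12))
    df
  }
  paths <- c(design = file.path(dir, paste0(prefix, "_design.tsv")),
             observations = file.path(dir,
                                      paste0(prefix, "_observations.tsv")))
  write.table(fmt(study$design), paths[["design"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(fmt(study$observations), paths[["observations"]],
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(study$true_params$v0)) {
    v0 <- as.data.frame(signif(study$true_params$v0, 12))
    v0 <- cbind(rat_id = study$design$rat_id, v0)
    paths[["true_v0"]] <- file.path(dir, paste0(prefix, "_true_v0.tsv"))
    write.table(v0, paths[["true_v0"]], sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(paths)
}

#' Read a study from delimited-text tables
#'
#' @param design_file Path to the design table; required columns
#'   \code{rat_id}, \code{dose_level}, \code{protocol},
#'   \code{sacrifice_day}, \code{bw_initial}, \code{bw_final},
#'   \code{liver_weight_ratio}.
#' @param observations_file Path to the observation table; required
#'   columns \code{rat_id}, \code{congener}, \code{tissue},
#'   \code{concentration}.
#' @param true_v0_file Optional path to a true-clearance table
#'   (\code{rat_id} plus one column per congener).
#' @return A \code{pcb_study}.
#' @export
read_study <- function(design_file, observations_file,
                       true_v0_file = NULL) {
  read_checked <- function(path, required) {
    df <- read.delim(path, stringsAsFactors = FALSE,
                     colClasses = "character")
    missing <- setdiff(required, names(df))
    if (length(missing))
      stop("read_study: file '", path, "' is missing column(s) ",
           paste(missing, collapse = ", "), call. = FALSE)
    df
  }
  to_num <- function(df, cols, path) {
    for (cl in cols) {
      v <- suppressWarnings(as.numeric(df[[cl]]))
      if (anyNA(v)) {
        row <- which(is.na(v))[1]
        stop("read_study: non-numeric value in '", path, "', row ", row,
             ", column '", cl, "'", call. = FALSE)
      }
      df[[cl]] <- v
    }
    df
  }
  des <- read_checked(design_file,
                      c("rat_id", "dose_level", "protocol",
                        "sacrifice_day", "bw_initial", "bw_final",
                        "liver_weight_ratio"))
  des <- to_num(des, c("dose_level", "sacrifice_day", "bw_initial",
                       "bw_final", "liver_weight_ratio"), design_file)
  obs <- read_checked(observations_file,
                      c("rat_id", "congener", "tissue", "concentration"))
  obs <- to_num(obs, "concentration", observations_file)
  if (any(obs$concentration <= 0))
    stop("read_study: nonpositive concentration in '", observations_file,
         "', row ", which(obs$concentration <= 0)[1], call. = FALSE)
  true_params <- NULL
  if (!is.null(true_v0_file)) {
    tv <- read_checked(true_v0_file, "rat_id")
    ks <- setdiff(names(tv), "rat_id")
    tv <- to_num(tv, ks, true_v0_file)
    v0 <- as.matrix(tv[ks])
    colnames(v0) <- sub("^X", "", ks)
    true_params <- list(v0 = v0)
  }
  structure(list(design = des, observations = obs,
                 true_params = true_params),
            class = "pcb_study")
}
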