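#' Lipid content of rat tissues
#'
#' Reference neutral-lipid-equivalent (NLE) content of rat blood and
#' tissues.  The NLE space of a tissue is defined as all of its neutral
#' lipids plus 30\% of its phospholipids; highly lipophilic chemicals such
#' as PCBs are assumed to distribute exclusively in this space.  Two ratios
#' are carried per compartment: \code{nle_ratio}, the volume of NLE per
#' volume of whole tissue (mL NLE / mL tissue), and
#' \code{nle_per_total_lipid}, the volume of NLE per volume of total
#' extractable lipid (mL NLE / mL total lipid), used to convert model
#' concentrations to the measurable total-lipid basis.
#'
#' The printed blood NLE ratio (0.0019) carries only two significant
#' figures; the reference NLE flow table is consistent with a slightly
#' smaller value (9.45/4980 = 0.0018976).  The printed value is the
#' default; pass \code{blood_nle_ratio = 9.45/4980} to reproduce reference
#' flows to three figures.
#'
#' @param blood_nle_ratio NLE ratio of whole blood (mL NLE / mL blood).
#' @return A data frame with columns \code{tissue}, \code{nle_ratio} and
#'   \code{nle_per_total_lipid}, one row per compartment
#'   (\code{blood}, \code{plasma}, \code{fat}, \code{liver}, \code{rapid},
#'   \code{poor}).  \code{plasma} is not a flow compartment; its row is
#'   used only to convert blood NLE concentrations to plasma total-lipid
#'   concentrations.
#' @export
lipid_content <- function(blood_nle_ratio = 0.0019) {
  stopifnot(is.numeric(blood_nle_ratio), blood_nle_ratio > 0,
            blood_nle_ratio < 1)
  out <- data.frame(
    tissue             = c("blood", "plasma", "fat", "liver", "rapid", "poor"),
    nle_ratio          = c(blood_nle_ratio, 0.0009, 0.8536, 0.0425, 0.0425,
                           0.0120),
    nle_per_total_lipid = c(0.576, 0.748, 0.998, 0.710, 0.710, 0.632),
    stringsAsFactors   = FALSE
  )
  validate_lipid_content(out)
  out
}

validate_lipid_content <- function(x) {
  stopifnot(is.data.frame(x),
            all(c("tissue", "nle_ratio", "nle_per_total_lipid") %in% names(x)))
  if (any(x$nle_ratio <= 0 | x$nle_ratio >= 1))
    stop("lipid content: nle_ratio must lie in (0, 1)", call. = FALSE)
  if (any(x$nle_per_total_lipid <= 0 | x$nle_per_total_lipid > 1))
    stop("lipid content: nle_per_total_lipid must lie in (0, 1]",
         call. = FALSE)
  invisible(x)
}

#' Conventional physiology of a standard rat
#'
#' Whole-tissue blood flows and volumes for a standard 225 g rat, used as
#' the starting point for the lipid-basis (NLE) physiology.  Flows cover
#' the four perfused compartments (fat, liver, rapidly perfused, poorly
#' perfused); volumes additionally include blood.
#'
#' @param tissue_flows Named numeric vector of tissue blood flows
#'   (mL blood/h) for \code{fat}, \code{liver}, \code{rapid}, \code{poor}.
#' @param tissue_volumes Named numeric vector of tissue volumes (mL) for
#'   \code{blood}, \code{fat}, \code{liver}, \code{rapid}, \code{poor}.
#' @param cardiac_output Total cardiac output (mL blood/h).  Must equal the
#'   sum of the tissue flows to within 1\%.
#' @param reference_body_weight Body weight (g) at which the flows and
#'   volumes apply.
#' @return An object of class \code{conventional_physiology}.
#' @export
conventional_physiology <- function(
    tissue_flows = c(fat = 448, liver = 1245, rapid = 2540, poor = 747),
    tissue_volumes = c(blood = 20.0, fat = 17.5, liver = 10.0, rapid = 12.5,
                       poor = 167.5),
    cardiac_output = 4980,
    reference_body_weight = 225) {
  flows <- tissue_flows[c("fat", "liver", "rapid", "poor")]
  vols  <- tissue_volumes[c("blood", "fat", "liver", "rapid", "poor")]
  if (anyNA(flows))
    stop("conventional physiology: flows must name fat, liver, rapid, poor",
         call. = FALSE)
  if (anyNA(vols))
    stop("conventional physiology: volumes must name blood, fat, liver, ",
         "rapid, poor", call. = FALSE)
  if (any(flows <= 0) || any(vols <= 0) || cardiac_output <= 0 ||
      reference_body_weight <= 0)
    stop("conventional physiology: all entries must be positive",
         call. = FALSE)
  if (abs(sum(flows) - cardiac_output) > 0.01 * cardiac_output)
    stop("conventional physiology: tissue flows (", sum(flows),
         " mL/h) do not balance cardiac output (", cardiac_output,
         " mL/h) within 1%", call. = FALSE)
  structure(
    list(tissue_flows = flows, tissue_volumes = vols,
         cardiac_output = cardiac_output,
         reference_body_weight = reference_body_weight),
    class = "conventional_physiology")
}

#' Convert conventional physiology to the lipid (NLE) basis
#'
#' Builds the neutral-lipid-equivalent physiology in which the PBTK model
#' operates.  Each compartment volume is multiplied by its own NLE ratio;
#' all flows and the cardiac output are multiplied by the blood NLE ratio
#' (chemical is carried between compartments by blood lipid).  Total-lipid
#' volumes, used to express concentrations on the measurable basis, are
#' the NLE volumes divided by the tissue's NLE-per-total-lipid fraction.
#'
#' @param conv A \code{\link{conventional_physiology}} object.
#' @param lipids A lipid-content table as returned by
#'   \code{\link{lipid_content}}.
#' @return An object of class \code{nle_physiology} with components
#'   \code{nle_flows} (mL NLE/h; fat, liver, rapid, poor),
#'   \code{nle_volumes} (mL NLE; blood, fat, liver, rapid, poor),
#'   \code{total_lipid_volumes} (mL total lipid),
#'   \code{nle_cardiac_output} (mL NLE/h), \code{reference_body_weight}
#'   (g) and the \code{lipids} table used.
#' @examples
#' phys <- scale_to_nle(conventional_physiology(), lipid_content())
#' phys$nle_volumes[["fat"]]   # 14.938 mL NLE
#' phys$nle_volumes[["liver"]] # 0.425 mL NLE
#' @export
scale_to_nle <- function(conv, lipids = lipid_content()) {
  stopifnot(inherits(conv, "conventional_physiology"))
  validate_lipid_content(lipids)
  ratio <- function(tissue) {
    i <- match(tissue, lipids$tissue)
    if (is.na(i))
      stop("scale_to_nle: no lipid content entry for compartment '", tissue,
           "'", call. = FALSE)
    lipids$nle_ratio[i]
  }
  tl_frac <- function(tissue) {
    i <- match(tissue, lipids$tissue)
    lipids$nle_per_total_lipid[i]
  }
  blood_r <- ratio("blood")
  vols <- conv$tissue_volumes
  nle_volumes <- vapply(names(vols),
                        function(t) vols[[t]] * ratio(t), numeric(1))
  total_lipid_volumes <- vapply(names(vols),
                                function(t) nle_volumes[[t]] / tl_frac(t),
                                numeric(1))
  structure(
    list(nle_flows = conv$tissue_flows * blood_r,
         nle_volumes = nle_volumes,
         total_lipid_volumes = total_lipid_volumes,
         nle_cardiac_output = conv$cardiac_output * blood_r,
         reference_body_weight = conv$reference_body_weight,
         lipids = lipids),
    class = "nle_physiology")
}

#' Rat covariates
#'
#' Individual-level covariates of one study animal: its body-weight
#' trajectory end points and its measured liver-weight fraction.  Body
#' weight between dosing start and sacrifice is interpolated linearly (see
#' \code{\link{body_weight_at}}); the measured liver-weight ratio, when
#' present, overrides the allometrically scaled liver volume.
#'
#' @param initial_body_weight Body weight at study start (g).
#' @param final_body_weight Body weight at sacrifice (g).
#' @param sacrifice_day Day of sacrifice (days since first dose).
#' @param liver_weight_ratio Liver weight as a fraction of body weight,
#'   or \code{NA} to use the scaled reference liver volume.
#' @return An object of class \code{rat_covariates}.
#' @export
rat_covariates <- function(initial_body_weight, final_body_weight,
                           sacrifice_day, liver_weight_ratio = NA_real_) {
  if (initial_body_weight <= 0 || final_body_weight <= 0)
    stop("rat covariates: body weights must be positive", call. = FALSE)
  if (sacrifice_day <= 0)
    stop("rat covariates: sacrifice day must be positive", call. = FALSE)
  if (!is.na(liver_weight_ratio) &&
      (liver_weight_ratio <= 0 || liver_weight_ratio >= 0.1))
    stop("rat covariates: liver weight ratio must lie in (0, 0.1)",
         call. = FALSE)
  structure(
    list(initial_body_weight = initial_body_weight,
         final_body_weight = final_body_weight,
         sacrifice_day = sacrifice_day,
         liver_weight_ratio = liver_weight_ratio),
    class = "rat_covariates")
}

#' Body weight at a given study day
#'
#' Linear interpolation between initial and final body weight over the
#' interval from study start to sacrifice, with constant extrapolation
#' outside it.
#'
#' @param cov A \code{\link{rat_covariates}} object.
#' @param t Time in days since the first dose (vectorised).
#' @return Body weight(s) in g.
#' @export
body_weight_at <- function(cov, t) {
  stopifnot(inherits(cov, "rat_covariates"))
  frac <- pmin(pmax(t / cov$sacrifice_day, 0), 1)
  cov$initial_body_weight +
    frac * (cov$final_body_weight - cov$initial_body_weight)
}

#' Rescale NLE physiology to a different body weight
#'
#' Volumes scale linearly with body weight; flows and cardiac output scale
#' with body weight to the 3/4 power (standard allometry, matching the
#' BW^0.75 scaling of metabolic clearance).  When covariates with a
#' measured liver-weight ratio are supplied, the liver volume is replaced
#' by \code{ratio * body weight * liver NLE ratio} (1 g tissue taken as
#' 1 mL).
#'
#' @param base An \code{nle_physiology} object at its reference weight.
#' @param current_bw Target body weight (g).
#' @param cov Optional \code{\link{rat_covariates}} supplying a measured
#'   liver-weight ratio.
#' @return A new \code{nle_physiology} object; its
#'   \code{reference_body_weight} is set to \code{current_bw}.
#' @export
scale_for_body_weight <- function(base, current_bw, cov = NULL) {
  stopifnot(inherits(base, "nle_physiology"))
  if (!is.numeric(current_bw) || current_bw <= 0)
    stop("scale_for_body_weight: body weight must be positive",
         call. = FALSE)
  r <- current_bw / base$reference_body_weight
  out <- base
  out$nle_volumes <- base$nle_volumes * r
  out$total_lipid_volumes <- base$total_lipid_volumes * r
  out$nle_flows <- base$nle_flows * r^0.75
  out$nle_cardiac_output <- base$nle_cardiac_output * r^0.75
  if (!is.null(cov) && inherits(cov, "rat_covariates") &&
      !is.na(cov$liver_weight_ratio)) {
    i <- match("liver", base$lipids$tissue)
    liver_nle_ratio <- base$lipids$nle_ratio[i]
    liver_tl <- base$lipids$nle_per_total_lipid[i]
    v <- cov$liver_weight_ratio * current_bw * liver_nle_ratio
    out$nle_volumes[["liver"]] <- v
    out$total_lipid_volumes[["liver"]] <- v / liver_tl
  }
  out$reference_body_weight <- current_bw
  out
}

#' @export
print.nle_physiology <- function(x, ...) {
  cat("NLE-basis rat physiology (reference body weight ",
      x$reference_body_weight, " g)\n", sep = "")
  cat("  NLE cardiac output:", signif(x$nle_cardiac_output, 4),
      "mL NLE/h\n")
  cat("  NLE flows (mL NLE/h):\n")
  print(signif(x$nle_flows, 4))
  cat("  NLE volumes (mL NLE):\n")
  print(signif(x$nle_volumes, 4))
  invisible(x)
}
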