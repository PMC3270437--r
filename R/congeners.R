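#' The six-congener PCB mixture
#'
#' Congener table for the studied mixture: PCB 118 (mono-ortho,
#' metabolized via CYP1A) and PCBs 138, 153, 170, 180 and 187
#' (multi-ortho, metabolized via CYP2B).  Basal metabolic clearances
#' \code{v0} (mL/h/kg^0.75) default to the package's reference population
#' calibration medians.
#'
#' Mono-ortho congeners induce CYP1A (driven by the liver NLE
#' concentration of PCB 118); all six congeners jointly induce CYP2B
#' (driven by the summed liver NLE concentration of the mixture).
#'
#' @param v0 Named numeric vector of basal clearances (mL/h/kg^0.75); names
#'   must be the congener labels.  Defaults to the reference calibration.
#' @return A data frame of class \code{congener_spec} with columns
#'   \code{congener}, \code{ortho_class}, \code{enzyme}, \code{v0}.
#' @export
pcb_mixture <- function(v0 = c(`118` = 0.038, `138` = 0.026, `153` = 0.025,
                               `170` = 0.029, `180` = 0.035,
                               `187` = 0.017)) {
  congeners <- c("118", "138", "153", "170", "180", "187")
  if (is.null(names(v0)) || !setequal(names(v0), congeners))
    stop("pcb_mixture: v0 must be named with the six congeners ",
         paste(congeners, collapse = ", "), call. = FALSE)
  v0 <- v0[congeners]
  if (any(v0 <= 0))
    stop("pcb_mixture: basal clearances must be positive", call. = FALSE)
  out <- data.frame(
    congener    = congeners,
    ortho_class = c("mono-ortho", rep("multi-ortho", 5)),
    enzyme      = c("CYP1A", rep("CYP2B", 5)),
    v0          = as.numeric(v0),
    stringsAsFactors = FALSE
  )
  class(out) <- c("congener_spec", "data.frame")
  out
}

#' CYP450 turnover and induction parameters
#'
#' Parameters of the hepatic CYP1A/CYP2B mass balance
#' \deqn{dA/dt = k_0 - k_e A + k_0 F C_{IND},}
#' where \eqn{A} is the enzyme amount (nmol/g microsomal protein),
#' \eqn{k_0} the basal production rate (nmol/h/g protein), \eqn{k_e} the
#' first-order degradation rate (1/h), and the stimulation term is linear
#' in the inducer concentration \eqn{C_{IND}} (liver NLE concentration,
#' \eqn{\mu}g/mL NLE) with dimensionless-per-concentration slope \eqn{F}.
#' At zero inducer the balance is at steady state, which closes the
#' parameter set via \eqn{k_0 = k_e A_0}; when \code{A0} is omitted it is
#' computed as \code{k0/ke}.
#'
#' By default one (\code{A0}, \code{ke}, \code{k0}) set serves both
#' enzymes; supply length-2 vectors named \code{CYP1A}, \code{CYP2B} for
#' per-enzyme values.  Induction only enters the kinetics through the
#' ratio \eqn{A/A_0}, so the absolute baseline matters little.
#'
#' @param ke Degradation rate (1/h); scalar or length-2 named vector.
#' @param k0 Basal production rate (nmol/h/g protein); scalar or length-2.
#' @param A0 Baseline enzyme amount (nmol/g protein); defaults to
#'   \code{k0/ke}.
#' @param F_1A CYP1A induction slope (per \eqn{\mu}g/mL NLE), driven by
#'   liver PCB 118.
#' @param F_2B CYP2B induction slope, driven by the summed liver
#'   concentration of all six congeners.
#' @return An object of class \code{induction_params}: list with
#'   components \code{A0}, \code{ke}, \code{k0} (each length-2, named
#'   \code{CYP1A}/\code{CYP2B}), \code{F_1A}, \code{F_2B}.
#' @examples
#' induction_params()$A0  # steady-state closure: k0/ke = 0.1
#' @export
induction_params <- function(ke = 0.04, k0 = 0.004, A0 = NULL,
                             F_1A = 0, F_2B = 0) {
  expand <- function(x, what) {
    if (length(x) == 1L) x <- c(CYP1A = unname(x), CYP2B = unname(x))
    if (!setequal(names(x), c("CYP1A", "CYP2B")))
      stop("induction_params: ", what,
           " must be scalar or named CYP1A/CYP2B", call. = FALSE)
    x[c("CYP1A", "CYP2B")]
  }
  ke <- expand(ke, "ke"); k0 <- expand(k0, "k0")
  if (any(ke <= 0) || any(k0 <= 0))
    stop("induction_params: ke and k0 must be positive", call. = FALSE)
  if (is.null(A0)) {
    A0 <- k0 / ke
  } else {
    A0 <- expand(A0, "A0")
    if (any(abs(k0 - ke * A0) > 1e-8 * pmax(k0, 1e-12)))
      stop("induction_params: steady-state closure violated ",
           "(k0 must equal ke * A0)", call. = FALSE)
  }
  if (F_1A < 0 || F_2B < 0)
    stop("induction_params: induction slopes must be nonnegative",
         call. = FALSE)
  structure(list(A0 = A0, ke = ke, k0 = k0, F_1A = F_1A, F_2B = F_2B),
            class = "induction_params")
}

#' Steady-state CYP amount implied by the turnover balance
#'
#' With zero inducer the production/degradation balance is stationary at
#' \eqn{A_0 = k_0 / k_e}.
#'
#' @param p An \code{\link{induction_params}} object.
#' @return Named length-2 vector of baseline amounts (nmol/g protein).
#' @export
cyp_steady_state <- function(p) {
  stopifnot(inherits(p, "induction_params"))
  p$k0 / p$ke
}

#' Time derivative of the CYP induction balance
#'
#' Right-hand side of the enzyme turnover ODE for both enzymes:
#' \eqn{dA/dt = k_0 - k_e A + k_0 F C_{IND}}, with the CYP1A inducer
#' concentration being liver NLE PCB 118 and the CYP2B inducer the summed
#' liver NLE concentration of all six congeners.
#'
#' @param A Named numeric vector \code{c(CYP1A = , CYP2B = )} of current
#'   enzyme amounts (nmol/g protein).
#' @param c_ind_1A Liver NLE concentration of PCB 118 (\eqn{\mu}g/mL NLE).
#' @param c_ind_2B Summed liver NLE concentration of all congeners.
#' @param p An \code{\link{induction_params}} object.
#' @return Named vector of derivatives (nmol/g protein/h).
#' @export
cyp_derivative <- function(A, c_ind_1A, c_ind_2B, p) {
  stopifnot(inherits(p, "induction_params"))
  if (c_ind_1A < 0 || c_ind_2B < 0)
    stop("cyp_derivative: inducer concentrations must be nonnegative",
         call. = FALSE)
  A <- A[c("CYP1A", "CYP2B")]
  stim <- p$k0 * c(p$F_1A * c_ind_1A, p$F_2B * c_ind_2B)
  p$k0 - p$ke * A + stim
}

#' Induced metabolic clearance
#'
#' Metabolic clearance scales with body weight to the 3/4 power and with
#' the current enzyme amount relative to baseline:
#' \eqn{v_{cl} = v_0 \, (BW/1000)^{0.75} \, A/A_0} (mL/h, with body weight
#' in g and \eqn{v_0} in mL/h/kg^0.75).
#'
#' @param v0 Basal clearance (mL/h/kg^0.75).
#' @param bw Body weight (g).
#' @param A Current enzyme amount (nmol/g protein).
#' @param A0 Baseline enzyme amount.
#' @return Clearance in mL/h.
#' @export
induced_clearance <- function(v0, bw, A, A0) {
  if (any(A0 <= 0)) stop("induced_clearance: A0 must be positive",
                         call. = FALSE)
  v0 * (bw / 1000)^0.75 * A / A0
}
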