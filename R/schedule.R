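#' Oral dosing schedules
#'
#' Builds the dose-event list for one of the study protocols.  Every event
#' administers the stated dose of \emph{each} congener in the mixture
#' (\eqn{\mu}g per kg body weight per congener, by default recomputed from
#' the body weight current at the event time).
#'
#' Protocols:
#' \describe{
#'   \item{\code{daily}}{one dose every 24 h, days 0 .. n_days-1.}
#'   \item{\code{weekly}}{one dose every 168 h, days 0, 7, 14, ...}
#'   \item{\code{daily13}}{daily doses on days 0--12 only, then no
#'     exposure (alias \code{"daily-to-day-13"}).}
#'   \item{\code{nonperiodic}}{13 irregularly timed doses; the default
#'     event days are 0, 1, 2, 5, 8, 9, 15, 22, 29, 43, 57, 71, 85 (a
#'     documented package default, user-overridable via
#'     \code{nonperiodic_days}).  Events beyond \code{n_days} are
#'     dropped.}
#'   \item{\code{custom}}{event days given explicitly via \code{times}.}
#' }
#'
#' @param protocol Protocol label (see above).
#' @param dose_level Dose per congener per event (\eqn{\mu}g/kg body
#'   weight, unless \code{basis = "amount"} in which case \eqn{\mu}g).
#' @param n_days Length of the dosing window (days); events at times
#'   strictly greater than \code{n_days} are excluded.
#' @param times Event days for \code{protocol = "custom"}.
#' @param nonperiodic_days Event days used by the nonperiodic protocol.
#' @param basis \code{"per_kg"} (default; dose mass recomputed from body
#'   weight at each administration) or \code{"amount"} (fixed \eqn{\mu}g).
#' @return An object of class \code{dose_schedule}: data frame with
#'   columns \code{time_h} and \code{dose} plus attributes
#'   \code{protocol} and \code{basis}.
#' @examples
#' nrow(build_schedule("daily", 500, 90))   # 90 events
#' nrow(build_schedule("weekly", 5, 41))    # 6 events
#' @export
build_schedule <- function(protocol, dose_level, n_days,
                           times = NULL,
                           nonperiodic_days = c(0, 1, 2, 5, 8, 9, 15, 22,
                                                29, 43, 57, 71, 85),
                           basis = c("per_kg", "amount")) {
  basis <- match.arg(basis)
  if (dose_level < 0) stop("build_schedule: dose must be nonnegative",
                           call. = FALSE)
  if (n_days <= 0) stop("build_schedule: n_days must be positive",
                        call. = FALSE)
  if (identical(protocol, "daily-to-day-13")) protocol <- "daily13"
  days <- switch(protocol,
    daily       = seq(0, n_days - 1e-9, by = 1),
    weekly      = seq(0, n_days, by = 7),
    daily13     = seq(0, min(12, n_days - 1e-9), by = 1),
    nonperiodic = nonperiodic_days[nonperiodic_days <= n_days],
    custom      = {
      if (is.null(times))
        stop("build_schedule: custom protocol needs explicit times",
             call. = FALSE)
      times
    },
    stop("build_schedule: unknown protocol '", protocol, "'",
         call. = FALSE)
  )
  days <- as.numeric(days)
  if (is.unsorted(days, strictly = TRUE))
    stop("build_schedule: event times must be strictly increasing",
         call. = FALSE)
  if (any(days < 0))
    stop("build_schedule: event times must be nonnegative", call. = FALSE)
  out <- data.frame(time_h = days * 24, dose = dose_level)
  attr(out, "protocol") <- protocol
  attr(out, "basis") <- basis
  class(out) <- c("dose_schedule", "data.frame")
  out
}

#' The four study protocols
#' @return Character vector of the protocol labels used in the study
#'   design.
#' @export
study_protocols <- function() c("daily", "weekly", "daily13", "nonperiodic")
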