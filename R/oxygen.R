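#' Oxygen-return schedule
#'
#' The oxygen fraction reaching the liver is held at `O0` until the
#' underlying condition is treated, after which it returns logistically to 1
#' at rate `epsilon`. The logistic midpoint is placed 3 hours after the
#' treatment time so that the rise in oxygen effectively begins at treatment.
#'
#' @param O0 Pre-treatment oxygen fraction (> 0).
#' @param epsilon Return rate (1/day).
#' @param tau Treatment time (days); `Inf` means never treated.
#' @param midpoint_offset Offset of the logistic midpoint after `tau` (days);
#'   default 0.125 d = 3 h.
#' @return An object of class `oxygen_schedule` with fields `O0`, `epsilon`,
#'   `tau_mid` and `treated`.
#' @examples
#' sch <- oxygen_schedule(O0 = 0.5, epsilon = 20, tau = 8 / 24)
#' oxygen_level(sch, sch$tau_mid)  # midpoint value (1 + O0)/2
#' @export
oxygen_schedule <- function(O0, epsilon, tau, midpoint_offset = 0.125) {
  stopifnot(is.numeric(O0), length(O0) == 1L, O0 > 0,
            is.numeric(epsilon), length(epsilon) == 1L, epsilon > 0,
            is.numeric(tau), length(tau) == 1L, tau >= 0)
  if (O0 > 1)
    warning("O0 > 1 is outside the validated regime of the model", call. = FALSE)
  structure(list(O0 = O0, epsilon = epsilon,
                 tau_mid = tau + midpoint_offset,
                 treated = is.finite(tau)),
            class = "oxygen_schedule")
}

#' Schedule implied by a parameter set
#' @param params A `liver_params` object.
#' @inheritParams oxygen_schedule
#' @return An `oxygen_schedule`.
#' @export
schedule_from_params <- function(params, midpoint_offset = 0.125) {
  oxygen_schedule(params$O0, params$epsilon, params$tau, midpoint_offset)
}

#' Oxygen fraction at time t
#'
#' Logistic oxygen return: `O(t) = O0 + (1 - O0) / (1 + exp(-epsilon (t -
#' tau_mid)))` when treated, constant `O0` otherwise. Continuous and, for
#' `O0 <= 1`, nondecreasing and bounded in `[O0, 1]`.
#'
#' @param schedule An `oxygen_schedule`.
#' @param t Time(s) in days, >= 0.
#' @return Oxygen fraction(s), same length as `t`.
#' @export
oxygen_level <- function(schedule, t) {
  stopifnot(inherits(schedule, "oxygen_schedule"), all(t >= 0))
  if (!schedule$treated) return(rep(schedule$O0, length(t)))
  schedule$O0 + (1 - schedule$O0) *
    stats::plogis(schedule$epsilon * (t - schedule$tau_mid))
}

#' Magnitude of the oxygen rate of change
#'
#' Closed form `|dO/dt| = epsilon |1 - O0| sig (1 - sig)` where `sig` is the
#' logistic factor; both the `O0 <= 1` and `O0 > 1` branches collapse to this
#' expression. Zero for an untreated schedule. This is the forcing term of
#' the reperfusion-extended hepatocyte equations.
#'
#' @inheritParams oxygen_level
#' @return Rate magnitude(s) (1/day).
#' @export
oxygen_rate_magnitude <- function(schedule, t) {
  stopifnot(inherits(schedule, "oxygen_schedule"), all(t >= 0))
  if (!schedule$treated) return(rep(0, length(t)))
  sig <- stats::plogis(schedule$epsilon * (t - schedule$tau_mid))
  schedule$epsilon * abs(1 - schedule$O0) * sig * (1 - sig)
}
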