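#' Short-term plasticity kernel parameters
#'
#' Bundles the constants of the two-state stochastic release process: a
#' facilitation kernel driven by signal arrivals and a depletion kernel driven
#' by successful releases. Defaults follow the reference parameterisation used
#' throughout the package (`C0 = 20`, `V0 = 10`, `tau_c = 100` ms,
#' `tau_v = 800` ms, `alpha = 4`).
#'
#' @param C0 Facilitation constant (dimensionless, > 0). Baseline of the
#'   facilitation state `C(t)`.
#' @param V0 Depression constant (dimensionless, > 0). Baseline of the
#'   depletion state `V(t)`; also its upper bound.
#' @param tau_c Facilitation decay time constant in ms (> 0).
#' @param tau_v Depression decay time constant in ms (> 0).
#' @param alpha Magnitude of the facilitation response to a single arrival
#'   (dimensionless, > 0).
#'
#' @return An object of class `stp_params` (a named list).
#' @export
#' @examples
#' p <- stp_params()
#' facilitation(p, arrival_times = c(0, 50), t = 100)
stp_params <- function(C0 = 20, V0 = 10, tau_c = 100, tau_v = 800, alpha = 4) {
  vals <- list(C0 = C0, V0 = V0, tau_c = tau_c, tau_v = tau_v, alpha = alpha)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("stp_params: `", nm, "` must be a single positive finite number", call. = FALSE)
    }
  }
  structure(vals, class = "stp_params")
}

#' Facilitation state C(t)
#'
#' Residual-calcium-like facilitation: each signal arrival at time `t_i < t`
#' adds `alpha * exp(-(t - t_i)/tau_c)`; the state never drops below `C0`.
#'
#' @param params An [stp_params()] object.
#' @param arrival_times Numeric vector of signal-arrival times (ms), all
#'   strictly earlier than `t`. An arrival exactly at `t` does not contribute.
#' @param t Evaluation time (ms).
#'
#' @return `C(t) = C0 + sum(alpha * exp(-(t - t_i)/tau_c))`, always `>= C0`.
#' @export
facilitation <- function(params, arrival_times = numeric(), t = 0) {
  stopifnot(inherits(params, "stp_params"))
  arrival_times <- arrival_times[arrival_times < t]
  params$C0 + params$alpha * sum(exp(-(t - arrival_times) / params$tau_c))
}

#' Depletion state V(t)
#'
#' Vesicle-pool depletion: each successful release at time `t_i < t` subtracts
#' `exp(-(t - t_i)/tau_v)` from the baseline `V0`; the state is clamped at 0.
#'
#' @inheritParams facilitation
#' @param release_times Numeric vector of successful-release times (ms), all
#'   strictly earlier than `t`.
#'
#' @return `V(t) = max(0, V0 - sum(exp(-(t - t_i)/tau_v)))`, in `[0, V0]`.
#' @export
depletion <- function(params, release_times = numeric(), t = 0) {
  stopifnot(inherits(params, "stp_params"))
  release_times <- release_times[release_times < t]
  max(0, params$V0 - sum(exp(-(t - release_times) / params$tau_v)))
}

#' Release probability of a transmitter
#'
#' Two-state stochastic release: `Ps = 1 - exp(-C * V)`. Monotone
#' nondecreasing in the product `C * V` and always in `[0, 1)`.
#'
#' @param C Facilitation state, `>= 0` (vectorised).
#' @param V Depletion state, `>= 0` (vectorised).
#'
#' @return Release probability/-ies in `[0, 1)`.
#' @export
#' @examples
#' release_probability(20, 10)        # ~1 within double precision
#' release_probability(log(2), 1)     # exactly 0.5
release_probability <- function(C, V) {
  if (any(C < 0) || any(V < 0)) {
    stop("release_probability: C and V must be nonnegative", call. = FALSE)
  }
  1 - exp(-C * V)
}

#' Activation probability of a receptor
#'
#' Receptors follow the same stochastic process as transmitters but take no
#' part in vesicle depletion: the depletion state is fixed at one, so the
#' probability is `1 - exp(-C(t))` with `C(t)` driven by arrivals alone.
#'
#' @inheritParams facilitation
#'
#' @return Activation probability in `[0, 1)`.
#' @export
receptor_probability <- function(params, arrival_times = numeric(), t = 0) {
  release_probability(facilitation(params, arrival_times, t), 1)
}
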