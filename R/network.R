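#' Threshold squashing function
#'
#' Maps the homeostatic activity ratios onto threshold values. The default
#' `"sigmoid"` mode is the logistic `1/(1 + e^-x)`, bounded in (0, 1) so that
#' the activation condition `Ps > theta` remains satisfiable. The
#' `"as-printed"` mode is `1/(1 - e^-x)`, which exceeds 1 for `x > 0` and is
#' singular at `x = 0`; it is kept for fidelity experiments only.
#'
#' @param x Numeric vector.
#' @param mode `"sigmoid"` (default) or `"as-printed"`.
#' @return Squashed values; in (0, 1) for the sigmoid mode.
#' @export
#' @examples
#' squash(0)                      # 0.5
#' squash(1, mode = "as-printed") # 1/(1 - exp(-1))
squash <- function(x, mode = c("sigmoid", "as-printed")) {
  mode <- match.arg(mode)
  if (mode == "sigmoid") {
    1 / (1 + exp(-x))
  } else {
    if (any(x == 0)) {
      stop("squash: as-printed form 1/(1 - e^-x) is singular at x = 0", call. = FALSE)
    }
    1 / (1 - exp(-x))
  }
}

# Per-neuron mutable state. Kernel states use lazy exponential decay: `cex` is
# the facilitation excess (C - C0) at time `ct`, `vsum` the depletion sum at
# time `vt`; decaying to the current time is done on access. Equivalent to the
# full-history kernels in stp-kernels.R (tested against them).
new_neuron <- function(id, cfg) {
  e <- new.env(parent = emptyenv())
  e$id <- id
  e$n_T <- cfg$n_T
  e$n_R <- cfg$n_R
  e$g <- cfg$g
  e$group_size <- cfg$n_R %/% cfg$g
  e$group_id <- rep(seq_len(cfg$g), each = e$group_size)
  n_act_T <- round(cfg$init_active_fraction * cfg$n_T)
  e$trans_active <- logical(cfg$n_T)
  e$trans_active[sample.int(cfg$n_T, n_act_T)] <- TRUE
  e$rec_active <- logical(cfg$n_R)
  n_act_R <- round(cfg$init_active_fraction * e$group_size)
  for (j in seq_len(cfg$g)) {
    pick <- sample.int(e$group_size, n_act_R)
    e$rec_active[(j - 1L) * e$group_size + pick] <- TRUE
  }
  e$trans_cex <- numeric(cfg$n_T); e$trans_ct <- numeric(cfg$n_T)
  e$trans_vsum <- numeric(cfg$n_T); e$trans_vt <- numeric(cfg$n_T)
  e$rec_cex <- numeric(cfg$n_R); e$rec_ct <- numeric(cfg$n_R)
  e$theta_T <- NA_real_
  e$theta_R <- rep(NA_real_, cfg$g)
  class(e) <- "dynsyn_neuron"
  e
}

#' Build a two-neuron network
#'
#' Constructs the fully connected two-neuron network: each neuron carries
#' `n_T` transmitters and `g` receptor groups of `n_R/g` receptors. A uniformly
#' random `init_active_fraction` of the transmitters, and of each receptor
#' group, starts in the active state. Initial thresholds are computed from the
#' initial activity ratios with [update_thresholds()]. Uses the current RNG
#' state; seed it with `set.seed()` for reproducibility.
#'
#' The returned network is a mutable object (per-neuron state lives in
#' environments); the engine updates it in place.
#'
#' @param config A [experiment_config()] object.
#' @return An object of class `dynsyn_network` with elements `neurons` (list
#'   of two), `step_ms`, `threshold_period`, and `config`.
#' @export
build_network <- function(config) {
  stopifnot(inherits(config, "dynsyn_config"))
  net <- structure(
    list(neurons = list(A = new_neuron("A", config), B = new_neuron("B", config)),
         step_ms = config$step_ms,
         threshold_period = config$threshold_period,
         config = config),
    class = "dynsyn_network")
  update_thresholds(net, t = 0)
  net
}

#' Activity ratios of a network
#'
#' Returns, for each neuron, the fraction of active transmitters `O` and the
#' per-group fraction of active receptors `X`; both always lie in `[0, 1]`.
#'
#' @param network A `dynsyn_network`.
#' @return A tibble with columns `neuron`, `O`, `group`, `X` (one row per
#'   receptor group).
#' @export
activity_ratios <- function(network) {
  purrr::map_dfr(network$neurons, function(nr) {
    tibble::tibble(
      neuron = nr$id,
      O = sum(nr$trans_active) / nr$n_T,
      group = seq_len(nr$g),
      X = as.vector(tapply(nr$rec_active, nr$group_id, sum)) / nr$group_size
    )
  })
}

#' Homeostatic threshold update
#'
#' Recomputes both neurons' thresholds from the instantaneous activity
#' ratios. For receptor group `j` of neuron `J` (presynaptic partner `I`) the
#' threshold is `f(X_Jj / O_I)`; for the transmitter set of neuron `I` it is
#' `f(O_I * sum_j X_Ij)` over neuron `I`'s own receptor groups (its synaptic
#' inputs), or `f(sum_j X_Ij / O_I)` in `theta_T_mode = "ratio"`. When a ratio
#' denominator `O` is zero the squash argument is replaced by the configured
#' cap `x_max`. In the intended protocol this is called every
#' `threshold_period` steps (default 60 steps = 300 ms).
#'
#' @param network A `dynsyn_network` (mutated in place).
#' @param t Current time in ms (recorded only).
#' @return The network, invisibly.
#' @export
update_thresholds <- function(network, t) {
  cfg <- network$config
  A <- network$neurons[[1]]; B <- network$neurons[[2]]
  O <- c(sum(A$trans_active) / A$n_T, sum(B$trans_active) / B$n_T)
  X <- list(as.vector(tapply(A$rec_active, A$group_id, sum)) / A$group_size,
            as.vector(tapply(B$rec_active, B$group_id, sum)) / B$group_size)
  capped_ratio <- function(num, den) {
    if (den == 0) rep(cfg$x_max, length(num)) else num / den
  }
  for (i in 1:2) {
    partner <- 3L - i
    nr <- network$neurons[[i]]
    # receptor groups of neuron i are contacted by the partner's transmitters
    nr$theta_R <- squash(capped_ratio(X[[i]], O[[partner]]), mode = cfg$squash_mode)
    arg_T <- if (cfg$theta_T_mode == "product") {
      O[[i]] * sum(X[[i]])
    } else {
      capped_ratio(sum(X[[i]]), O[[i]])
    }
    nr$theta_T <- squash(arg_T, mode = cfg$squash_mode)
  }
  invisible(network)
}

#' Evaluate a single unit on signal arrival (reference semantics)
#'
#' Pure single-unit form of the arrival-triggered state update used
#' (vectorised, with lazy kernel decay) inside the engine. The arriving signal
#' is appended to the unit's history, the release (transmitter) or activation
#' (receptor) probability is evaluated from strictly earlier history, and the
#' unit becomes active iff `Ps > theta` (strict). An active transmitter
#' records `t` as a successful release.
#'
#' @param unit A list with fields `role` (`"transmitter"` or `"receptor"`),
#'   `state` (`"active"`/`"inactive"`), `arrival_times`, `release_times`
#'   (numeric, ms).
#' @param theta Threshold the unit is compared against.
#' @param t Arrival time (ms); must exceed all recorded times.
#' @param params An [stp_params()] object.
#' @return The updated unit, with an added field `Ps` (the probability used).
#' @export
evaluate_unit <- function(unit, theta, t, params = stp_params()) {
  stopifnot(unit$role %in% c("transmitter", "receptor"))
  Ps <- if (unit$role == "transmitter") {
    release_probability(facilitation(params, unit$arrival_times, t),
                        depletion(params, unit$release_times, t))
  } else {
    receptor_probability(params, unit$arrival_times, t)
  }
  unit$arrival_times <- c(unit$arrival_times, t)
  unit$state <- if (Ps > theta) "active" else "inactive"
  if (unit$state == "active" && unit$role == "transmitter") {
    unit$release_times <- c(unit$release_times, t)
  }
  unit$Ps <- Ps
  unit
}

# Vectorised arrival handling for one neuron's receptors. `idx` may contain
# duplicates (simultaneous signals); all arrivals at time t see the same
# strictly-earlier history, so Ps is computed once per unique unit.
process_receptor_events <- function(nr, idx, t, cfg) {
  if (length(idx) == 0L) return(integer())
  u <- unique(idx)
  cnt <- tabulate(match(idx, u), nbins = length(u))
  p <- cfg$stp
  cex <- nr$rec_cex[u] * exp(-(t - nr$rec_ct[u]) / p$tau_c)
  Ps <- 1 - exp(-(p$C0 + cex))            # receptor: depletion fixed at 1
  act <- Ps > nr$theta_R[nr$group_id[u]]
  nr$rec_active[u] <- act
  nr$rec_cex[u] <- cex + p$alpha * cnt
  nr$rec_ct[u] <- t
  # each signal landing on a now-active receptor is forwarded to a uniformly
  # random transmitter of the same neuron (next step)
  n_fwd <- sum(cnt[act])
  if (n_fwd == 0L) return(integer())
  sample.int(nr$n_T, n_fwd, replace = TRUE)
}

# Vectorised arrival handling for one neuron's transmitters. Returns receptor
# indices on the *other* neuron (one per successfully released signal).
process_transmitter_events <- function(nr, other, idx, t, cfg) {
  if (length(idx) == 0L) return(integer())
  u <- unique(idx)
  cnt <- tabulate(match(idx, u), nbins = length(u))
  p <- cfg$stp
  cex <- nr$trans_cex[u] * exp(-(t - nr$trans_ct[u]) / p$tau_c)
  vsum <- nr$trans_vsum[u] * exp(-(t - nr$trans_vt[u]) / p$tau_v)
  V <- pmax(0, p$V0 - vsum)
  Ps <- 1 - exp(-(p$C0 + cex) * V)
  act <- Ps > nr$theta_T
  nr$trans_active[u] <- act
  nr$trans_cex[u] <- cex + p$alpha * cnt
  nr$trans_ct[u] <- t
  nr$trans_vsum[u] <- vsum + ifelse(act, cnt, 0)  # releases: one per signal
  nr$trans_vt[u] <- t
  n_fwd <- sum(cnt[act])
  if (n_fwd == 0L) return(integer())
  grp <- sample.int(other$g, n_fwd, replace = TRUE)
  rec <- sample.int(other$group_size, n_fwd, replace = TRUE)
  (grp - 1L) * other$group_size + rec
}

#' Empty event queue
#'
#' @param network A `dynsyn_network`.
#' @return A list with integer target vectors `rec$A`, `rec$B`, `trans$A`,
#'   `trans$B`.
#' @export
empty_events <- function(network) {
  list(rec = list(A = integer(), B = integer()),
       trans = list(A = integer(), B = integer()))
}

#' Propagate one step of signals through the network
#'
#' Applies the behavioural propagation rule for one 5 ms step: every event
#' targets a unit, the unit's state is re-evaluated on arrival, and active
#' units forward one signal per arriving signal — receptors to a uniformly
#' random transmitter of the same neuron, transmitters to a uniformly random
#' receptor of a uniformly random receptor group of the other neuron — for the
#' next step. Inactive units drop the signal. Events are processed in a fixed
#' order (neuron A receptor events, B receptor events, A transmitter events,
#' B transmitter events; within each class in enqueue order), so runs are
#' reproducible under a fixed seed. Signal count is never amplified.
#'
#' @param network A `dynsyn_network` (mutated in place).
#' @param events Event queue for step `t` (see [empty_events()]).
#' @param t Current time in ms.
#' @return The event queue for step `t + 1`.
#' @export
propagate <- function(network, events, t) {
  cfg <- network$config
  A <- network$neurons[[1]]; B <- network$neurons[[2]]
  nxt <- empty_events(network)
  nxt$trans$A <- process_receptor_events(A, events$rec$A, t, cfg)
  nxt$trans$B <- process_receptor_events(B, events$rec$B, t, cfg)
  nxt$rec$B <- process_transmitter_events(A, B, events$trans$A, t, cfg)
  nxt$rec$A <- process_transmitter_events(B, A, events$trans$B, t, cfg)
  nxt
}

# Release probabilities of (a subsample of) a neuron's transmitters at time t.
transmitter_ps <- function(nr, t, cfg) {
  p <- cfg$stp
  idx <- if (is.na(cfg$ps_subsample) || cfg$ps_subsample >= nr$n_T) {
    seq_len(nr$n_T)
  } else {
    sample.int(nr$n_T, cfg$ps_subsample)
  }
  C <- p$C0 + nr$trans_cex[idx] * exp(-(t - nr$trans_ct[idx]) / p$tau_c)
  V <- pmax(0, p$V0 - nr$trans_vsum[idx] * exp(-(t - nr$trans_vt[idx]) / p$tau_v))
  1 - exp(-C * V)
}

#' @export
print.dynsyn_network <- function(x, ...) {
  a <- x$neurons[[1]]
  cat("<dynsyn_network> 2 neurons |", a$n_T, "transmitters,", a$n_R, "receptors in",
      a$g, "groups each | step", x$step_ms, "ms\n")
  invisible(x)
}
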