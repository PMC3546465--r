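#' STDP learning parameters
#'
#' Parameters of the bin-level spike-timing-dependent plasticity rule. The
#' window amplitudes `A_plus`/`A_minus` define the reference exponential
#' window (see [stdp_window()]); the learning rates `gamma_p`/`gamma_d` scale
#' the actual weight update. Stability of the learned weights requires the
#' integral of the weight window to be negative, i.e.
#' `gamma_p * tau_plus < gamma_d * tau_minus` (and likewise for the reference
#' amplitudes); construction fails otherwise.
#'
#' @param gamma_p Potentiation learning rate (default 0.005).
#' @param gamma_d Depression learning rate (default 0.00525).
#' @param tau_plus Potentiation time constant in ms (default 20).
#' @param tau_minus Depression time constant in ms (default 20).
#' @param A_plus,A_minus Reference window amplitudes; default to the learning
#'   rates.
#'
#' @return An object of class `stdp_params`.
#' @export
stdp_params <- function(gamma_p = 0.005, gamma_d = 0.00525,
                        tau_plus = 20, tau_minus = 20,
                        A_plus = gamma_p, A_minus = gamma_d) {
  vals <- list(gamma_p = gamma_p, gamma_d = gamma_d, tau_plus = tau_plus,
               tau_minus = tau_minus, A_plus = A_plus, A_minus = A_minus)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("stdp_params: `", nm, "` must be a single positive finite number", call. = FALSE)
    }
  }
  if (gamma_p * tau_plus >= gamma_d * tau_minus) {
    stop("stdp_params: stability requires gamma_p * tau_plus < gamma_d * tau_minus ",
         "(the STDP window integral must be negative)", call. = FALSE)
  }
  if (A_plus * tau_plus >= A_minus * tau_minus) {
    stop("stdp_params: stability requires A_plus * tau_plus < A_minus * tau_minus", call. = FALSE)
  }
  structure(vals, class = "stdp_params")
}

# Scale presets. "desk" runs in seconds on one core and is used throughout the
# test suite; "full" matches the reference protocol (30000 transmitters and
# receptors per neuron, ten receptor groups, ~2 simulated hours, sparse bins).
.presets <- list(
  desk = list(n_T = 600L, n_R = 600L, g = 3L, duration_steps = 20000L,
              bin_stride = 7L, ps_subsample = NA_integer_),
  full = list(n_T = 30000L, n_R = 30000L, g = 10L, duration_steps = 1440000L,
              bin_stride = 7200L, ps_subsample = 1000L)
)

#' Experiment configuration
#'
#' Builds and validates the full run configuration: network sizes, time grid,
#' input rate, short-term-plasticity and STDP parameters, and the switches
#' that select between the printed and the conventional forms of the
#' ambiguous formulas.
#'
#' @param lambda_hz Mean rate of the Poisson input (must be > 0). The input
#'   stream is encoded by the median-threshold rule: one Poisson draw with mean
#'   `lambda_hz` per 5 ms step, emitting 1 iff the draw exceeds the
#'   distribution's median (see [encode_poisson()]).
#' @param preset `"desk"` (600/600 units, 3 groups, 20000 steps, contiguous
#'   bins) or `"full"` (30000/30000 units, 10 groups, 1.44e6 steps = ~2 h,
#'   one 7-cell bin every 7200 steps). Any field can be overridden.
#' @param n_T,n_R,g Transmitters and receptors per neuron and number of
#'   receptor groups (`g` must divide `n_R`).
#' @param duration_steps Number of 5 ms steps to simulate (>= 7).
#' @param bin_stride Steps between consecutive bin starts (>= 7; 7 =
#'   contiguous bins).
#' @param step_ms Grid resolution in ms (default 5; also the gap between bin
#'   cells).
#' @param threshold_period Steps between homeostatic threshold updates
#'   (default 60, i.e. 300 ms).
#' @param init_active_fraction Fraction of transmitters, and of each receptor
#'   group, set active at the onset (default 0.01).
#' @param stp An [stp_params()] object.
#' @param stdp An [stdp_params()] object.
#' @param w_init Initial synaptic weight W(0) (default 1.0; the absolute
#'   weight scale depends on this choice).
#' @param squash_mode `"sigmoid"` (default; logistic `1/(1+e^-x)`) or
#'   `"as-printed"` (`1/(1-e^-x)`); see [squash()].
#' @param theta_T_mode `"product"` (default): transmitter-set threshold
#'   argument is `O * sum(X)`; `"ratio"`: `sum(X) / O`.
#' @param x_max Cap substituted for the ratio argument of the threshold
#'   squash when the presynaptic output fraction `O` is zero (default 10).
#' @param var_mode `"as-printed"` (default): bin variance is
#'   `S2_pre + S2_post - 2 Cov`; `"plus2cov"`: conventional variance of a sum.
#' @param amplitude_mode `"var-over-mu"` (default; amplitude ratio uses
#'   `sigma^2/mu` terms as printed) or `"cv-sigma"` (uses `sigma/mu`).
#' @param ps_subsample Number of presynaptic transmitters sampled when
#'   recording per-cell mean release probability; `NA` = all transmitters.
#'
#' @return An object of class `dynsyn_config` (a named list).
#' @export
#' @examples
#' cfg <- experiment_config(lambda_hz = 10, preset = "desk", duration_steps = 700L)
experiment_config <- function(lambda_hz = 10,
                              preset = c("desk", "full"),
                              n_T = NULL, n_R = NULL, g = NULL,
                              duration_steps = NULL, bin_stride = NULL,
                              step_ms = 5,
                              threshold_period = 60L,
                              init_active_fraction = 0.01,
                              stp = stp_params(),
                              stdp = stdp_params(),
                              w_init = 1.0,
                              squash_mode = c("sigmoid", "as-printed"),
                              theta_T_mode = c("product", "ratio"),
                              x_max = 10,
                              var_mode = c("as-printed", "plus2cov"),
                              amplitude_mode = c("var-over-mu", "cv-sigma"),
                              ps_subsample = NULL) {
  preset <- match.arg(preset)
  p <- .presets[[preset]]
  cfg <- list(
    lambda_hz = lambda_hz,
    preset = preset,
    n_T = as.integer(n_T %||% p$n_T),
    n_R = as.integer(n_R %||% p$n_R),
    g = as.integer(g %||% p$g),
    duration_steps = as.integer(duration_steps %||% p$duration_steps),
    bin_stride = as.integer(bin_stride %||% p$bin_stride),
    step_ms = step_ms,
    threshold_period = as.integer(threshold_period),
    init_active_fraction = init_active_fraction,
    stp = stp,
    stdp = stdp,
    w_init = w_init,
    squash_mode = match.arg(squash_mode),
    theta_T_mode = match.arg(theta_T_mode),
    x_max = x_max,
    var_mode = match.arg(var_mode),
    amplitude_mode = match.arg(amplitude_mode),
    ps_subsample = as.integer(ps_subsample %||% p$ps_subsample)
  )
  validate_config(cfg)
}

validate_config <- function(cfg) {
  bad <- character()
  chk <- function(ok, msg) if (!isTRUE(ok)) bad <<- c(bad, msg)
  chk(is.numeric(cfg$lambda_hz) && cfg$lambda_hz > 0, "lambda_hz must be > 0")
  chk(cfg$n_T > 0L, "n_T must be > 0")
  chk(cfg$n_R > 0L, "n_R must be > 0")
  chk(cfg$g > 0L, "g must be > 0")
  chk(cfg$n_R %% cfg$g == 0L, "g must divide n_R")
  chk(cfg$duration_steps >= 7L, "duration_steps must be >= 7")
  chk(cfg$bin_stride >= 7L, "bin_stride must be >= 7")
  chk(cfg$step_ms > 0, "step_ms must be > 0")
  chk(cfg$threshold_period > 0L, "threshold_period must be > 0")
  chk(cfg$init_active_fraction >= 0 && cfg$init_active_fraction <= 1,
      "init_active_fraction must be in [0, 1]")
  chk(inherits(cfg$stp, "stp_params"), "stp must be an stp_params object")
  chk(inherits(cfg$stdp, "stdp_params"), "stdp must be an stdp_params object")
  chk(is.numeric(cfg$w_init) && is.finite(cfg$w_init), "w_init must be finite")
  chk(cfg$x_max > 0, "x_max must be > 0")
  chk(is.na(cfg$ps_subsample) || cfg$ps_subsample > 0L,
      "ps_subsample must be NA or > 0")
  if (length(bad) > 0L) {
    stop("invalid configuration: ", paste(bad, collapse = "; "), call. = FALSE)
  }
  structure(cfg, class = "dynsyn_config")
}

#' Read a run configuration from a YAML file
#'
#' Reads a flat YAML mapping and fills every unstated field with its default
#' (the reference kernel constants `C0 = 20`, `V0 = 10`, `tau_c = 100`,
#' `tau_v = 800`, `alpha = 4`, STDP constants `tau = 20` ms,
#' `gamma_p = 0.005`, `gamma_d = 0.00525`, and the preset's sizes). Keys match
#' the arguments of [experiment_config()]; kernel and STDP constants are given
#' flat as `C0, V0, tau_c, tau_v, alpha, gamma_p, gamma_d, tau_plus,
#' tau_minus, A_plus, A_minus`. Unknown keys and invariant violations are
#' rejected with a message listing the offending keys.
#'
#' @param path Path to a YAML file; an empty file yields all defaults.
#' @return A validated `dynsyn_config`.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config file must be a YAML mapping", call. = FALSE)
  stp_keys <- c("C0", "V0", "tau_c", "tau_v", "alpha")
  stdp_keys <- c("gamma_p", "gamma_d", "tau_plus", "tau_minus", "A_plus", "A_minus")
  top_keys <- setdiff(names(formals(experiment_config)), c("stp", "stdp"))
  unknown <- setdiff(names(raw), c(stp_keys, stdp_keys, top_keys))
  if (length(unknown) > 0L) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  args <- raw[intersect(names(raw), top_keys)]
  args$stp <- do.call(stp_params, raw[intersect(names(raw), stp_keys)])
  args$stdp <- do.call(stdp_params, raw[intersect(names(raw), stdp_keys)])
  do.call(experiment_config, args)
}

#' Write a run configuration to a YAML file
#'
#' Inverse of [load_config()]: `load_config(save_config(cfg, path))` returns a
#' configuration identical to `cfg`.
#'
#' @param cfg A `dynsyn_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "dynsyn_config"))
  flat <- cfg[setdiff(names(cfg), c("stp", "stdp"))]
  flat <- c(flat, unclass(cfg$stp), unclass(cfg$stdp))
  flat <- lapply(flat, function(x) if (is.integer(x) && is.na(x)) NULL else x)
  flat <- flat[!vapply(flat, is.null, logical(1))]
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' @export
print.dynsyn_config <- function(x, ...) {
  cat("<dynsyn_config> preset:", x$preset,
      sprintf("| lambda %g Hz | n_T %d n_R %d g %d | %d steps x %g ms | bin stride %d\n",
              x$lambda_hz, x$n_T, x$n_R, x$g, x$duration_steps, x$step_ms, x$bin_stride))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
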