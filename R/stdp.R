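#' Highest hitters of a bin
#'
#' Finds, over the seven cells, the cell with the maximal presynaptic
#' active-transmitter count and the cell with the maximal postsynaptic
#' active-transmitter count — the bin's "highest hitters", which stand in for
#' a pre- and a postsynaptic action potential. Ties break toward the earliest
#' cell. Times map as `t = (cell - 1) * 5` ms.
#'
#' @param rec A [bin_record()].
#' @return A one-row tibble with `c_pre`, `c_post` (cell indices in 1..7) and
#'   `t_pre_ms`, `t_post_ms`.
#' @export
find_hitters <- function(rec) {
  c_pre <- which.max(rec$at_pre)
  c_post <- which.max(rec$at_post)
  tibble::tibble(
    c_pre = c_pre, c_post = c_post,
    t_pre_ms = (c_pre - 1) * 5, t_post_ms = (c_post - 1) * 5
  )
}

#' Reference STDP weight window
#'
#' The classical exponential pair-based window: `A_plus * exp(-(t_post -
#' t_pre)/tau_plus)` when the presynaptic event leads (`t_pre < t_post`),
#' `-A_minus * exp(-(t_pre - t_post)/tau_minus)` otherwise; coincident events
#' (`t_pre == t_post`) take the depression branch. In this model the actual
#' weight update ([weight_update()]) replaces the amplitudes with
#' modulated learning rates; this reference form documents the window shape
#' and its stability condition (negative integral when
#' `A_plus * tau_plus < A_minus * tau_minus`).
#'
#' @param t_pre,t_post Event times in ms.
#' @param params An [stdp_params()] object.
#' @return The window value (positive for potentiation, negative for
#'   depression).
#' @export
stdp_window <- function(t_pre, t_post, params = stdp_params()) {
  if (t_pre < t_post) {
    params$A_plus * exp(-(t_post - t_pre) / params$tau_plus)
  } else {
    -params$A_minus * exp(-(t_pre - t_post) / params$tau_minus)
  }
}

#' Fresh per-synapse learning state
#'
#' Holds the cumulative synapse statistics (mean, variance, total mean release
#' probability — all sums over the bins seen so far), the running bin-mean
#' activities used by the quiescence gate, and the weight history starting at
#' `W(0) = w_init`.
#'
#' @param w_init Initial weight W(0).
#' @return An object of class `synapse_state`.
#' @export
synapse_state <- function(w_init = 1.0) {
  structure(
    list(mu_S = 0, var_S = 0, M_T_S = 0,
         n_bins = 0L,
         sum_at_pre = 0, sum_at_post = 0,
         weight = w_init,
         weight_history = w_init),
    class = "synapse_state")
}

#' Accumulate a bin into the cumulative synapse statistics
#'
#' Bins are treated as mutually independent with linearly summing impact, so
#' the synapse's cumulative mean, variance, and total mean release probability
#' are running sums of the corresponding bin statistics (all starting at 0).
#' The running bin-mean activities for the quiescence gate are advanced too;
#' call [quiescence_gate()] *before* this.
#'
#' @param state A [synapse_state()].
#' @param stats A one-row [bin_stats()] tibble.
#' @param rec The [bin_record()] the stats came from (for the running
#'   activity means).
#' @return The updated `synapse_state`.
#' @export
accumulate <- function(state, stats, rec) {
  state$mu_S <- state$mu_S + stats$mu_B
  state$var_S <- state$var_S + stats$var_B
  state$M_T_S <- state$M_T_S + stats$mean_release_B
  state$sum_at_pre <- state$sum_at_pre + mean(rec$at_pre)
  state$sum_at_post <- state$sum_at_post + mean(rec$at_post)
  state$n_bins <- state$n_bins + 1L
  state
}

#' Quiescence gate
#'
#' A neuron counts as non-quiescent when its average output during the current
#' bin meets or exceeds the average output it has produced so far. The weight
#' may only be updated when both neurons are non-quiescent: the current bin's
#' mean active-transmitter count, presynaptic and postsynaptic, must each be
#' `>=` its running mean over all previous bins (inclusive comparison). The
#' first bin passes vacuously (running means are 0).
#'
#' @param state A [synapse_state()] *before* the current bin is accumulated.
#' @param rec The current [bin_record()].
#' @return `TRUE` if the weight update is permitted.
#' @export
quiescence_gate <- function(state, rec) {
  if (state$n_bins == 0L) return(TRUE)
  run_pre <- state$sum_at_pre / state$n_bins
  run_post <- state$sum_at_post / state$n_bins
  run_pre <= mean(rec$at_pre) && run_post <= mean(rec$at_post)
}

#' Bin amplitude relative to the synapse history
#'
#' The amplitude of the bin's impact is the bin's dispersion-to-mean term
#' relative to the synapse's cumulative one: `(var_B/mu_B) / (var_S/mu_S)`,
#' with the cumulative statistics including the current bin (call after
#' [accumulate()]). The printed statistic uses `sigma^2/mu`; mode
#' `"cv-sigma"` uses the coefficient of variation `sigma/mu` instead.
#'
#' @param stats A one-row [bin_stats()] tibble.
#' @param state A [synapse_state()] *after* accumulating the current bin.
#' @param mode `"var-over-mu"` (default) or `"cv-sigma"`.
#' @return `A_k >= 0`, or `NA_real_` when a guard fails (`mu_B`, `mu_S`, or
#'   the cumulative dispersion term is zero) — the caller must then skip the
#'   update.
#' @export
amplitude <- function(stats, state, mode = c("var-over-mu", "cv-sigma")) {
  mode <- match.arg(mode)
  if (stats$mu_B <= 0 || state$mu_S <= 0 || state$var_S <= 0) return(NA_real_)
  if (mode == "var-over-mu") {
    (stats$var_B / stats$mu_B) / (state$var_S / state$mu_S)
  } else {
    (sqrt(stats$var_B) / stats$mu_B) / (sqrt(state$var_S) / state$mu_S)
  }
}

#' Release fraction of the current bin
#'
#' Ratio of the bin's mean release probability to the synapse's cumulative
#' total (current bin included), hence always in `(0, 1]` when defined.
#'
#' @inheritParams amplitude
#' @return `U_k` in `(0, 1]`, or `NA_real_` when the cumulative total is zero.
#' @export
release_fraction <- function(stats, state) {
  if (state$M_T_S <= 0) return(NA_real_)
  stats$mean_release_B / state$M_T_S
}

#' Potentiation reference weight
#'
#' The median of all previously recorded weights (including `W(0)`): a robust
#' center of the weight distribution, insensitive to outliers, used as the
#' divisor of the potentiation update so that strong synapses are potentiated
#' less than weak ones.
#'
#' @param weight_history Numeric vector `W(0), ..., W(k-1)`; must be nonempty.
#' @return The median (even counts average the middle two).
#' @export
potentiation_reference <- function(weight_history) {
  if (length(weight_history) == 0L) {
    stop("potentiation_reference: weight history is empty", call. = FALSE)
  }
  stats::median(weight_history)
}

#' Bin-level STDP weight update
#'
#' Computes `W(k) = W(k-1) + dW` for one bin, where the update is the STDP
#' window evaluated at the highest-hitter times, modulated by the bin's
#' amplitude and release fraction, and — for potentiation only — divided by
#' the median reference weight:
#' `dW = gamma_p * (A_k/U_k) * (1/W_p) * exp(-(t_post - t_pre)/tau_plus)` when
#' `t_pre < t_post`, and
#' `dW = -gamma_d * (A_k/U_k) * exp(-(t_pre - t_post)/tau_minus)` when
#' `t_pre >= t_post`. No clipping and no weight bounds are applied. A
#' potentiating update with `W_p = 0` is skipped (`dW = NA`).
#'
#' @param state A [synapse_state()].
#' @param hitters A one-row tibble from [find_hitters()].
#' @param A_k Amplitude from [amplitude()].
#' @param U_k Release fraction from [release_fraction()].
#' @param W_p Reference weight from [potentiation_reference()].
#' @param params An [stdp_params()] object.
#' @return The updated `synapse_state` with the new weight appended to the
#'   history, plus a `last_dW` field.
#' @export
weight_update <- function(state, hitters, A_k, U_k, W_p, params = stdp_params()) {
  dW <- stdp_delta(hitters$t_pre_ms, hitters$t_post_ms, A_k, U_k, W_p, params)
  if (!is.na(dW)) state$weight <- state$weight + dW
  state$last_dW <- dW
  state$weight_history <- c(state$weight_history, state$weight)
  state
}

# The raw dW; NA when potentiation is requested with W_p == 0.
stdp_delta <- function(t_pre, t_post, A_k, U_k, W_p, params) {
  if (t_pre < t_post) {
    if (W_p == 0) return(NA_real_)
    params$gamma_p * (A_k / U_k) * (1 / W_p) * exp(-(t_post - t_pre) / params$tau_plus)
  } else {
    -params$gamma_d * (A_k / U_k) * exp(-(t_pre - t_post) / params$tau_minus)
  }
}

# Full learning pass over the binned activity of one synapse.
#
# `at_pre`, `at_post`, `ar`, `ps` are 7 x n_bins matrices (cells in rows).
# Returns a tibble with one row per bin: the bin statistics, hitters, gate
# flag, modulation terms, dW, the post-update weight, and a skip reason
# (NA when the update was applied).
learn_synapse <- function(at_pre, at_post, ar, ps, cfg) {
  n_bins <- ncol(at_pre)
  sp <- cfg$stdp
  n_b <- 7L
  m_pre <- colMeans(at_pre)
  m_post <- colMeans(at_post)
  m_ar <- colMeans(ar)
  s2_pre <- colSums((at_pre - rep(m_pre, each = n_b))^2) / (n_b - 1)
  s2_ar <- colSums((ar - rep(m_ar, each = n_b))^2) / (n_b - 1)
  cov_b <- colSums((at_pre - rep(m_pre, each = n_b)) * (ar - rep(m_ar, each = n_b))) / (n_b - 1)
  mu_B <- m_pre + m_ar
  var_B <- if (cfg$var_mode == "as-printed") s2_pre + s2_ar - 2 * cov_b else s2_pre + s2_ar + 2 * cov_b
  M_T_B <- colMeans(ps)
  c_pre <- apply(at_pre, 2L, which.max)
  c_post <- apply(at_post, 2L, which.max)
  t_pre <- (c_pre - 1) * cfg$step_ms
  t_post <- (c_post - 1) * cfg$step_ms

  st <- synapse_state(cfg$w_init)
  gate <- logical(n_bins)
  A_k <- U_k <- W_p <- dW <- weight <- rep(NA_real_, n_bins)
  skip <- rep(NA_character_, n_bins)
  mu_S <- var_S <- M_T_S <- numeric(n_bins)
  for (k in seq_len(n_bins)) {
    gate[k] <- if (st$n_bins == 0L) TRUE else {
      (st$sum_at_pre / st$n_bins) <= m_pre[k] && (st$sum_at_post / st$n_bins) <= m_post[k]
    }
    # cumulative statistics advance every bin; the gate only blocks the update
    st$mu_S <- st$mu_S + mu_B[k]
    st$var_S <- st$var_S + var_B[k]
    st$M_T_S <- st$M_T_S + M_T_B[k]
    st$sum_at_pre <- st$sum_at_pre + m_pre[k]
    st$sum_at_post <- st$sum_at_post + m_post[k]
    st$n_bins <- st$n_bins + 1L
    mu_S[k] <- st$mu_S; var_S[k] <- st$var_S; M_T_S[k] <- st$M_T_S
    if (!gate[k]) {
      skip[k] <- "gate"
    } else if (mu_B[k] <= 0 || st$mu_S <= 0 || st$var_S <= 0) {
      skip[k] <- "amplitude_guard"
    } else if (st$M_T_S <= 0) {
      skip[k] <- "release_guard"
    } else {
      a <- if (cfg$amplitude_mode == "var-over-mu") {
        (var_B[k] / mu_B[k]) / (st$var_S / st$mu_S)
      } else {
        (sqrt(var_B[k]) / mu_B[k]) / (sqrt(st$var_S) / st$mu_S)
      }
      u <- M_T_B[k] / st$M_T_S
      wp <- stats::median(st$weight_history)
      d <- stdp_delta(t_pre[k], t_post[k], a, u, wp, sp)
      A_k[k] <- a; U_k[k] <- u; W_p[k] <- wp
      if (is.na(d)) {
        skip[k] <- "W_p_zero"
      } else {
        st$weight <- st$weight + d
        dW[k] <- d
      }
    }
    st$weight_history <- c(st$weight_history, st$weight)
    weight[k] <- st$weight
  }
  tibble::tibble(
    bin = seq_len(n_bins),
    mu_B = mu_B, var_B = var_B, cov_B = cov_b, M_T_B = M_T_B,
    cv_B = ifelse(mu_B > 0, sqrt(pmax(var_B, 0)) / mu_B, NA_real_),
    mean_at_pre = m_pre, mean_at_post = m_post,
    c_pre = as.integer(c_pre), c_post = as.integer(c_post),
    mu_S = mu_S, var_S = var_S, M_T_S = M_T_S,
    gate = gate, A_k = A_k, U_k = U_k, W_p = W_p, dW = dW,
    weight = weight, skip = skip
  )
}
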