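#' Construct a 7-cell bin record
#'
#' A bin is the unit of STDP application: seven consecutive 5 ms cells of one
#' synapse's activity. Each cell stores the number of active transmitters in
#' the presynaptic neuron, the number of active transmitters in the
#' postsynaptic neuron, the number of active receptors in the synapse's
#' receptor group, and the mean release probability of the presynaptic
#' transmitters. Cell time offsets are fixed at `(0, 5, ..., 30)` ms so that
#' the first cell (0 ms) precedes the STDP time constants (20 ms) and the last
#' cell (30 ms) follows them.
#'
#' @param at_pre,at_post Integer vectors of length 7: active transmitter
#'   counts in the pre- and postsynaptic neuron.
#' @param ar_post Integer vector of length 7: active receptor counts in the
#'   synapse's receptor group.
#' @param mean_release Numeric vector of length 7 in `[0, 1]`: per-cell mean
#'   release probability of the presynaptic transmitters.
#' @param synapse_id Optional identifier (direction + group index).
#'
#' @return A tibble of class `bin_record` with columns `cell` (1:7),
#'   `t_offset_ms` (0, 5, ..., 30), `at_pre`, `at_post`, `ar_post`,
#'   `mean_release`.
#' @export
bin_record <- function(at_pre, at_post, ar_post, mean_release, synapse_id = NA_character_) {
  n_b <- 7L
  for (v in list(at_pre, at_post, ar_post, mean_release)) {
    if (length(v) != n_b) stop("bin_record: every cell vector must have length 7", call. = FALSE)
  }
  rec <- tibble::tibble(
    cell = seq_len(n_b),
    t_offset_ms = 5 * (seq_len(n_b) - 1),
    at_pre = as.numeric(at_pre),
    at_post = as.numeric(at_post),
    ar_post = as.numeric(ar_post),
    mean_release = as.numeric(mean_release)
  )
  attr(rec, "synapse_id") <- synapse_id
  class(rec) <- c("bin_record", class(rec))
  rec
}

#' Extract one bin from a run's activity log
#'
#' Rebuilds the 7-cell [bin_record()] of one synapse from the per-step cell
#' log of a [run_experiment()] result, taking the 7 consecutive recorded steps
#' starting at `start_step`.
#'
#' @param run A `dynsyn_run` (must have been recorded with its cell log, the
#'   default).
#' @param direction `"BA"` (presynaptic A, postsynaptic B) or `"AB"`.
#' @param synapse Receptor-group index in `1..g`.
#' @param start_step Recorded step index of the bin's first cell.
#' @return A `bin_record` tibble.
#' @export
collect_bin <- function(run, direction = c("BA", "AB"), synapse = 1L, start_step = 1L) {
  direction <- match.arg(direction)
  cells <- run$cells
  if (is.null(cells)) stop("collect_bin: run has no cell log", call. = FALSE)
  rows <- start_step + 0:6
  if (max(rows) > length(cells$at_A)) {
    stop("collect_bin: fewer than 7 recorded steps from start_step", call. = FALSE)
  }
  pre <- if (direction == "BA") "A" else "B"
  post <- if (direction == "BA") "B" else "A"
  bin_record(
    at_pre = cells[[paste0("at_", pre)]][rows],
    at_post = cells[[paste0("at_", post)]][rows],
    ar_post = cells[[paste0("ar_", post)]][rows, synapse],
    mean_release = cells[[paste0("ps_", pre)]][rows],
    synapse_id = paste0("S_", direction, "_", synapse)
  )
}

#' Bin mean
#'
#' Sample mean of the presynaptic active-transmitter cells plus sample mean of
#' the synapse's active-receptor cells.
#'
#' @param rec A [bin_record()].
#' @return A single number.
#' @export
bin_mean <- function(rec) {
  mean(rec$at_pre) + mean(rec$ar_post)
}

#' Bin covariance
#'
#' Sample covariance (denominator `n_b - 1 = 6`) between the presynaptic
#' active-transmitter cells and the synapse's active-receptor cells.
#'
#' @inheritParams bin_mean
#' @return A single number.
#' @export
bin_covariance <- function(rec) {
  sum((rec$at_pre - mean(rec$at_pre)) * (rec$ar_post - mean(rec$ar_post))) / (length(rec$at_pre) - 1)
}

#' Bin variance
#'
#' The bin's dispersion statistic `S2_pre + S2_post - 2 * Cov` with sample
#' variances and covariance over the seven cells (denominator 6). The defined
#' statistic subtracts twice the covariance (the `"as-printed"` mode, the
#' default); this keeps it nonnegative for all inputs, since
#' `S2_pre + S2_post - 2 Cov >= (S_pre - S_post)^2 >= 0`. The conventional
#' variance-of-a-sum (`+ 2 Cov`) is available as `mode = "plus2cov"` for
#' sensitivity runs.
#'
#' @inheritParams bin_mean
#' @param mode `"as-printed"` (default) or `"plus2cov"`.
#' @return A single nonnegative number (in the default mode).
#' @export
bin_variance <- function(rec, mode = c("as-printed", "plus2cov")) {
  mode <- match.arg(mode)
  s2_pre <- stats::var(rec$at_pre)
  s2_post <- stats::var(rec$ar_post)
  cv <- bin_covariance(rec)
  if (mode == "as-printed") s2_pre + s2_post - 2 * cv else s2_pre + s2_post + 2 * cv
}

#' Bin mean release probability
#'
#' Arithmetic mean of the seven per-cell mean release probabilities of the
#' presynaptic transmitters.
#'
#' @inheritParams bin_mean
#' @return A probability in `[0, 1]`.
#' @export
bin_mean_release <- function(rec) {
  mean(rec$mean_release)
}

#' All summary statistics of a bin
#'
#' @inheritParams bin_variance
#' @return A one-row tibble with `mu_B`, `var_B`, `cov_B`, `mean_release_B`,
#'   and `cv_B` (`sqrt(var_B)/mu_B`; `NA` when `mu_B <= 0`).
#' @export
bin_stats <- function(rec, mode = c("as-printed", "plus2cov")) {
  mu <- bin_mean(rec)
  v <- bin_variance(rec, mode = mode)
  tibble::tibble(
    mu_B = mu,
    var_B = v,
    cov_B = bin_covariance(rec),
    mean_release_B = bin_mean_release(rec),
    cv_B = if (mu > 0) sqrt(max(v, 0)) / mu else NA_real_
  )
}
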