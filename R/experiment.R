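#' Median of a Poisson distribution
#'
#' Smallest integer `m` with `P(X <= m) >= 1/2` for `X ~ Poisson(lambda)`,
#' computed from the CDF.
#'
#' @param lambda Poisson mean (> 0).
#' @return The median as an integer-valued double.
#' @export
poisson_median <- function(lambda) {
  stopifnot(lambda > 0)
  stats::qpois(0.5, lambda)
}

#' Encode a Poisson stream as input bits
#'
#' One Poisson draw with mean `lambda_hz` per 5 ms step; the draw is converted
#' to a bit by the median-threshold rule: 1 iff the value strictly exceeds the
#' distribution's median, else 0. Only 1-bits inject a signal into the
#' network. The printed rate value is used directly as the per-draw mean (the
#' encoding treats the rate as dimensionless; see the methods vignette for
#' this fidelity caveat). Uses the current RNG state.
#'
#' @param lambda_hz Mean rate (> 0).
#' @param n_steps Number of steps to encode.
#' @return An integer vector of 0/1 bits of length `n_steps`.
#' @export
#' @examples
#' set.seed(1)
#' mean(encode_poisson(10, 1000))  # ~ P(X > 10), X ~ Poisson(10)
encode_poisson <- function(lambda_hz, n_steps) {
  stopifnot(lambda_hz > 0, n_steps >= 0)
  med <- poisson_median(lambda_hz)
  as.integer(stats::rpois(n_steps, lambda_hz) > med)
}

#' Run the two-neuron experiment
#'
#' Full protocol: a median-thresholded Poisson bit stream drives neuron A —
#' every 1-bit delivers one signal simultaneously to one uniformly random
#' receptor in *each* of A's receptor groups — signals hop through the network
#' one step per 5 ms per [propagate()], thresholds update every
#' `threshold_period` steps, a 7-cell activity snapshot is recorded per bin
#' (every `bin_stride` steps), and the bin-level STDP pass updates the weight
#' of each of the `2 * g` synapses per bin.
#'
#' All randomness flows from one generator seeded with `seed`; runs are
#' bit-reproducible.
#'
#' @param config A [experiment_config()].
#' @param seed Integer seed.
#' @param keep_cells Keep the per-step cell log in the result (default TRUE;
#'   needed by [collect_bin()]).
#' @return An object of class `dynsyn_run`: a list with `bins` (tibble, one
#'   row per bin x synapse), `thresholds` (tibble), `cells` (per-step log),
#'   `config`, `seed`, `skip_counts`, and `input_fraction`.
#' @export
run_experiment <- function(config, seed = 1L, keep_cells = TRUE) {
  stopifnot(inherits(config, "dynsyn_config"))
  set.seed(seed)
  cfg <- config
  n_steps <- cfg$duration_steps
  g <- cfg$g
  bits <- encode_poisson(cfg$lambda_hz, n_steps)
  net <- build_network(cfg)
  A <- net$neurons[[1]]; B <- net$neurons[[2]]

  # recorded steps: 7 consecutive cells per bin, bins every bin_stride steps
  n_bins <- max(0L, (n_steps - 7L) %/% cfg$bin_stride + 1L)
  bin_starts <- 1L + (seq_len(n_bins) - 1L) * cfg$bin_stride
  rec_steps <- as.vector(outer(0:6, bin_starts, `+`))  # column-major: bin-by-bin
  rec_at <- integer(n_steps)                 # map step -> recorded row (0 = not recorded)
  rec_at[rec_steps] <- seq_along(rec_steps)
  n_rec <- length(rec_steps)

  at_A <- numeric(n_rec); at_B <- numeric(n_rec)
  ps_A <- numeric(n_rec); ps_B <- numeric(n_rec)
  ar_A <- matrix(0, n_rec, g); ar_B <- matrix(0, n_rec, g)

  n_thr <- n_steps %/% cfg$threshold_period
  thr_log <- matrix(NA_real_, n_thr, 2L * (g + 1L))
  thr_steps <- integer(n_thr)

  events <- empty_events(net)
  group_size <- A$group_size
  for (step in seq_len(n_steps)) {
    t_ms <- (step - 1L) * cfg$step_ms
    if (bits[step] == 1L) {
      # one signal to a random receptor of every group of neuron A
      tgt <- (seq_len(g) - 1L) * group_size + sample.int(group_size, g, replace = TRUE)
      events$rec$A <- c(events$rec$A, tgt)
    }
    events <- propagate(net, events, t_ms)
    r <- rec_at[step]
    if (r > 0L) {
      at_A[r] <- sum(A$trans_active); at_B[r] <- sum(B$trans_active)
      ar_A[r, ] <- tabulate(A$group_id[A$rec_active], nbins = g)
      ar_B[r, ] <- tabulate(B$group_id[B$rec_active], nbins = g)
      t_end <- t_ms + cfg$step_ms  # end-of-step snapshot
      ps_A[r] <- mean(transmitter_ps(A, t_end, cfg))
      ps_B[r] <- mean(transmitter_ps(B, t_end, cfg))
    }
    if (step %% cfg$threshold_period == 0L) {
      update_thresholds(net, t_ms)
      i <- step %/% cfg$threshold_period
      thr_steps[i] <- step
      thr_log[i, ] <- c(A$theta_T, A$theta_R, B$theta_T, B$theta_R)
    }
  }

  cells <- list(step = rec_steps, at_A = at_A, at_B = at_B,
                ps_A = ps_A, ps_B = ps_B, ar_A = ar_A, ar_B = ar_B)

  # STDP learning pass per direction and synapse (pure post-processing: the
  # weights never feed back into the network dynamics)
  bins <- purrr::map_dfr(c("BA", "AB"), function(dir) {
    pre_at <- matrix(if (dir == "BA") at_A else at_B, 7L, n_bins)
    post_at <- matrix(if (dir == "BA") at_B else at_A, 7L, n_bins)
    pre_ps <- matrix(if (dir == "BA") ps_A else ps_B, 7L, n_bins)
    ar_post <- if (dir == "BA") ar_B else ar_A
    purrr::map_dfr(seq_len(g), function(s) {
      out <- learn_synapse(pre_at, post_at, matrix(ar_post[, s], 7L, n_bins), pre_ps, cfg)
      dplyr::mutate(out, direction = dir, synapse = s, .after = "bin")
    })
  })

  thresholds <- tibble::tibble(
    step = rep(thr_steps, each = 2L * (g + 1L)),
    neuron = rep(rep(c("A", "B"), each = g + 1L), times = n_thr),
    kind = rep(rep(c("transmitter_set", rep("receptor_group", g)), 2L), times = n_thr),
    group = rep(rep(c(NA_integer_, seq_len(g)), 2L), times = n_thr),
    theta = as.vector(t(thr_log))
  )

  skip_counts <- table(bins$skip, useNA = "no")
  structure(
    list(bins = bins,
         thresholds = thresholds,
         cells = if (keep_cells) cells else NULL,
         config = cfg,
         seed = as.integer(seed),
         n_bins = n_bins,
         skip_counts = as.list(skip_counts),
         input_fraction = mean(bits)),
    class = "dynsyn_run")
}

#' @export
print.dynsyn_run <- function(x, ...) {
  cat("<dynsyn_run> lambda", x$config$lambda_hz, "Hz | seed", x$seed, "|",
      x$n_bins, "bins x", 2L * x$config$g, "synapses |",
      "input fraction", round(x$input_fraction, 3), "\n")
  invisible(x)
}

#' Detect the stabilization bin of a weight series
#'
#' Smallest bin index `k` such that the median absolute successive change of
#' the series over the window `[k, k + window)` is below `tol`. Returns
#' `NA_integer_` when no window qualifies ("not stabilized"). Indices are
#' 1-based; a constant series stabilizes at bin 1.
#'
#' @param weights Numeric weight series (one value per bin).
#' @param window Window length in bins (default 20).
#' @param tol Absolute tolerance; default 1% of the series range (and any
#'   exactly-constant series stabilizes immediately).
#' @return The stabilization bin index, or `NA_integer_`.
#' @export
stabilization_bin <- function(weights, window = 20L, tol = NULL) {
  n <- length(weights)
  if (n <= window) stop("stabilization_bin: series not longer than window", call. = FALSE)
  if (is.null(tol)) tol <- 0.01 * diff(range(weights))
  d <- abs(diff(weights))
  # window [k, k+window) covers successive changes d[k .. k+window-2]
  for (k in seq_len(n - window + 1L)) {
    if (stats::median(d[k:(k + window - 2L)]) < tol || all(d[k:(k + window - 2L)] == 0)) {
      return(k)
    }
  }
  NA_integer_
}

#' Median weight after stabilization
#'
#' @param weights Numeric weight series.
#' @param stab_bin Stabilization bin from [stabilization_bin()]; must not be
#'   `NA`.
#' @return Median of `weights[stab_bin:length(weights)]`.
#' @export
median_after_stabilization <- function(weights, stab_bin) {
  if (is.na(stab_bin)) stop("median_after_stabilization: series did not stabilize", call. = FALSE)
  stopifnot(stab_bin >= 1L, stab_bin <= length(weights))
  stats::median(weights[stab_bin:length(weights)])
}

#' Two-segment regression slopes
#'
#' Ordinary least-squares slopes of a per-bin series over an early and a late
#' segment: bins `[1, break_bin]` and `[break_bin, n]`. Used for the
#' mean-release-probability and CV trend summaries.
#'
#' @param series Numeric per-bin series.
#' @param break_bin Segment boundary (included in both segments).
#' @return A one-row tibble with `m_I` and `m_II`.
#' @export
slope_segments <- function(series, break_bin) {
  n <- length(series)
  if (break_bin < 2L || n - break_bin < 1L) {
    stop("slope_segments: each segment needs at least 2 points", call. = FALSE)
  }
  ols <- function(x, y) {
    xc <- x - mean(x)
    sum(xc * y) / sum(xc^2)
  }
  i1 <- seq_len(break_bin)
  i2 <- break_bin:n
  tibble::tibble(m_I = ols(i1, series[i1]), m_II = ols(i2, series[i2]))
}

#' Per-synapse stabilized summary of a run
#'
#' For every synapse: the stabilization bin of its weight series, the median
#' weight after stabilization, the median CV and mean release probability
#' after stabilization, and the two-segment slopes of the mean release
#' probability and the CV (break at the stabilization bin).
#'
#' @param bins The `bins` tibble of a `dynsyn_run` (data-frame-first; a
#'   `dynsyn_run` is also accepted).
#' @param window,tol Passed to [stabilization_bin()].
#' @return A tibble with one row per direction x synapse.
#' @export
summarize_synapses <- function(bins, window = 20L, tol = NULL) {
  if (inherits(bins, "dynsyn_run")) bins <- bins$bins
  bins |>
    dplyr::arrange(.data$direction, .data$synapse, .data$bin) |>
    dplyr::group_by(.data$direction, .data$synapse) |>
    dplyr::group_map(function(d, key) {
      sb <- stabilization_bin(d$weight, window = window, tol = tol)
      brk <- max(if (is.na(sb)) 2L else sb, 2L)
      brk <- min(brk, nrow(d) - 1L)
      tail_idx <- if (is.na(sb)) integer() else sb:nrow(d)
      cv <- dplyr::coalesce(d$cv_B, 0)
      sl_rel <- slope_segments(d$M_T_B, brk)
      sl_cv <- slope_segments(cv, brk)
      tibble::tibble(
        direction = key$direction, synapse = key$synapse,
        n_bins = nrow(d),
        stab_bin = sb,
        median_weight = if (is.na(sb)) NA_real_ else median_after_stabilization(d$weight, sb),
        median_cv = if (is.na(sb)) NA_real_ else stats::median(d$cv_B[tail_idx], na.rm = TRUE),
        median_release = if (is.na(sb)) NA_real_ else stats::median(d$M_T_B[tail_idx]),
        m_release_I = sl_rel$m_I, m_release_II = sl_rel$m_II,
        m_cv_I = sl_cv$m_I, m_cv_II = sl_cv$m_II,
        final_weight = d$weight[nrow(d)]
      )
    }) |>
    dplyr::bind_rows()
}

#' Sweep the input rate
#'
#' Runs the experiment at each rate, detects stabilization, computes the
#' per-synapse post-stabilization median weights, and averages them over the
#' `g` synapses of each direction: `M_S_BA` (postsynaptic neuron B, driven by
#' A) and `M_S_AB` (postsynaptic neuron A).
#'
#' @param rates Numeric vector of input rates in Hz (all > 0).
#' @param config A [experiment_config()]; its `lambda_hz` is replaced per
#'   rate.
#' @param seed Integer seed (each rate runs with this same seed).
#' @param window,tol Passed to [stabilization_bin()].
#' @return A tibble with one row per rate: `lambda_hz`, `M_S_BA`, `M_S_AB`,
#'   and `all_stabilized` (flag; rows with non-stabilized synapses report the
#'   average over the stabilized ones).
#' @export
rate_sweep <- function(rates, config, seed = 1L, window = 20L, tol = NULL) {
  stopifnot(all(rates > 0))
  purrr::map_dfr(rates, function(r) {
    cfg <- config
    cfg$lambda_hz <- r
    run <- run_experiment(cfg, seed = seed, keep_cells = FALSE)
    sm <- summarize_synapses(run$bins, window = window, tol = tol)
    per_dir <- sm |>
      dplyr::group_by(.data$direction) |>
      dplyr::summarise(m = mean(.data$median_weight, na.rm = TRUE), .groups = "drop")
    tibble::tibble(
      lambda_hz = r,
      M_S_BA = per_dir$m[per_dir$direction == "BA"],
      M_S_AB = per_dir$m[per_dir$direction == "AB"],
      all_stabilized = !anyNA(sm$stab_bin)
    )
  })
}
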