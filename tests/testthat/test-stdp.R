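test_that("highest hitters take the argmax cell with earliest-cell tie-break", {
  rec <- bin_record(c(1, 5, 2, 2, 2, 2, 2), rep(1, 7), rep(0, 7), rep(0, 7))
  h <- find_hitters(rec)
  expect_identical(h$c_pre, 2L)
  expect_identical(h$t_pre_ms, 5)
  expect_identical(h$c_post, 1L)  # all-equal ties resolve to the first cell
  rec2 <- bin_record(rep(1, 7), c(0, 0, 0, 0, 0, 0, 9), rep(0, 7), rep(0, 7))
  expect_identical(find_hitters(rec2)$t_post_ms, 30)
})

test_that("the reference STDP window has the printed branch structure", {
  p <- stdp_params(A_plus = 0.1, A_minus = 0.2, gamma_p = 0.005, gamma_d = 0.00525)
  expect_equal(stdp_window(0, 0, p), -0.2)                       # equality -> depression
  expect_equal(stdp_window(0, 20, p), 0.1 * exp(-1), tolerance = 1e-12)
  expect_equal(stdp_window(20, 0, p), -0.2 * exp(-1), tolerance = 1e-12)
})

test_that("the window integral is negative under the stability condition", {
  p <- stdp_params()
  dt <- seq(-30, 30, by = 0.01)  # dt = t_post - t_pre
  w <- vapply(dt, function(d) stdp_window(0, d, p), numeric(1))
  expect_lt(sum(w) * 0.01, 0)
})

test_that("parameter validation rejects a non-negative window integral", {
  expect_error(stdp_params(gamma_p = 0.01, gamma_d = 0.005), "stability")
  expect_error(stdp_params(gamma_p = 0.005, gamma_d = 0.005), "stability")
  expect_silent(stdp_params())
})

test_that("accumulation is a running sum of bin statistics", {
  rec <- random_bin()
  st <- bin_stats(rec)
  s <- accumulate(synapse_state(), st, rec)
  expect_equal(s$mu_S, st$mu_B)
  expect_equal(s$var_S, st$var_B)
  expect_equal(s$M_T_S, st$mean_release_B)
  # cumulative values equal the sum over a stored bin list
  set.seed(31)
  recs <- replicate(10, random_bin(), simplify = FALSE)
  s <- synapse_state()
  for (r in recs) s <- accumulate(s, bin_stats(r), r)
  expect_equal(s$mu_S, sum(vapply(recs, bin_mean, numeric(1))), tolerance = 1e-12)
  expect_equal(s$var_S, sum(vapply(recs, bin_variance, numeric(1))), tolerance = 1e-12)
  expect_equal(s$M_T_S, sum(vapply(recs, bin_mean_release, numeric(1))), tolerance = 1e-12)
})

test_that("quiescence gate compares bin means against running means inclusively", {
  s0 <- synapse_state()
  expect_true(quiescence_gate(s0, random_bin()))  # first bin is vacuous
  # construct a state with running means (6, 4)
  s <- s0; s$n_bins <- 1L; s$sum_at_pre <- 6; s$sum_at_post <- 4
  low_pre <- bin_record(rep(5, 7), rep(9, 7), rep(0, 7), rep(0, 7))
  expect_false(quiescence_gate(s, low_pre))
  s$sum_at_pre <- 5; s$sum_at_post <- 5
  boundary <- bin_record(rep(5, 7), rep(5, 7), rep(0, 7), rep(0, 7))
  expect_true(quiescence_gate(s, boundary))  # "<=" is inclusive
})

test_that("amplitude and release fraction are the printed cumulative ratios", {
  rec <- random_bin()
  st <- bin_stats(rec)
  s <- accumulate(synapse_state(), st, rec)
  # first bin after accumulate: cumulative stats equal the bin's -> both ratios 1
  expect_equal(amplitude(st, s), 1, tolerance = 1e-12)
  expect_equal(release_fraction(st, s), 1, tolerance = 1e-12)
  # explicit values
  st2 <- tibble::tibble(mu_B = 10, var_B = 2, mean_release_B = 0.5)
  s2 <- list(mu_S = 20, var_S = 8, M_T_S = 5)
  expect_equal(amplitude(st2, s2), (2 / 10) / (8 / 20), tolerance = 1e-12)  # 0.5
  expect_equal(release_fraction(st2, s2), 0.1, tolerance = 1e-12)
  # guards return NA
  expect_true(is.na(amplitude(tibble::tibble(mu_B = 0, var_B = 1), list(mu_S = 5, var_S = 1))))
  expect_true(is.na(release_fraction(st2, list(M_T_S = 0))))
})

test_that("the potentiation reference is the median including W(0)", {
  expect_identical(potentiation_reference(c(0.1, 0.3, 0.2)), 0.2)
  expect_identical(potentiation_reference(0.7), 0.7)
  expect_error(potentiation_reference(numeric()), "empty")
  # a single outlier leaves the median of a long history unchanged
  h <- rep(1, 99)
  expect_identical(potentiation_reference(c(h, 1e6)), 1)
})

test_that("weight updates follow the modulated exponential rule without bounds", {
  p <- stdp_params()
  h_pot <- find_hitters(bin_with_hitters(1, 5))   # t_pre = 0, t_post = 20
  h_dep <- find_hitters(bin_with_hitters(5, 1))   # t_pre = 20, t_post = 0
  h_eq <- find_hitters(bin_with_hitters(3, 3))
  s <- synapse_state(w_init = 1)
  s1 <- weight_update(s, h_pot, A_k = 1, U_k = 1, W_p = 1, params = p)
  expect_equal(s1$last_dW, 0.005 * exp(-1), tolerance = 1e-12)
  s2 <- weight_update(s, h_dep, A_k = 1, U_k = 1, W_p = 1, params = p)
  expect_equal(s2$last_dW, -0.00525 * exp(-1), tolerance = 1e-12)
  s3 <- weight_update(s, h_eq, A_k = 1, U_k = 1, W_p = 1, params = p)
  expect_equal(s3$last_dW, -0.00525, tolerance = 1e-12)  # e^0, depression branch
  # potentiation scales as 1/W_p; depression is independent of W_p
  a <- weight_update(s, h_pot, 1, 1, W_p = 2, params = p)
  expect_equal(a$last_dW, s1$last_dW / 2, tolerance = 1e-12)
  b <- weight_update(s, h_dep, 1, 1, W_p = 2, params = p)
  expect_equal(b$last_dW, s2$last_dW, tolerance = 1e-12)
  # W_p = 0 skips potentiation (weight unchanged), not depression
  z <- weight_update(s, h_pot, 1, 1, W_p = 0, params = p)
  expect_true(is.na(z$last_dW))
  expect_identical(z$weight, 1)
  # history grows by one per applied bin
  expect_length(s1$weight_history, 2)
})

test_that("update sign is positive exactly when the pre hitter leads", {
  p <- stdp_params()
  for (cp in 1:7) for (cq in 1:7) {
    h <- find_hitters(bin_with_hitters(cp, cq))
    expect_identical(h$c_pre, as.integer(cp))
    expect_identical(h$c_post, as.integer(cq))
    s <- weight_update(synapse_state(), h, A_k = 0.7, U_k = 0.3, W_p = 1.1, params = p)
    if (cp < cq) expect_gt(s$last_dW, 0) else expect_lt(s$last_dW, 0)
  }
})

test_that("the vectorised learning pass matches the single-bin operations replayed", {
  set.seed(41)
  n_bins <- 40
  cfg <- experiment_config(duration_steps = 7L)  # only for modes/params
  at_pre <- matrix(sample(0:30, 7 * n_bins, TRUE), 7, n_bins)
  at_post <- matrix(sample(0:30, 7 * n_bins, TRUE), 7, n_bins)
  ar <- matrix(sample(0:30, 7 * n_bins, TRUE), 7, n_bins)
  ps <- matrix(runif(7 * n_bins), 7, n_bins)
  fast <- learn_synapse(at_pre, at_post, ar, ps, cfg)

  st <- synapse_state(cfg$w_init)
  for (k in seq_len(n_bins)) {
    rec <- bin_record(at_pre[, k], at_post[, k], ar[, k], ps[, k])
    stats <- bin_stats(rec)
    gate <- quiescence_gate(st, rec)
    st <- accumulate(st, stats, rec)
    expect_equal(fast$mu_B[k], stats$mu_B, tolerance = 1e-12)
    expect_equal(fast$var_B[k], stats$var_B, tolerance = 1e-12)
    expect_identical(fast$gate[k], gate)
    if (gate && stats$mu_B > 0 && st$mu_S > 0 && st$var_S > 0 && st$M_T_S > 0) {
      a <- amplitude(stats, st)
      u <- release_fraction(stats, st)
      wp <- potentiation_reference(st$weight_history)
      st <- weight_update(st, find_hitters(rec), a, u, wp, cfg$stdp)
      expect_equal(fast$A_k[k], a, tolerance = 1e-12)
      expect_equal(fast$U_k[k], u, tolerance = 1e-12)
      expect_equal(fast$W_p[k], wp, tolerance = 1e-12)
    } else {
      st$weight_history <- c(st$weight_history, st$weight)
      expect_false(is.na(fast$skip[k]))
    }
    expect_equal(fast$weight[k], st$weight, tolerance = 1e-12)
  }
})

test_that("gated bins leave the weight exactly unchanged and stats nondecreasing", {
  cfg <- tiny_config()
  run <- run_experiment(cfg, seed = 5)
  b <- dplyr::filter(run$bins, direction == "BA", synapse == 1) |> dplyr::arrange(bin)
  w_prev <- c(cfg$w_init, b$weight[-nrow(b)])
  gated <- which(b$skip == "gate")
  expect_true(length(gated) > 0)
  expect_identical(b$weight[gated], w_prev[gated])
  expect_true(all(diff(b$mu_S) >= 0))
  expect_true(all(diff(b$var_S) >= -1e-12))
  expect_true(all(diff(b$M_T_S) >= 0))
  ok <- !is.na(b$U_k)
  expect_true(all(b$U_k[ok] > 0 & b$U_k[ok] <= 1 + 1e-12))
  expect_true(all(b$A_k[!is.na(b$A_k)] >= 0))
})
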