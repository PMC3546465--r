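test_that("build_network seeds the right number of active units", {
  set.seed(1)
  cfg <- experiment_config(n_T = 100L, n_R = 100L, g = 4L,
                           init_active_fraction = 0.5, duration_steps = 7L)
  net <- build_network(cfg)
  for (nr in net$neurons) {
    expect_equal(sum(nr$trans_active), 50)
    expect_equal(as.vector(tapply(nr$rec_active, nr$group_id, sum)), rep(12, 4))  # round(0.5*25)
  }
  # reproducible active sets under a fixed seed
  set.seed(1); a1 <- build_network(cfg)$neurons$A$trans_active
  set.seed(1); a2 <- build_network(cfg)$neurons$A$trans_active
  expect_identical(a1, a2)
})

test_that("zero initial fraction leaves all units inactive", {
  set.seed(1)
  cfg <- experiment_config(n_T = 50L, n_R = 50L, g = 5L,
                           init_active_fraction = 0, duration_steps = 7L)
  net <- build_network(cfg)
  expect_false(any(net$neurons$A$trans_active))
  expect_false(any(net$neurons$B$rec_active))
})

test_that("group count must divide receptor count", {
  expect_error(experiment_config(n_R = 100L, g = 3L, n_T = 10L), "divide")
})

test_that("squash modes match their closed forms", {
  expect_identical(squash(0), 0.5)
  expect_equal(squash(1), 1 / (1 + exp(-1)), tolerance = 1e-15)
  expect_equal(squash(1, mode = "as-printed"), 1 / (1 - exp(-1)), tolerance = 1e-15)
  expect_error(squash(0, mode = "as-printed"), "singular")
})

test_that("threshold update implements the homeostatic ratios", {
  set.seed(2)
  cfg <- experiment_config(n_T = 100L, n_R = 100L, g = 2L,
                           init_active_fraction = 0.5, duration_steps = 7L)
  net <- build_network(cfg)
  A <- net$neurons$A; B <- net$neurons$B
  # force exact states: O_A = 0.5, X_A = (0.2, 0.3); O_B = 0.4, X_B = (0.5, 0.5)
  A$trans_active <- rep(c(TRUE, FALSE), 50)
  A$rec_active <- c(rep(TRUE, 10), rep(FALSE, 40), rep(TRUE, 15), rep(FALSE, 35))
  B$trans_active <- rep(c(TRUE, FALSE, FALSE, FALSE, TRUE), 20)
  B$rec_active <- rep(c(TRUE, FALSE), 50)
  update_thresholds(net, t = 0)
  # group thresholds use the presynaptic partner's output fraction
  expect_equal(A$theta_R, squash(c(0.2, 0.3) / 0.4), tolerance = 1e-12)
  expect_equal(B$theta_R, squash(c(0.5, 0.5) / 0.5), tolerance = 1e-12)
  # transmitter-set threshold: f(O * sum of own group ratios)
  expect_equal(A$theta_T, squash(0.5 * (0.2 + 0.3)), tolerance = 1e-12)
  expect_equal(B$theta_T, squash(0.4 * 1.0), tolerance = 1e-12)
})

test_that("all-inactive receptor groups give the midpoint threshold", {
  set.seed(3)
  cfg <- experiment_config(n_T = 20L, n_R = 20L, g = 2L,
                           init_active_fraction = 0, duration_steps = 7L)
  net <- build_network(cfg)
  net$neurons$B$trans_active[1:10] <- TRUE   # O_B = 0.5, X_A = 0
  update_thresholds(net, 0)
  expect_equal(net$neurons$A$theta_R, c(0.5, 0.5))
})

test_that("zero presynaptic output is capped at x_max in the group ratio", {
  set.seed(3)
  cfg <- experiment_config(n_T = 20L, n_R = 20L, g = 2L,
                           init_active_fraction = 0.5, duration_steps = 7L, x_max = 10)
  net <- build_network(cfg)
  net$neurons$B$trans_active[] <- FALSE  # O_B = 0
  update_thresholds(net, 0)
  expect_equal(net$neurons$A$theta_R, rep(squash(10), 2))
})

test_that("evaluate_unit applies strict threshold comparison and records history", {
  p <- stp_params()
  unit <- list(role = "transmitter", state = "inactive",
               arrival_times = numeric(), release_times = numeric())
  # fresh transmitter: Ps = 1 - e^{-200} ~ 1 > theta
  u <- evaluate_unit(unit, theta = squash(1), t = 10, params = p)
  expect_identical(u$state, "active")
  expect_identical(u$release_times, 10)
  expect_identical(u$arrival_times, 10)
  # boundary: Ps == theta stays inactive (strict ">")
  ps0 <- u$Ps
  u2 <- evaluate_unit(unit, theta = ps0, t = 10, params = p)
  expect_identical(u2$state, "inactive")
  expect_length(u2$release_times, 0)
  # receptors never record releases
  rec <- list(role = "receptor", state = "inactive",
              arrival_times = numeric(), release_times = numeric())
  r <- evaluate_unit(rec, theta = 0.5, t = 10, params = p)
  expect_identical(r$state, "active")
  expect_length(r$release_times, 0)
})

test_that("propagate conserves or reduces the signal count, never amplifies", {
  set.seed(5)
  cfg <- experiment_config(n_T = 40L, n_R = 40L, g = 2L,
                           init_active_fraction = 0.1, duration_steps = 7L)
  net <- build_network(cfg)
  ev <- empty_events(net)
  ev$rec$A <- sample.int(40, 10, replace = TRUE)
  ev$trans$B <- sample.int(40, 5, replace = TRUE)
  n_in <- 15L
  out <- propagate(net, ev, t = 0)
  n_out <- length(out$rec$A) + length(out$rec$B) + length(out$trans$A) + length(out$trans$B)
  expect_lte(n_out, n_in)
  # fresh units have Ps ~ 1 > sigmoid thresholds, so nothing is dropped here
  expect_identical(n_out, n_in)
})

test_that("propagate drops signals arriving at units that go inactive", {
  set.seed(6)
  cfg <- experiment_config(n_T = 10L, n_R = 10L, g = 1L,
                           init_active_fraction = 0, duration_steps = 7L)
  net <- build_network(cfg)
  net$neurons$A$theta_R <- 1.5  # unattainable: Ps < 1 always
  ev <- empty_events(net)
  ev$rec$A <- c(1L, 2L, 3L)
  out <- propagate(net, ev, t = 0)
  expect_length(out$trans$A, 0)
  expect_false(any(net$neurons$A$rec_active[1:3]))
})

test_that("the engine's vectorised unit updates match evaluate_unit replayed per event", {
  set.seed(8)
  cfg <- tiny_config()
  net <- build_network(cfg)
  theta_T <- net$neurons$A$theta_T
  # drive one transmitter repeatedly; replay the same arrivals through the
  # pure single-unit reference
  unit <- list(role = "transmitter", state = "inactive",
               arrival_times = numeric(), release_times = numeric())
  arrivals <- seq(0, 600, by = 15)
  for (t in arrivals) {
    process_transmitter_events(net$neurons$A, net$neurons$B, 1L, t, cfg)
    unit <- evaluate_unit(unit, theta_T, t, cfg$stp)
    expect_identical(net$neurons$A$trans_active[1], unit$state == "active")
  }
  # lazily decayed kernel state equals the full-history kernels
  t_end <- 650
  C_engine <- cfg$stp$C0 + net$neurons$A$trans_cex[1] *
    exp(-(t_end - net$neurons$A$trans_ct[1]) / cfg$stp$tau_c)
  expect_equal(C_engine, facilitation(cfg$stp, unit$arrival_times, t_end), tolerance = 1e-12)
  V_engine <- max(0, cfg$stp$V0 - net$neurons$A$trans_vsum[1] *
    exp(-(t_end - net$neurons$A$trans_vt[1]) / cfg$stp$tau_v))
  expect_equal(V_engine, depletion(cfg$stp, unit$release_times, t_end), tolerance = 1e-12)
})

test_that("activity ratios stay in [0, 1]", {
  set.seed(9)
  net <- build_network(tiny_config())
  ar <- activity_ratios(net)
  expect_true(all(ar$O >= 0 & ar$O <= 1))
  expect_true(all(ar$X >= 0 & ar$X <= 1))
})
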