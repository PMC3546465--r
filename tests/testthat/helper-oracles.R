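# Independent brute-force oracles: plain loops over the full event history,
# written without reference to the package's internals.

oracle_facilitation <- function(C0, alpha, tau_c, arrivals, t) {
  acc <- C0
  for (ti in arrivals) {
    if (ti < t) acc <- acc + alpha * exp(-(t - ti) / tau_c)
  }
  acc
}

oracle_depletion <- function(V0, tau_v, releases, t) {
  acc <- V0
  for (ti in releases) {
    if (ti < t) acc <- acc - exp(-(t - ti) / tau_v)
  }
  max(0, acc)
}

oracle_release_prob <- function(C, V) 1 - exp(-C * V)

# Bin statistics recomputed from the raw 7-tuples with explicit sums.
oracle_bin_stats <- function(at_pre, ar_post, mean_release) {
  n <- 7
  m1 <- sum(at_pre) / n
  m2 <- sum(ar_post) / n
  s1 <- sum((at_pre - m1)^2) / (n - 1)
  s2 <- sum((ar_post - m2)^2) / (n - 1)
  cv <- sum((at_pre - m1) * (ar_post - m2)) / (n - 1)
  list(mu = m1 + m2, var = s1 + s2 - 2 * cv, cov = cv, mrel = sum(mean_release) / n)
}

# Brute-force scan for the stabilization rule.
oracle_stab_scan <- function(w, window, tol) {
  d <- abs(diff(w))
  n <- length(w)
  for (k in seq_len(n - window + 1)) {
    dd <- d[k:(k + window - 2)]
    if (median(dd) < tol || all(dd == 0)) return(k)
  }
  NA_integer_
}

# Random bin record for property tests.
random_bin <- function() {
  bin_record(
    at_pre = sample(0:50, 7, replace = TRUE),
    at_post = sample(0:50, 7, replace = TRUE),
    ar_post = sample(0:50, 7, replace = TRUE),
    mean_release = runif(7)
  )
}

# A bin whose pre/post highest hitters sit at prescribed cells (unique argmax).
bin_with_hitters <- function(c_pre, c_post) {
  at_pre <- rep(1, 7); at_pre[c_pre] <- 10
  at_post <- rep(1, 7); at_post[c_post] <- 10
  bin_record(at_pre, at_post, ar_post = c(3, 1, 4, 1, 5, 9, 2), mean_release = rep(0.5, 7))
}

# Tiny fast configuration for engine tests.
tiny_config <- function(...) {
  experiment_config(lambda_hz = 10, preset = "desk",
                    n_T = 60L, n_R = 60L, g = 3L, duration_steps = 700L, ...)
}
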