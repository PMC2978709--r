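# shared fixtures for the suite; everything is generated in code

# deterministic pool-depletion sequence: m_i = p * remaining pool, exact
depletion_sequence <- function(pool, p, n_pulses) {
  m <- numeric(n_pulses)
  for (i in seq_len(n_pulses)) {
    m[i] <- p * pool
    pool <- pool - m[i]
  }
  m
}

# build a noiseless trace with quantal events at known times
trace_with_events <- function(times_ms, amplitudes_mv, duration_ms,
                              v_rest = -70, sample_rate = 10000,
                              noise_sd = 0, rise_tau = 0.5, decay_tau = 5,
                              seed = 1) {
  dt_ms <- 1000 / sample_rate
  v <- rep(v_rest, ceiling(duration_ms / dt_ms))
  kern <- nmjquant:::quantal_kernel(rise_tau, decay_tau, dt_ms)
  for (i in seq_along(times_ms)) {
    v <- nmjquant:::add_kernel(v, floor(times_ms[i] / dt_ms) + 1L,
                               amplitudes_mv[i], kern)
  }
  if (noise_sd > 0) {
    v <- v + withr::with_seed(seed, rnorm(length(v), 0, noise_sd))
  }
  voltage_trace(v, sample_rate, v_rest = v_rest)
}

# match detected events to ground-truth times within a tolerance
match_events <- function(detected_ms, truth_ms, tol_ms = 3) {
  hits <- vapply(truth_ms, function(t0) any(abs(detected_ms - t0) <= tol_ms),
                 logical(1))
  fps <- vapply(detected_ms, function(t0) !any(abs(truth_ms - t0) <= tol_ms),
                logical(1))
  list(n_hit = sum(hits), n_fp = sum(fps), n_truth = length(truth_ms))
}

# two-group samples with exact means (n values per group, zero-mean jitter)
cohort_with_means <- function(mean_control, mean_test, n = 6, spread = 1) {
  jitter <- seq(-1, 1, length.out = n) * spread
  tibble::tibble(
    group = rep(c("control", "test"), each = n),
    value = c(mean_control + jitter, mean_test + jitter)
  )
}
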