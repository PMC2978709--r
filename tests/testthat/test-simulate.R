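test_that("quantal amplitudes have the requested mean and stay positive", {
  p0 <- quantal_params(q_mean = 0.61, q_cv = 0)
  expect_equal(sample_quantal_amplitude(p0, n = 5, seed = 1),
               rep(0.61, 5))

  p <- quantal_params(q_mean = 0.61, q_cv = 0.3)
  draws <- sample_quantal_amplitude(p, n = 1e5, seed = 2)
  expect_lt(abs(mean(draws) - 0.61) / 0.61, 0.01)

  wide <- quantal_params(q_mean = 0.61, q_cv = 2.0)
  expect_true(all(sample_quantal_amplitude(wide, n = 1e5, seed = 3) > 0))

  # identical seeds give identical draws
  expect_identical(sample_quantal_amplitude(p, 10, seed = 9),
                   sample_quantal_amplitude(p, 10, seed = 9))
})

test_that("parameter constructors validate their invariants", {
  expect_error(quantal_params(q_mean = -1), "q_mean")
  expect_error(quantal_params(rise_tau = 5, decay_tau = 2), "rise_tau")
  expect_error(release_model(p0 = 1.5), "p0")
  expect_error(release_model(pool_size = -3), "pool_size")
  expect_error(membrane_model(v_rest = 10, v_rev = 0), "below")
})

test_that("spontaneous event counts follow the Poisson law", {
  q <- quantal_params(); m <- membrane_model(sample_rate = 2000)

  zero <- simulate_spontaneous(0, 10, q, m, seed = 1)
  expect_identical(nrow(zero$event_truth), 0L)
  expect_lt(max(abs(zero$trace$v_mv - m$v_rest)), 6 * m$noise_sd)

  counts <- vapply(1:200, function(s) {
    nrow(simulate_spontaneous(8.97, 60, q, m, seed = s)$event_truth)
  }, numeric(1))
  lambda <- 8.97  # events per 60 s at 8.97/min
  expect_lt(abs(mean(counts) - lambda), 3 * sqrt(lambda / 200))

  # chi-square goodness of fit against the Poisson reference
  brk <- c(-Inf, 4, 6, 8, 10, 12, Inf)
  obs <- table(cut(counts, brk))
  p_bins <- diff(ppois(c(-1, 4, 6, 8, 10, 12, Inf), lambda))
  gof <- suppressWarnings(chisq.test(as.vector(obs), p = p_bins))
  expect_gt(gof$p.value, 0.01)
})

test_that("noiseless spontaneous events are visible above baseline", {
  q <- quantal_params(q_cv = 0)
  m <- membrane_model(noise_sd = 0, sample_rate = 5000)
  sim <- simulate_spontaneous(10, 30, q, m, seed = 4)
  expect_gt(nrow(sim$event_truth), 0)
  expect_gte(max(sim$trace$v_mv), m$v_rest + 0.9 * q$q_mean *
               (1 / (1 + m$f_sat * q$q_mean / (m$v_rev - m$v_rest))))
})

test_that("simulated traces are bit-identical under the same seed", {
  q <- quantal_params(); m <- membrane_model()
  a <- simulate_spontaneous(9, 5, q, m, seed = 7)
  b <- simulate_spontaneous(9, 5, q, m, seed = 7)
  expect_identical(a$trace$v_mv, b$trace$v_mv)
  expect_identical(a$event_truth, b$event_truth)
  tr1 <- simulate_train(release_model(100, 0.2), q, m, c(10, 30), seed = 5)
  tr2 <- simulate_train(release_model(100, 0.2), q, m, c(10, 30), seed = 5)
  expect_identical(tr1$trace$v_mv, tr2$trace$v_mv)
})

test_that("evoked release is binomial and conserves the pool", {
  q <- quantal_params(); m <- membrane_model(noise_sd = 0)

  silent <- simulate_train(release_model(100, 0), q, m, c(10, 30), seed = 1)
  expect_identical(silent$event_truth$quanta, c(0L, 0L))
  expect_equal(max(abs(silent$trace$v_mv - m$v_rest)), 0)

  # first-pulse mean within 3 SE of N * p0
  rel <- release_model(640, 0.027)
  k1 <- vapply(1:1000, function(s) {
    simulate_train(rel, q, m, 5, seed = s, tail_ms = 10)$event_truth$quanta[1]
  }, integer(1))
  se <- sqrt(640 * 0.027 * (1 - 0.027) / 1000)
  expect_lt(abs(mean(k1) - 640 * 0.027), 3 * se)

  # depletion without replenishment can never release more than the pool
  rel2 <- release_model(100, 0.2)
  totals <- vapply(1:200, function(s) {
    sum(simulate_train(rel2, q, m, seq(10, 390, 20),
                       seed = s)$event_truth$quanta)
  }, integer(1))
  expect_true(all(totals <= 100))

  # per-pulse release declines in expectation as the pool empties
  mean_per_pulse <- rowMeans(vapply(1:200, function(s) {
    simulate_train(rel2, q, m, seq(10, 390, 20), seed = s)$event_truth$quanta
  }, integer(20)))
  expect_true(all(diff(mean_per_pulse[1:10]) < 0))
})

test_that("facilitation raises the second response of a pair", {
  q <- quantal_params(q_cv = 0); m <- membrane_model(noise_sd = 0)
  rel <- release_model(640, 0.027, facilitation_increment = 0.012,
                       facilitation_tau = 50)
  k <- vapply(1:600, function(s) {
    simulate_train(rel, q, m, c(10, 20), seed = s)$event_truth$quanta
  }, integer(2))
  expect_gt(mean(k[2, ]), mean(k[1, ]))
})

test_that("saturation is hyperbolic, bounded, and inverts exactly", {
  m <- membrane_model(v_rest = -50, v_rev = 0, f_sat = 0.8)
  m0 <- membrane_model(v_rest = -50, v_rev = 0, f_sat = 0)
  v <- c(0, 0.61, 3, 7.27, 20)
  expect_equal(saturate(v, m0), v)
  expect_equal(saturate(11.9047619047619, m), 10, tolerance = 1e-12)
  # asymptote E / f_sat
  expect_lt(saturate(1e9, m), 50 / 0.8)
  expect_true(all(diff(saturate(seq(0, 30, 0.5), m)) > 0))
  expect_true(all(saturate(v, m) <= v))
})

test_that("morphometry tables match the requested count distribution", {
  specs <- tibble::tibble(group = "g", mean_count = 64.3, dispersion = Inf,
                          n = 1e4)
  tab <- simulate_morphometry(specs, seed = 1)
  expect_lt(abs(mean(tab$count) - 64.3) / 64.3, 0.01)

  zero <- simulate_morphometry(
    tibble::tibble(group = "g", mean_count = 0, n = 50), seed = 1)
  expect_true(all(zero$count == 0))

  # over-dispersion: small size parameter gives variance above the mean
  od <- simulate_morphometry(
    tibble::tibble(group = "g", mean_count = 64.3, dispersion = 1.8,
                   n = 5000), seed = 2)
  expect_gt(var(od$count), 10 * mean(od$count))
  expect_true(all(od$perimeter_um > 0))
  expect_true(all(od$area_um2 > 0))
})

test_that("group differences built into the generator are recovered", {
  specs <- tibble::tibble(
    group = c("control", "smndelta7"),
    mean_count = c(64.3, 46.1), dispersion = c(12, 12), n = c(180, 163)
  )
  tab <- simulate_morphometry(specs, seed = 3)
  cmp <- group_compare(dplyr::mutate(tab, value = count),
                       control = "control")
  truth_pc <- percent_change(64.3, 46.1)
  # Monte-Carlo error on the percent change at these n and dispersions
  expect_lt(abs(glance(cmp)$percent_change - truth_pc), 6)
  expect_lt(glance(cmp)$p_value, 0.001)
})

test_that("tension waveforms reproduce their construction parameters", {
  flat <- simulate_tension(0, stim_freq = 1, n_stim = 1)
  expect_equal(max(abs(flat$force_g)), 0)

  tw <- simulate_tension(2.0, stim_freq = 1, n_stim = 1)
  expect_lt(abs(peak_force(tw) - 2.0) / 2.0, 0.01)

  tet <- simulate_tension(2.0, stim_freq = 100, n_stim = 50)
  expect_gte(peak_force(tet), peak_force(tw))

  expect_identical(simulate_tension(1.5, seed = 3, noise_sd = 0.01)$force_g,
                   simulate_tension(1.5, seed = 3, noise_sd = 0.01)$force_g)
})
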